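# End-to-end design pipeline: annotation + genome in, per-gene arm stores
# and ranked knock-in / knock-out scenarios out.

#' Run the full design pipeline
#'
#' For every (requested) gene: build target regions from the gene's exon
#' projections, generate the homology-arm database, design knock-in
#' scenarios per projection and knock-out scenarios per eligible exon, and
#' link complementary stop-codon knock-ins. Writes per-gene arm stores and
#' scenario tables under \code{out_dir} when given.
#'
#' @param ccds_path CCDS-style annotation table.
#' @param fasta_path soft-masked genome FASTA.
#' @param out_dir output directory, or \code{NULL} for in-memory results
#'   only.
#' @param params a \code{design_params}.
#' @param engine a \code{primer_engine}.
#' @param genes optional integer vector restricting the run to some GeneIDs.
#' @return list with \code{gms} (the parsed \code{GeneModelSet}),
#'   \code{arms} (named list of per-gene \code{arm_store}s),
#'   \code{knockin}, \code{knockout} (scenario data frames),
#'   \code{ko_options} (per eligible exon: deletion design / complementary
#'   knock-in availability) and \code{summary} (named counts).
#' @export
run_pipeline <- function(ccds_path, fasta_path, out_dir = NULL,
                         params = design_params(), engine = builtin_engine(),
                         genes = NULL) {
  gms <- parse_ccds(ccds_path)
  genome <- genome_store(fasta_path)
  gene_ids <- sort(unique(gms$transcripts$gene_id))
  if (!is.null(genes)) gene_ids <- intersect(gene_ids, as.integer(genes))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "arms"), showWarnings = FALSE, recursive = TRUE)
  }

  arms <- list()
  ki_all <- list(); ko_all <- list(); opt_all <- list()
  for (gid in gene_ids) {
    pr <- project_exons(gms, gid)
    regions <- lapply(seq_len(nrow(pr)), function(i)
      target_region(genome, pr$chrom[i], pr$start[i], pr$end[i],
                    params$flank_size))
    store <- build_arm_database(gid, regions, params, engine)
    arms[[as.character(gid)]] <- store
    if (!is.null(out_dir)) {
      utils::write.table(as.data.frame(store),
                         file.path(out_dir, "arms", paste0("gene_", gid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # knock-in per projection; the gene's other features feed the exclusion
    # rules (unique exons outside the target projection)
    ue <- compress_exons(gms, gid)
    ki_gene <- list()
    for (i in seq_len(nrow(pr))) {
      others <- ue[!(ue$start >= pr$start[i] & ue$end <= pr$end[i]),
                   c("start", "end"), drop = FALSE]
      ki <- design_knockin(gid, pr$chrom[i], pr$start[i], pr$end[i],
                           store, others, params)
      if (nrow(ki)) ki_gene[[length(ki_gene) + 1L]] <- ki
    }
    ki_gene <- if (length(ki_gene)) do.call(rbind, ki_gene) else empty_scenarios()
    ki_all[[as.character(gid)]] <- ki_gene

    elig <- knockout_eligible_exons(gms, gid)
    for (i in seq_len(nrow(elig))) {
      exon <- list(start = elig$start[i], end = elig$end[i], eligible = TRUE)
      res <- design_knockout(gid, elig$chrom[i], exon, store, ki_gene, params)
      ko_all[[length(ko_all) + 1L]] <- res$scenarios
      opt_all[[length(opt_all) + 1L]] <- data.frame(
        gene_id = gid, chrom = elig$chrom[i],
        start = elig$start[i], end = elig$end[i],
        n_deletion = nrow(res$scenarios),
        n_complementary = nrow(res$complementary),
        has_option = res$has_option
      )
    }
  }

  knockin <- if (length(ki_all)) do.call(rbind, ki_all) else empty_scenarios()
  rownames(knockin) <- NULL
  knockout <- if (length(ko_all)) do.call(rbind, ko_all) else empty_scenarios()
  rownames(knockout) <- NULL
  ko_options <- if (length(opt_all)) do.call(rbind, opt_all) else
    data.frame(gene_id = integer(), chrom = character(), start = integer(),
               end = integer(), n_deletion = integer(),
               n_complementary = integer(), has_option = logical())
  rownames(ko_options) <- NULL

  summary <- pipeline_summary(gms, arms, knockin, knockout, ko_options)
  if (!is.null(out_dir)) {
    export_scenarios(knockin, file.path(out_dir, "knockin.tsv"), "tsv")
    export_scenarios(knockout, file.path(out_dir, "knockout.tsv"), "tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(gms = gms, arms = arms, knockin = knockin, knockout = knockout,
       ko_options = ko_options, summary = summary)
}

# aggregate counts over a pipeline run
pipeline_summary <- function(gms, arms, knockin, knockout, ko_options) {
  ann <- annotation_summary(gms)
  pr <- .projections_all(gms)
  feat_key <- paste(pr$gene_id, pr$start, pr$end)
  ki_key <- unique(paste(knockin$gene_id, knockin$feature_start,
                         knockin$feature_end))
  covered <- feat_key %in% ki_key
  # bases of projected exon sequence covered by >= 1 knock-in scenario's
  # target feature
  base_cov <- if (nrow(pr)) sum((pr$end - pr$start)[covered]) /
    sum(pr$end - pr$start) else NA_real_
  list(
    transcripts = ann$transcripts, genes = ann$genes, exons = ann$exons,
    unique_exons = ann$unique_exons, projections = ann$projections,
    projected_length = ann$projected_length,
    eligible_exons = ann$eligible_exons, eligible_genes = ann$eligible_genes,
    n_arms = sum(vapply(arms, nrow, 0L)),
    genes_with_arms = sum(vapply(arms, nrow, 0L) > 0),
    knockin_scenarios = nrow(knockin),
    features_with_knockin = sum(covered),
    feature_fraction_with_knockin = if (nrow(pr)) mean(covered) else NA_real_,
    base_fraction_with_knockin = base_cov,
    knockout_scenarios = nrow(knockout),
    exons_with_knockout = if (nrow(ko_options)) sum(ko_options$n_deletion > 0) else 0L,
    exons_with_any_ko_option = if (nrow(ko_options)) sum(ko_options$has_option) else 0L,
    ko_option_fraction = if (nrow(ko_options)) mean(ko_options$has_option) else NA_real_
  )
}
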