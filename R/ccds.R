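# CCDS-style annotation: transcripts, unique exons, exon projections and
# knock-out eligibility.
#
# The input dialect is the tab-separated CCDS table (columns chromosome,
# nc_accession, gene, gene_id, ccds_id, ccds_status, cds_strand, cds_from,
# cds_to, cds_locations, match_type). CCDS coordinates are 0-based with an
# inclusive end; they are converted to the internal 0-based half-open
# convention on parse (end = cds_to + 1).

CCDS_REQUIRED <- c("chromosome", "gene", "gene_id", "ccds_id", "ccds_status",
                   "cds_strand", "cds_from", "cds_to", "cds_locations")

#' Parse a CCDS-style annotation table
#'
#' Keeps only records whose status is exactly \code{"Public"} (case
#' sensitive; statuses like \code{"Public, under review"} are excluded) and
#' that carry a GeneID. Records with unparsable coordinates or a missing
#' GeneID are skipped with a warning; structurally malformed lines (wrong
#' field count) are an error naming the line.
#'
#' @param path tab-separated CCDS-dialect file with a header line.
#' @return a \code{GeneModelSet}: list with \code{transcripts} (one row per
#'   kept transcript) and \code{exons} (one row per exon occurrence,
#'   0-based half-open).
#' @export
parse_ccds <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file: ", path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(CCDS_REQUIRED, cols)
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != length(cols))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, ": expected ",
         length(cols), " fields, found ", nf[bad[1]])
  }
  if (!length(body)) {
    return(new_gene_model_set(empty_transcripts(), empty_exons()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- cols
  tab$line <- seq_along(body) + 1L

  pub <- tab[tab$ccds_status == "Public", , drop = FALSE]
  gene_id <- suppressWarnings(as.integer(pub$gene_id))
  no_gid <- is.na(gene_id)
  if (any(no_gid)) {
    log_note(sum(no_gid), " Public record(s) without a parseable GeneID skipped")
    pub <- pub[!no_gid, , drop = FALSE]
    gene_id <- gene_id[!no_gid]
  }
  loc_ok <- grepl("^\\[\\s*\\d+\\s*-\\s*\\d+\\s*(,\\s*\\d+\\s*-\\s*\\d+\\s*)*\\]$",
                  pub$cds_locations)
  if (any(!loc_ok)) {
    warning(sum(!loc_ok), " Public record(s) with unparsable cds_locations skipped (first at line ",
            pub$line[which(!loc_ok)[1]], ")", call. = FALSE)
    pub <- pub[loc_ok, , drop = FALSE]
    gene_id <- gene_id[loc_ok]
  }
  if (!nrow(pub)) {
    return(new_gene_model_set(empty_transcripts(), empty_exons()))
  }

  locs <- strsplit(gsub("\\[|\\]|\\s", "", pub$cds_locations), ",", fixed = TRUE)
  n_ex <- lengths(locs)
  pieces <- strsplit(unlist(locs), "-", fixed = TRUE)
  starts <- as.integer(vapply(pieces, `[`, "", 1L))
  ends <- as.integer(vapply(pieces, `[`, "", 2L)) + 1L  # inclusive -> half-open
  exons <- data.frame(
    ccds_id = rep(pub$ccds_id, n_ex),
    gene_id = rep(gene_id, n_ex),
    chrom = rep(pub$chromosome, n_ex),
    strand = rep(pub$cds_strand, n_ex),
    start = starts, end = ends,
    stringsAsFactors = FALSE
  )
  if (any(exons$end <= exons$start)) {
    stop("malformed exon interval (end <= start) at line ",
         rep(pub$line, n_ex)[which(exons$end <= exons$start)[1]])
  }
  transcripts <- data.frame(
    ccds_id = pub$ccds_id, gene_id = gene_id, gene_symbol = pub$gene,
    chrom = pub$chromosome, strand = pub$cds_strand,
    status = pub$ccds_status, n_exons = n_ex,
    stringsAsFactors = FALSE
  )
  new_gene_model_set(transcripts, exons)
}

empty_transcripts <- function() {
  data.frame(ccds_id = character(), gene_id = integer(),
             gene_symbol = character(), chrom = character(),
             strand = character(), status = character(),
             n_exons = integer(), stringsAsFactors = FALSE)
}
empty_exons <- function() {
  data.frame(ccds_id = character(), gene_id = integer(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

new_gene_model_set <- function(transcripts, exons) {
  structure(list(transcripts = transcripts, exons = exons),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("<GeneModelSet>", n_transcripts(x), "transcripts,", n_genes(x),
      "genes,", n_exons(x), "exon occurrences\n")
  invisible(x)
}

#' Totals of a GeneModelSet
#'
#' @param gms a \code{GeneModelSet}.
#' @return integer count.
#' @export
n_transcripts <- function(gms) nrow(gms$transcripts)

#' @rdname n_transcripts
#' @export
n_genes <- function(gms) length(unique(gms$transcripts$gene_id))

#' @rdname n_transcripts
#' @export
n_exons <- function(gms) nrow(gms$exons)

.assert_gene <- function(gms, gene_id) {
  if (!gene_id %in% gms$transcripts$gene_id) {
    stop("unknown gene_id: ", gene_id)
  }
}

# unique exons for every gene at once (vectorised); internal backbone of
# compress_exons / knockout_eligible_exons
.unique_exons_all <- function(gms) {
  ex <- gms$exons
  if (!nrow(ex)) {
    return(data.frame(gene_id = integer(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      ccds_ids = character(), n_ccds = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ex$gene_id, ex$chrom, ex$start, ex$end, sep = "\r")
  ord <- order(ex$gene_id, ex$chrom, ex$start, ex$end, ex$ccds_id)
  ex <- ex[ord, ]; key <- key[ord]
  first <- !duplicated(key)
  ids <- vapply(split(ex$ccds_id, factor(key, levels = key[first])),
                function(v) paste(sort(unique(v)), collapse = ","), character(1))
  out <- ex[first, c("gene_id", "chrom", "strand", "start", "end")]
  out$ccds_ids <- as.vector(ids)
  out$n_ccds <- lengths(strsplit(out$ccds_ids, ",", fixed = TRUE))
  out <- out[order(out$gene_id, out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Unique exons of a gene
#'
#' Exon occurrences of one gene sharing identical coordinates are compressed
#' to a single entry that keeps the union of contributing CCDS identifiers.
#'
#' @param gms a \code{GeneModelSet}.
#' @param gene_id integer GeneID present in the set.
#' @return data frame of unique exons (sorted by start) with columns
#'   \code{gene_id, chrom, strand, start, end, ccds_ids, n_ccds}.
#' @export
compress_exons <- function(gms, gene_id) {
  .assert_gene(gms, gene_id)
  ue <- .unique_exons_all(gms)
  out <- ue[ue$gene_id == gene_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# projections for every gene at once; internal backbone of project_exons
.projections_all <- function(gms) {
  ue <- .unique_exons_all(gms)
  if (!nrow(ue)) {
    return(data.frame(gene_id = integer(), chrom = character(),
                      start = integer(), end = integer(), n_members = integer(),
                      commonality = integer(), stringsAsFactors = FALSE))
  }
  grp <- paste(ue$gene_id, ue$chrom, sep = "\r")
  ir <- IRanges::IRanges(ue$start + 1L, ue$end)   # 1-based closed for IRanges
  irl <- S4Vectors::split(ir, factor(grp, levels = unique(grp)))
  red <- IRanges::reduce(irl, min.gapwidth = 0L, with.revmap = TRUE)
  flat <- unlist(red, use.names = FALSE)
  ngrp <- S4Vectors::elementNROWS(red)
  grp_first <- match(unique(grp), grp)
  gene_id <- rep(ue$gene_id[grp_first], ngrp)
  chrom <- rep(ue$chrom[grp_first], ngrp)
  # revmap indices are within-group; translate to rows of ue
  offs <- rep(cumsum(c(0L, head(ngrp_members <- as.integer(table(factor(grp, levels = unique(grp)))), -1L))),
              ngrp)
  revmap <- S4Vectors::mcols(flat)$revmap
  members <- lapply(seq_along(flat), function(i) revmap[[i]] + offs[i])
  n_tx <- tabulate_transcripts(gms)
  commonality <- vapply(members, function(m) {
    length(unique(unlist(strsplit(ue$ccds_ids[m], ",", fixed = TRUE))))
  }, integer(1))
  out <- data.frame(gene_id = gene_id, chrom = chrom,
                    start = IRanges::start(flat) - 1L, end = IRanges::end(flat),
                    n_members = lengths(members), commonality = commonality,
                    stringsAsFactors = FALSE)
  out$members <- members
  out <- out[order(out$gene_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

tabulate_transcripts <- function(gms) {
  tx <- gms$transcripts
  tapply(tx$ccds_id, tx$gene_id, function(v) length(unique(v)))
}

#' Exon projections of a gene
#'
#' Overlapping unique exons of one gene are merged transitively, keeping the
#' outermost coordinates; non-overlapping exons become singleton
#' projections. \code{commonality} counts the distinct transcripts of the
#' gene contributing at least one member exon.
#'
#' @inheritParams compress_exons
#' @return data frame of projections with columns \code{gene_id, chrom,
#'   start, end, n_members, commonality, members} (list of row indices into
#'   \code{compress_exons(gms, gene_id)}).
#' @export
project_exons <- function(gms, gene_id) {
  .assert_gene(gms, gene_id)
  pr <- .projections_all(gms)
  out <- pr[pr$gene_id == gene_id, , drop = FALSE]
  # re-base member indices to the gene's own unique-exon table
  ue <- .unique_exons_all(gms)
  base <- match(TRUE, ue$gene_id == gene_id) - 1L
  out$members <- lapply(out$members, function(m) m - base)
  rownames(out) <- NULL
  out
}

#' Knock-out eligible exons of a gene
#'
#' An exon is eligible when it is present in every transcript variant of its
#' gene (single-transcript genes qualify trivially) and its length is not
#' divisible by 3, so exon skipping cannot restore the reading frame.
#' Decidable from the annotation alone; no genome access.
#'
#' @inheritParams compress_exons
#' @return data frame of eligible unique exons (same columns as
#'   \code{\link{compress_exons}}).
#' @export
knockout_eligible_exons <- function(gms, gene_id) {
  ue <- compress_exons(gms, gene_id)
  n_tx <- length(unique(gms$transcripts$ccds_id[gms$transcripts$gene_id == gene_id]))
  out <- ue[ue$n_ccds == n_tx & (ue$end - ue$start) %% 3L != 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide annotation summary
#'
#' Aggregates the per-gene databases over the whole set: unique exon and
#' projection totals, projected length, projection length distribution, and
#' knock-out eligibility counts.
#'
#' @param gms a \code{GeneModelSet}.
#' @return list of named totals.
#' @export
annotation_summary <- function(gms) {
  ue <- .unique_exons_all(gms)
  pr <- .projections_all(gms)
  n_tx <- tabulate_transcripts(gms)
  elig <- ue$n_ccds == as.integer(n_tx[as.character(ue$gene_id)]) &
    (ue$end - ue$start) %% 3L != 0L
  common <- ue$n_ccds == as.integer(n_tx[as.character(ue$gene_id)])
  plen <- pr$end - pr$start
  list(
    transcripts = n_transcripts(gms),
    genes = n_genes(gms),
    exons = n_exons(gms),
    unique_exons = nrow(ue),
    projections = nrow(pr),
    projected_length = sum(plen),
    projection_length_range = if (nrow(pr)) range(plen) else c(NA, NA),
    projection_length_median = if (nrow(pr)) stats::median(plen) else NA,
    projection_frac_below_700 = if (nrow(pr)) mean(plen < 700) else NA,
    common_exons = sum(common),
    common_exon_genes = length(unique(ue$gene_id[common])),
    eligible_exons = sum(elig),
    eligible_genes = length(unique(ue$gene_id[elig]))
  )
}

#' Export exon projections as BED
#'
#' 0-based half-open records, name field \code{gene_id|index|commonality}.
#'
#' @param gms a \code{GeneModelSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_projections_bed <- function(gms, path) {
  pr <- .projections_all(gms)
  df <- data.frame(pr$chrom, pr$start, pr$end,
                   name = paste(pr$gene_id,
                                stats::ave(pr$start, pr$gene_id, FUN = seq_along),
                                pr$commonality, sep = "|"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
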