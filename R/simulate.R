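# Deterministic synthetic genomes and CCDS-style annotation with ground
# truth, so every pipeline stage is testable offline.
#
# The generator emulates the statistical structure of the real inputs:
# multi-transcript genes with shared, boundary-shifted (overlapping) and
# dropped (unique) exons, non-Public decoy records (including the
# "Public, under review" trap the status filter must exclude), and
# soft-masked repeat tracts of geometric length. It does not model splice
# sites, codon structure or realistic repeat families.

#' Simulation configuration
#'
#' Defaults emulate a compact CCDS-like locus: a 120 kb chromosome at 41%
#' GC, 20% repeat-masked sequence in tracts of mean length 300 nt, 8 genes
#' with 1-3 transcripts, 3-7 exons per transcript with log-normal lengths
#' (median 123 bp, matching the median coding exon length), introns of
#' 250-1500 nt, and 60/20/20% shared/boundary-shifted/dropped exons in
#' alternative transcripts. 20% of genes gain a non-Public decoy record.
#'
#' @param seed integer seed fixing all randomness.
#' @param chrom_len chromosome length (nt).
#' @param chrom chromosome name used in FASTA and table.
#' @param gc GC fraction.
#' @param repeat_density target repeat-masked fraction.
#' @param repeat_mean_len mean repeat tract length (geometric).
#' @param n_genes number of genes.
#' @param transcripts_per_gene inclusive integer range.
#' @param exons_per_transcript inclusive integer range.
#' @param exon_len_meanlog,exon_len_sdlog log-normal exon length parameters.
#' @param intron_len inclusive intron length range (min 60 to keep
#'   boundary shifts inside introns).
#' @param frac_shared,frac_overlap,frac_unique exon fate fractions in
#'   alternative transcripts (must sum to 1).
#' @param frac_nonpublic fraction of genes receiving a non-Public decoy
#'   record.
#' @return a validated \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, chrom_len = 120000L, chrom = "1",
                       gc = 0.41, repeat_density = 0.2,
                       repeat_mean_len = 300L, n_genes = 8L,
                       transcripts_per_gene = c(1L, 3L),
                       exons_per_transcript = c(3L, 7L),
                       exon_len_meanlog = log(123), exon_len_sdlog = 0.6,
                       intron_len = c(250L, 1500L),
                       frac_shared = 0.6, frac_overlap = 0.2,
                       frac_unique = 0.2, frac_nonpublic = 0.2) {
  cfg <- as.list(environment())
  check_that(
    "fractions must lie in [0,1]" = all(unlist(cfg[c(
      "gc", "repeat_density", "frac_shared", "frac_overlap", "frac_unique",
      "frac_nonpublic")]) >= 0 & unlist(cfg[c(
      "gc", "repeat_density", "frac_shared", "frac_overlap", "frac_unique",
      "frac_nonpublic")]) <= 1),
    "exon fate fractions must sum to 1" =
      abs(frac_shared + frac_overlap + frac_unique - 1) < 1e-9,
    "lengths must be positive" = chrom_len > 0 && repeat_mean_len > 0 &&
      all(intron_len > 0) && n_genes >= 1,
    "intron_len must allow boundary shifts (min 60)" = intron_len[1] >= 60
  )
  class(cfg) <- "sim_config"
  cfg
}

.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# repeat tracts drawn until the merged masked fraction reaches the target
.repeat_tracts <- function(chrom_len, density, mean_len) {
  if (density <= 0) return(data.frame(start = integer(), end = integer()))
  target <- density * chrom_len
  starts <- integer(0); ends <- integer(0)
  masked <- 0
  while (masked < target) {
    len <- min(stats::rgeom(1, 1 / mean_len) + 1L, chrom_len)
    s <- sample.int(chrom_len - len + 1L, 1L) - 1L
    starts <- c(starts, s); ends <- c(ends, s + len)
    # merged coverage
    o <- order(starts)
    ss <- starts[o]; ee <- ends[o]
    keep_s <- ss[1]; keep_e <- ee[1]; masked <- 0
    if (length(ss) > 1) {
      ms <- ss[1]; me <- ee[1]
      out_s <- integer(0); out_e <- integer(0)
      for (i in 2:length(ss)) {
        if (ss[i] <= me) me <- max(me, ee[i])
        else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- ss[i]; me <- ee[i] }
      }
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      masked <- sum(out_e - out_s)
    } else masked <- ee[1] - ss[1]
  }
  # final merge
  o <- order(starts)
  ss <- starts[o]; ee <- ends[o]
  ms <- ss[1]; me <- ee[1]; out_s <- integer(0); out_e <- integer(0)
  if (length(ss) > 1) for (i in 2:length(ss)) {
    if (ss[i] <= me) me <- max(me, ee[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- ss[i]; me <- ee[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e)
}

.apply_mask <- function(seq, tracts) {
  if (!nrow(tracts)) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(tracts))) {
    idx <- (tracts$start[i] + 1L):tracts$end[i]
    x[idx] <- tolower(x[idx])
  }
  paste(x, collapse = "")
}

# independent merge used for truth projections (simple scan, not IRanges)
.truth_projections <- function(starts, ends) {
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  ps <- s[1]; pe <- e[1]; out_s <- integer(0); out_e <- integer(0)
  if (length(s) > 1) for (i in 2:length(s)) {
    if (s[i] < pe) pe <- max(pe, e[i])       # strict overlap only
    else { out_s <- c(out_s, ps); out_e <- c(out_e, pe); ps <- s[i]; pe <- e[i] }
  }
  data.frame(start = c(out_s, ps), end = c(out_e, pe))
}

.ccds_line <- function(chrom, gene, gene_id, ccds_id, status, strand,
                       starts, ends) {
  locs <- paste(sprintf("%d-%d", starts, ends - 1L), collapse = ", ")
  paste(chrom, paste0("NC_SIM", chrom), gene, gene_id, ccds_id, status,
        strand, min(starts), max(ends) - 1L, paste0("[", locs, "]"),
        "Identical", sep = "\t")
}

CCDS_HEADER <- "#chromosome\tnc_accession\tgene\tgene_id\tccds_id\tccds_status\tcds_strand\tcds_from\tcds_to\tcds_locations\tmatch_type"

#' Simulate a soft-masked genome with CCDS-style annotation
#'
#' Writes \code{genome.fa}, \code{annotation.txt} (exact CCDS column
#' dialect, including the \code{[from-to, ...]} location syntax and decoy
#' statuses) and \code{truth.json} into \code{dir}. The truth record lists,
#' per gene, the expected unique exons, exon projections, knock-out eligible
#' exons, and the genome's repeat tracts; every truth field is recomputable
#' from the emitted files by the corresponding pipeline operation. Identical
#' seeds give byte-identical files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return list with \code{fasta}, \code{table}, \code{truth_json} paths and
#'   the in-memory \code{truth} list.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simdata")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  L <- config$chrom_len
  seq <- .random_seq(L, config$gc)
  tracts <- .repeat_tracts(L, config$repeat_density, config$repeat_mean_len)
  seq <- .apply_mask(seq, tracts)

  lines <- character(0)
  truth_genes <- list()
  cursor <- 3500L
  ccds_n <- 0L
  for (g in seq_len(config$n_genes)) {
    gene_id <- 1000L + g
    symbol <- sprintf("SIMG%02d", g)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(config$transcripts_per_gene[1]:config$transcripts_per_gene[2], 1)
    n_ex <- sample(config$exons_per_transcript[1]:config$exons_per_transcript[2], 1)
    ex_len <- pmax(30L, as.integer(round(stats::rlnorm(n_ex, config$exon_len_meanlog,
                                                       config$exon_len_sdlog))))
    introns <- sample(config$intron_len[1]:config$intron_len[2], n_ex - 1,
                      replace = TRUE)
    starts <- cursor + c(0L, cumsum(ex_len[-n_ex] + introns))
    ends <- starts + ex_len
    if (ends[n_ex] > L - 3500L) {
      stop("infeasible config: gene ", g, " exceeds the chromosome")
    }
    cursor <- ends[n_ex] + sample(4000:7000, 1)

    # transcript 1 = primary; others share / shift / drop exons
    tx_exons <- list(data.frame(start = starts, end = ends))
    if (n_tx > 1) for (t in 2:n_tx) {
      fate <- sample(c("shared", "overlap", "unique"), n_ex, replace = TRUE,
                     prob = c(config$frac_shared, config$frac_overlap,
                              config$frac_unique))
      fate[1] <- "shared"   # keep at least one exon
      s <- starts; e <- ends; keep <- fate != "unique"
      shift <- sample(5:20, n_ex, replace = TRUE)
      ov <- which(fate == "overlap")
      if (length(ov)) {
        grow <- sample(c(TRUE, FALSE), length(ov), replace = TRUE)
        s[ov] <- ifelse(grow, s[ov] - shift[ov], s[ov] + shift[ov])
        e[ov] <- e[ov] + sample(c(-1L, 1L), length(ov), TRUE) * shift[ov]
        bad <- e[ov] - s[ov] < 20L
        s[ov][bad] <- starts[ov][bad]; e[ov][bad] <- ends[ov][bad]
      }
      tx_exons[[t]] <- data.frame(start = s[keep], end = e[keep])
    }
    for (t in seq_len(n_tx)) {
      ccds_n <- ccds_n + 1L
      lines <- c(lines, .ccds_line(config$chrom, symbol, gene_id,
                                   sprintf("CCDS%d.1", 50000L + ccds_n),
                                   "Public", strand,
                                   tx_exons[[t]]$start, tx_exons[[t]]$end))
    }
    if (stats::runif(1) < config$frac_nonpublic) {
      ccds_n <- ccds_n + 1L
      lines <- c(lines, .ccds_line(config$chrom, symbol, gene_id,
                                   sprintf("CCDS%d.1", 50000L + ccds_n),
                                   sample(c("Withdrawn", "Public, under review",
                                            "Reviewed, update pending"), 1),
                                   strand, tx_exons[[1]]$start, tx_exons[[1]]$end))
    }

    # ground truth from the constructed structure
    all_ex <- do.call(rbind, tx_exons)
    key <- paste(all_ex$start, all_ex$end)
    uniq <- all_ex[!duplicated(key), , drop = FALSE]
    uniq <- uniq[order(uniq$start, uniq$end), ]
    n_containing <- vapply(seq_len(nrow(uniq)), function(i) {
      sum(vapply(tx_exons, function(tx)
        any(tx$start == uniq$start[i] & tx$end == uniq$end[i]), logical(1)))
    }, integer(1))
    proj <- .truth_projections(uniq$start, uniq$end)
    elig <- uniq[n_containing == n_tx & (uniq$end - uniq$start) %% 3L != 0L, ,
                 drop = FALSE]
    truth_genes[[as.character(gene_id)]] <- list(
      gene_id = gene_id, symbol = symbol, n_transcripts = n_tx,
      unique_exons = uniq, projections = proj, eligible_exons = elig
    )
  }

  fasta <- file.path(dir, "genome.fa")
  tab <- file.path(dir, "annotation.txt")
  truth_json <- file.path(dir, "truth.json")
  write_genome(genome_store(stats::setNames(seq, config$chrom)), fasta)
  writeLines(c(CCDS_HEADER, lines), tab)
  truth <- list(chrom = config$chrom, chrom_len = L,
                repeat_tracts = tracts, genes = truth_genes)
  jsonlite::write_json(truth, truth_json, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  list(fasta = fasta, table = tab, truth_json = truth_json, truth = truth)
}

#' Bundled hand-constructed micro fixtures
#'
#' Tiny (under 20 kb) deterministic instances with fully known structure for
#' oracle tests: \code{"one-gene-knockin"} (one clean single-transcript
#' gene, three exons), \code{"ko-eligible"} (two transcripts; one exon
#' eligible, one frame-preserving, one not shared), and \code{"all-masked"}
#' (fully repeat-masked chromosome; the pipeline must yield zero arms).
#'
#' @param name fixture name.
#' @param dir output directory for the files.
#' @return same structure as \code{\link{simulate_dataset}}.
#' @export
micro_fixture <- function(name = c("one-gene-knockin", "ko-eligible",
                                   "all-masked"),
                          dir = tempfile("microfix")) {
  if (length(name) != 1 || !name %in% c("one-gene-knockin", "ko-eligible",
                                        "all-masked")) {
    stop("unknown micro fixture: ", paste(name, collapse = "/"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(424242L)
  chrom <- "1"
  if (name == "one-gene-knockin") {
    L <- 20000L
    seq <- .random_seq(L, 0.45)
    ex <- data.frame(start = c(6000L, 9000L, 12000L),
                     end = c(6100L, 9130L, 12100L))
    lines <- .ccds_line(chrom, "MFK1", 2001L, "CCDS90001.1", "Public", "+",
                        ex$start, ex$end)
    tracts <- data.frame(start = integer(), end = integer())
    genes <- list(`2001` = list(gene_id = 2001L, symbol = "MFK1",
                                n_transcripts = 1L, unique_exons = ex,
                                projections = ex,
                                eligible_exons = ex[(ex$end - ex$start) %% 3L != 0L, ]))
  } else if (name == "ko-eligible") {
    L <- 16000L
    seq <- .random_seq(L, 0.45)
    tx1 <- data.frame(start = c(5000L, 8000L, 11000L),
                      end = c(5100L, 8099L, 11100L))
    tx2 <- data.frame(start = c(5000L, 8000L), end = c(5100L, 8099L))
    lines <- c(.ccds_line(chrom, "MFK2", 2002L, "CCDS90002.1", "Public", "+",
                          tx1$start, tx1$end),
               .ccds_line(chrom, "MFK2", 2002L, "CCDS90003.1", "Public", "+",
                          tx2$start, tx2$end))
    tracts <- data.frame(start = integer(), end = integer())
    genes <- list(`2002` = list(gene_id = 2002L, symbol = "MFK2",
                                n_transcripts = 2L, unique_exons = tx1,
                                projections = tx1,
                                eligible_exons = tx1[1, ]))
  } else {
    L <- 12000L
    seq <- tolower(.random_seq(L, 0.45))
    ex <- data.frame(start = 5000L, end = 5101L)
    lines <- .ccds_line(chrom, "MFK3", 2003L, "CCDS90004.1", "Public", "+",
                        ex$start, ex$end)
    tracts <- data.frame(start = 0L, end = L)
    genes <- list(`2003` = list(gene_id = 2003L, symbol = "MFK3",
                                n_transcripts = 1L, unique_exons = ex,
                                projections = ex,
                                eligible_exons = ex[(ex$end - ex$start) %% 3L != 0L, ]))
  }
  fasta <- file.path(dir, "genome.fa")
  tab <- file.path(dir, "annotation.txt")
  truth_json <- file.path(dir, "truth.json")
  write_genome(genome_store(stats::setNames(seq, chrom)), fasta)
  writeLines(c(CCDS_HEADER, lines), tab)
  truth <- list(chrom = chrom, chrom_len = L, repeat_tracts = tracts,
                genes = genes)
  jsonlite::write_json(truth, truth_json, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  list(fasta = fasta, table = tab, truth_json = truth_json, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
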