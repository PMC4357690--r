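# Wet-lab exports: Gateway attB-tailed amplification primers and
# machine-readable scenario reports (TSV / JSON / BED).

#' Default Gateway attB tail sequences
#'
#' Canonical attB1/attB2 tails for the first homology arm (cloned into a
#' pDONR P1-P2 class entry vector) and attB3/attB4 tails for the second arm.
#' These are sensible, documented defaults and fully user-replaceable: pass
#' any named list with the four keys \code{arm1_fwd}, \code{arm1_rev},
#' \code{arm2_fwd}, \code{arm2_rev} (labels in
#' \code{attr(, "labels")}).
#'
#' @return named list of four tail sequences.
#' @export
att_tails <- function() {
  structure(
    list(arm1_fwd = "GGGGACAAGTTTGTACAAAAAAGCAGGCT",
         arm1_rev = "GGGGACCACTTTGTACAAGAAAGCTGGGT",
         arm2_fwd = "GGGGACAACTTTGTATAATAAAGTTG",
         arm2_rev = "GGGGACAACTTTGTATAGAAAAGTTG"),
    labels = c(arm1_fwd = "attB1", arm1_rev = "attB2",
               arm2_fwd = "attB3", arm2_rev = "attB4")
  )
}

#' attB-tailed amplification primers for one scenario
#'
#' Pure concatenation: each of the four genomic primers (arm1/arm2 x
#' forward/reverse) is prefixed with its configured att tail; the genomic
#' portion is byte-identical to the stored primer, so stripping the tail
#' recovers it exactly. The two arms receive distinct att pairs so they
#' recombine into different entry vectors.
#'
#' @param scenario one scenario row (data frame of one row).
#' @param tails named list of four tails, as \code{\link{att_tails}}.
#' @return data frame with one row per primer: \code{arm}, \code{direction},
#'   \code{att}, \code{tail}, \code{genomic}, \code{tailed}.
#' @export
tail_primers <- function(scenario, tails = att_tails()) {
  stopifnot(nrow(scenario) == 1)
  need <- c("arm1_fwd", "arm1_rev", "arm2_fwd", "arm2_rev")
  miss <- setdiff(need, names(tails))
  if (length(miss)) stop("missing att tail(s) in config: ",
                         paste(miss, collapse = ", "))
  labels <- attr(tails, "labels") %||%
    stats::setNames(need, need)
  genomic <- c(scenario$arm1_fwd_seq, scenario$arm1_rev_seq,
               scenario$arm2_fwd_seq, scenario$arm2_rev_seq)
  data.frame(
    arm = c(1L, 1L, 2L, 2L),
    direction = c("fwd", "rev", "fwd", "rev"),
    att = unname(labels[need]),
    tail = unlist(tails[need], use.names = FALSE),
    genomic = genomic,
    tailed = paste0(unlist(tails[need], use.names = FALSE), genomic),
    stringsAsFactors = FALSE
  )
}

#' Export scenarios to TSV, JSON or BED
#'
#' TSV and JSON carry every scenario field with a stable column order and
#' round-trip losslessly (\code{\link{read_scenarios_tsv}}). BED (0-based
#' half-open) writes one record per arm plus one per gap/deletion interval;
#' the name field encodes \code{gene|feature|category|rank|part}.
#'
#' @param scenarios scenario data frame.
#' @param path output file.
#' @param format \code{"tsv"}, \code{"json"} or \code{"bed"}.
#' @return \code{path}, invisibly.
#' @export
export_scenarios <- function(scenarios, path, format = c("tsv", "json", "bed")) {
  if (length(format) != 1 || !format %in% c("tsv", "json", "bed")) {
    stop("unknown format: ", paste(format, collapse = "/"))
  }
  cols <- intersect(c(SCENARIO_COLS, "gap_mod3", "stop_codon_candidate"),
                    names(scenarios))
  scenarios <- scenarios[, cols, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(scenarios, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(scenarios, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  } else {
    feat <- paste0(scenarios$gene_id, "|", scenarios$feature_chrom, ":",
                   scenarios$feature_start, "-", scenarios$feature_end, "|",
                   scenarios$category, "|", scenarios$rank)
    rec <- function(start, end, part)
      data.frame(chrom = scenarios$feature_chrom, start = start, end = end,
                 name = paste0(feat, "|", part), stringsAsFactors = FALSE)
    bed <- rbind(rec(scenarios$arm1_start, scenarios$arm1_end, "arm1"),
                 rec(scenarios$gap_start, scenarios$gap_end, "gap"),
                 rec(scenarios$arm2_start, scenarios$arm2_end, "arm2"))
    bed <- bed[order(bed$start, bed$end, bed$name), , drop = FALSE]
    con <- file(path, "w")
    writeLines("track name=raavarms_scenarios", con)
    if (nrow(bed)) {
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    close(con)
  }
  invisible(path)
}

#' Read scenarios back from TSV
#'
#' Inverse of \code{\link{export_scenarios}(format = "tsv")}.
#'
#' @param path TSV written by \code{export_scenarios}.
#' @return scenario data frame.
#' @export
read_scenarios_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("feature_chrom", "category", "arm1_fwd_seq", "arm1_rev_seq",
                "arm2_fwd_seq", "arm2_rev_seq")) {
    if (col %in% names(df)) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][is.na(df[[col]])] <- ""
    }
  }
  df
}
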