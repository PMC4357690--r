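# Soft-masked genome access.
#
# Sequences are held in memory as plain character strings (case preserved;
# lowercase and N mark repeat-masked positions). FASTA I/O goes through
# Biostrings::BStringSet, which is byte-preserving.

#' Open a soft-masked genome
#'
#' @param x path to a FASTA file, or a named character vector of sequences.
#' @return an object of class \code{genome_store}.
#' @examples
#' g <- genome_store(c(chr1 = "ACGTacgtNNNNACGT"))
#' fetch(g, "chr1", 0, 8)
#' @export
genome_store <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    bs <- Biostrings::readBStringSet(x)
    seqs <- as.character(bs)
    names(seqs) <- sub("\\s.*$", "", names(bs))   # drop FASTA description
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else {
    stop("genome_store: need a FASTA path or a named character vector")
  }
  structure(list(seq = seqs, lengths = nchar(seqs)), class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("<genome_store>", length(x$seq), "sequence(s),",
      sum(x$lengths), "bases\n")
  invisible(x)
}

#' Write a genome store to FASTA
#'
#' Case-preserving (soft-masking survives a write/read round trip).
#'
#' @param genome a \code{genome_store}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome$seq), path)
  invisible(path)
}

#' Fetch a masked subsequence
#'
#' Coordinates are 0-based half-open. Requests beyond the chromosome ends
#' are clipped (with a logged note), never an error; an empty interval gives
#' an empty sequence.
#'
#' @param genome a \code{genome_store}.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return a \code{masked_seq}: list with \code{chrom}, \code{start},
#'   \code{end} (the clipped interval) and \code{seq}.
#' @export
fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  s <- max(0L, as.integer(start)); e <- min(L, as.integer(end))
  if (s != start || e != end) {
    log_note("fetch clipped [", start, ",", end, ") to [", s, ",", e,
             ") on ", chrom)
  }
  if (e < s) e <- s
  structure(list(chrom = chrom, start = s, end = e,
                 seq = substr0(genome$seq[[chrom]], s, e)),
            class = "masked_seq")
}

#' @export
print.masked_seq <- function(x, ...) {
  cat("<masked_seq>", x$chrom, paste0("[", x$start, ",", x$end, ")"),
      x$end - x$start, "bases\n")
  invisible(x)
}

#' Extract a target region: focus feature plus flanks
#'
#' The design unit of the pipeline: an exon or exon projection extended by
#' \code{flank_size} on both sides, clipped to the chromosome.
#'
#' @param genome a \code{genome_store}.
#' @param chrom chromosome name.
#' @param focus_start,focus_end 0-based half-open focus interval.
#' @param flank_size flank added on each side (default 3000 nt).
#' @return a \code{target_region}: list with \code{chrom},
#'   \code{focus_start}, \code{focus_end}, \code{start}, \code{end},
#'   \code{seq}.
#' @export
target_region <- function(genome, chrom, focus_start, focus_end,
                          flank_size = 3000L) {
  ms <- fetch(genome, chrom, focus_start - flank_size, focus_end + flank_size)
  structure(list(chrom = chrom,
                 focus_start = as.integer(focus_start),
                 focus_end = as.integer(focus_end),
                 start = ms$start, end = ms$end, seq = ms$seq),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat("<target_region>", x$chrom, paste0("[", x$start, ",", x$end, ")"),
      "focus", paste0("[", x$focus_start, ",", x$focus_end, ")"), "\n")
  invisible(x)
}

#' Repeat-masked fraction of a sequence
#'
#' Fraction of positions that are soft-masked (lowercase) or hard-masked (N
#' or n). Undefined (an error) on empty input.
#'
#' @param seq character string, or a \code{masked_seq}.
#' @return fraction in [0, 1].
#' @examples
#' repeat_fraction("acgtACGT")  # 0.5
#' @export
repeat_fraction <- function(seq) {
  if (inherits(seq, "masked_seq")) seq <- seq$seq
  n <- nchar(seq)
  if (n == 0) stop("repeat_fraction: empty sequence")
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(x %in% c("a", "c", "g", "t", "n", "N")) / n
}

# 0/1 mask vector (repeat or N) for a region sequence; internal
.mask_vector <- function(seq) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  as.integer(x %in% c("a", "c", "g", "t", "n", "N"))
}
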