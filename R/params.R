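# Design parameters and configuration files.

#' Homology-arm design parameters
#'
#' Bundles every tunable of the arm-generation and scenario-design pipeline.
#' Defaults are the pipeline's production settings: a 1300 nt sliding window
#' (larger than the maximum arm, smaller than two minimum arms), 50 nt step,
#' 50 retained pairs per window and size range, product size ranges tiling
#' 700-1200 bp in 50 bp increments, 18-30 nt primers, mononucleotide runs
#' capped at 3, at most 25% repeat-masked sequence per arm, and 3 kb target
#' flanks.
#'
#' @param sw sliding-window size (nt).
#' @param ss window step size (nt).
#' @param npp primer pairs retained per window and size range.
#' @param size_min,size_max product (arm) length bounds (bp), tiled into
#'   \code{bin_width} bins.
#' @param bin_width width of each product size range (bp).
#' @param primer_len length-2 integer vector, primer length bounds.
#' @param max_monorun longest allowed mononucleotide run in a primer.
#' @param max_product_repeat_fraction maximum repeat-masked fraction of an
#'   arm.
#' @param flank_size flank added on each side of a target feature (nt).
#' @param max_gap maximum (exclusive) gap between paired arms (nt).
#' @param span_margin minimum distance between a span-arm end and the target
#'   exon border (nt).
#' @param whole_exon_max_len largest exon considered for whole-exon excision
#'   (bp).
#' @param cluster_eps DBSCAN epsilon (Chebyshev, nt) for arm clustering.
#' @param cluster_min_pts DBSCAN minimum neighbourhood size; 1 keeps every
#'   arm (no noise points).
#' @param end_tolerance per-end coordinate tolerance when grouping similar
#'   scenarios (nt).
#' @param max_scenarios scenarios kept per category (LS/SR, or knock-out
#'   mode) per exon.
#' @return an object of class \code{design_params}.
#' @examples
#' p <- design_params(ss = 25)
#' p$size_bins
#' @export
design_params <- function(sw = 1300L, ss = 50L, npp = 50L,
                          size_min = 700L, size_max = 1200L, bin_width = 50L,
                          primer_len = c(18L, 30L), max_monorun = 3L,
                          max_product_repeat_fraction = 0.25,
                          flank_size = 3000L, max_gap = 700L,
                          span_margin = 20L, whole_exon_max_len = 700L,
                          cluster_eps = 50, cluster_min_pts = 1L,
                          end_tolerance = 5L, max_scenarios = 5L) {
  p <- list(sw = as.integer(sw), ss = as.integer(ss), npp = as.integer(npp),
            size_min = as.integer(size_min), size_max = as.integer(size_max),
            bin_width = as.integer(bin_width),
            primer_len = as.integer(primer_len),
            max_monorun = as.integer(max_monorun),
            max_product_repeat_fraction = max_product_repeat_fraction,
            flank_size = as.integer(flank_size), max_gap = as.integer(max_gap),
            span_margin = as.integer(span_margin),
            whole_exon_max_len = as.integer(whole_exon_max_len),
            cluster_eps = as.numeric(cluster_eps),
            cluster_min_pts = as.integer(cluster_min_pts),
            end_tolerance = as.integer(end_tolerance),
            max_scenarios = as.integer(max_scenarios))
  check_that(
    "ss must be >= 1" = p$ss >= 1L,
    "npp must be >= 1" = p$npp >= 1L,
    "sw must exceed the maximum product size" = p$sw > p$size_max,
    "size bounds must satisfy 0 < size_min <= size_max" =
      p$size_min > 0L && p$size_min <= p$size_max,
    "primer_len must be two increasing positive integers" =
      length(p$primer_len) == 2L && p$primer_len[1] > 0L &&
      p$primer_len[1] <= p$primer_len[2],
    "max_product_repeat_fraction must be in [0,1]" =
      p$max_product_repeat_fraction >= 0 && p$max_product_repeat_fraction <= 1,
    "cluster_eps must be > 0" = p$cluster_eps > 0,
    "cluster_min_pts must be >= 1" = p$cluster_min_pts >= 1L
  )
  # product size ranges: half-open 50 bp bins, last bin closed at size_max
  lo <- seq(p$size_min, p$size_max - 1L, by = p$bin_width)
  hi <- pmin(lo + p$bin_width - 1L, p$size_max)
  hi[length(hi)] <- p$size_max
  p$size_bins <- cbind(lo = lo, hi = hi)
  class(p) <- "design_params"
  p
}

#' @export
print.design_params <- function(x, ...) {
  cat("<design_params>\n")
  cat("  window/step/pairs (SW/SS/NPP):", x$sw, "/", x$ss, "/", x$npp, "\n")
  cat("  arm size:", x$size_min, "-", x$size_max, "bp in",
      nrow(x$size_bins), "bins\n")
  cat("  primers:", x$primer_len[1], "-", x$primer_len[2],
      "nt, mono-run <=", x$max_monorun, "\n")
  cat("  repeat fraction <=", x$max_product_repeat_fraction,
      "; flank", x$flank_size, "nt; gap <", x$max_gap, "\n")
  invisible(x)
}

#' Read design parameters from a YAML config file
#'
#' Any field of \code{\link{design_params}} may be set in the file; unnamed
#' fields keep their defaults. Overrides passed as \code{...} (e.g. from CLI
#' flags) take precedence over the file.
#'
#' @param path YAML file, or \code{NULL} for defaults only.
#' @param ... named overrides of individual parameters.
#' @return a \code{design_params} object.
#' @export
read_params <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    allowed <- names(formals(design_params))
    bad <- setdiff(names(vals), allowed)
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(design_params, vals)
}
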