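# Homology-arm enumeration: sliding windows, filtering, per-gene arm store,
# coverage statistics and the SS x NPP optimisation sweep.

#' Sliding windows over a region
#'
#' Offsets 0, ss, 2*ss, ... while \code{offset + sw <= region_len}. A region
#' shorter than the window yields one window covering the whole region. If a
#' remainder is left at the region end, one final window anchored at the end
#' is appended so region tails are never systematically uncovered.
#'
#' @param region_len region length (nt).
#' @param sw window size (nt).
#' @param ss step size (nt).
#' @return data frame with columns \code{offset}, \code{size} (0-based).
#' @examples
#' windows(1400, 1300, 50)
#' @export
windows <- function(region_len, sw, ss) {
  region_len <- as.integer(region_len); sw <- as.integer(sw); ss <- as.integer(ss)
  stopifnot(region_len >= 1, sw >= 1, ss >= 1)
  if (region_len <= sw) {
    return(data.frame(offset = 0L, size = region_len))
  }
  offs <- seq.int(0L, region_len - sw, by = ss)
  tail_off <- region_len - sw
  if (offs[length(offs)] != tail_off) offs <- c(offs, tail_off)
  data.frame(offset = offs, size = sw)
}

#' Filter primer pairs into homology arms
#'
#' Applies the three arm filters to engine output: (i) no primer base may be
#' repeat-masked or N, (ii) no mononucleotide run longer than
#' \code{params$max_monorun} in either primer (checked on the primer as
#' synthesized, 5' to 3'), (iii) the product may contain at most
#' \code{params$max_product_repeat_fraction} repeat-masked sequence (25%
#' exactly is kept). Survivors are annotated with their repeat fraction and
#' primer sequences.
#'
#' @param pairs data frame of primer pairs in 0-based region coordinates
#'   (as from \code{\link{design_in_window}}, possibly shifted).
#' @param region_seq the soft-masked region sequence the coordinates refer
#'   to.
#' @param params a \code{design_params}.
#' @return data frame of homology arms (subset of \code{pairs} plus
#'   \code{length}, \code{repeat_fraction}, \code{fwd_seq}, \code{rev_seq}).
#' @export
filter_pairs <- function(pairs, region_seq, params = design_params()) {
  if (!nrow(pairs)) {
    pairs$length <- integer(0); pairs$repeat_fraction <- numeric(0)
    pairs$fwd_seq <- character(0); pairs$rev_seq <- character(0)
    return(pairs)
  }
  cmask <- c(0L, cumsum(.mask_vector(region_seq)))
  mask_free <- function(s, e) (cmask[e + 1L] - cmask[s + 1L]) == 0L
  fwd_seq <- substring(region_seq, pairs$fwd_start + 1L, pairs$fwd_end)
  rev_seq <- revcomp(substring(region_seq, pairs$rev_start + 1L, pairs$rev_end))
  run_re <- sprintf("([ACGTacgt])\\1{%d,}", params$max_monorun)
  rf <- (cmask[pairs$end + 1L] - cmask[pairs$start + 1L]) /
    (pairs$end - pairs$start)
  keep <- mask_free(pairs$fwd_start, pairs$fwd_end) &
    mask_free(pairs$rev_start, pairs$rev_end) &
    !grepl("[Nn]", fwd_seq) & !grepl("[Nn]", rev_seq) &
    !grepl(run_re, fwd_seq, perl = TRUE) & !grepl(run_re, rev_seq, perl = TRUE) &
    rf <= params$max_product_repeat_fraction
  out <- pairs[keep, , drop = FALSE]
  out$length <- out$end - out$start
  out$repeat_fraction <- rf[keep]
  out$fwd_seq <- fwd_seq[keep]
  out$rev_seq <- rev_seq[keep]
  rownames(out) <- NULL
  out
}

ARM_COLS <- c("chrom", "start", "end", "length", "penalty", "repeat_fraction",
              "fwd_start", "fwd_end", "rev_start", "rev_end",
              "fwd_seq", "rev_seq", "window_offset", "bin_lo", "pair_rank")

#' Coerce a data frame to an arm store
#'
#' Validates the column set and invariants of a homology-arm table. Mostly
#' useful for constructing hand-placed arm sets in tests and examples.
#'
#' @param df data frame with at least \code{chrom, start, end, penalty}.
#' @param gene_id gene the store belongs to.
#' @param params design parameters used for invariant checks.
#' @param check validate arm-length bounds (disable for deliberately
#'   out-of-spec fixtures).
#' @return an \code{arm_store} (data frame subclass).
#' @export
as_arm_store <- function(df, gene_id = NA_integer_, params = design_params(),
                         check = TRUE) {
  for (col in setdiff(ARM_COLS, names(df))) {
    val <- switch(col,
      length = df$end - df$start,
      repeat_fraction = 0,
      fwd_start = df$start, fwd_end = pmin(df$start + 20L, df$end),
      rev_start = pmax(df$end - 20L, df$start), rev_end = df$end,
      fwd_seq = "", rev_seq = "",
      window_offset = NA_integer_, bin_lo = NA_integer_, pair_rank = NA_integer_,
      penalty = 0)
    df[[col]] <- rep(val, length.out = nrow(df))
  }
  df <- df[, ARM_COLS]
  if (check && nrow(df)) {
    check_that(
      "arm length out of bounds" =
        df$length >= params$size_min & df$length <= params$size_max,
      "repeat fraction above threshold" =
        df$repeat_fraction <= params$max_product_repeat_fraction,
      "forward primer must precede reverse primer" = df$fwd_end <= df$rev_start
    )
  }
  df <- df[order(df$start, df$end, df$fwd_end, df$rev_start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, gene_id = gene_id, no_arms = nrow(df) == 0L,
            class = c("arm_store", "data.frame"))
}

#' Build the homology-arm database of a gene
#'
#' Runs the primer engine over every window and product size range of every
#' target region of the gene, applies the arm filters, and deduplicates:
#' pairs with identical forward and reverse genomic intervals collapse to
#' one arm keeping the lowest penalty. Genes whose neighbourhood yields no
#' arm are flagged (\code{attr(store, "no_arms")}).
#'
#' @param gene_id integer GeneID (recorded on the store).
#' @param regions list of \code{\link{target_region}} objects.
#' @param params a \code{design_params}.
#' @param engine a \code{primer_engine}.
#' @return an \code{arm_store}: data frame of arms in genomic coordinates,
#'   sorted by interval, with primer coordinates/sequences, penalty, repeat
#'   fraction and provenance columns (\code{window_offset}, \code{bin_lo},
#'   \code{pair_rank} = rank within its window and size range).
#' @export
build_arm_database <- function(gene_id, regions, params = design_params(),
                               engine = builtin_engine()) {
  occ <- .arm_occurrences(regions, params, engine)
  if (is.null(occ) || !nrow(occ)) {
    log_note("gene ", gene_id, ": no suitable primer pairs")
    return(as_arm_store(data.frame(chrom = character(), start = integer(),
                                   end = integer(), penalty = numeric()),
                        gene_id = gene_id, params = params))
  }
  as_arm_store(.dedupe_occurrences(occ), gene_id = gene_id, params = params)
}

# dedupe filtered occurrences on the primer-interval quadruple, keeping the
# lowest penalty (first window in reading order among ties)
.dedupe_occurrences <- function(occ) {
  key <- occ$pair_key %||% paste(occ$chrom, occ$fwd_start, occ$fwd_end,
                                 occ$rev_start, occ$rev_end, sep = ":")
  ord <- order(occ$penalty, occ$start, occ$end, occ$window_offset, occ$bin_lo)
  occ <- occ[ord, , drop = FALSE]
  occ[!duplicated(key[ord]), , drop = FALSE]
}

# every filtered primer pair from every window and size range of the
# regions, with provenance (window offset, size bin, within-call rank), in
# genomic coordinates; one row per (pair, window, bin) occurrence
.arm_occurrences <- function(regions, params, engine) {
  acc <- list(); k <- 0L
  for (ri in seq_along(regions)) {
    reg <- regions[[ri]]
    rlen <- nchar(reg$seq)
    if (rlen < params$size_min) next
    ctx <- tryCatch(engine$prepare(reg$seq, params), error = function(e) {
      log_note("engine failure on region (skipped): ", conditionMessage(e))
      NULL
    })
    if (is.null(ctx)) next
    win <- windows(rlen, params$sw, params$ss)
    for (wi in seq_len(nrow(win))) {
      ms <- tryCatch({
        if (is.function(engine$design_bins)) {
          engine$design_bins(ctx, win$offset[wi], win$size[wi],
                             params$size_bins, params$npp, params)
        } else {
          lapply(seq_len(nrow(params$size_bins)), function(bi)
            engine$design(ctx, win$offset[wi], win$size[wi],
                          params$size_bins[bi, "lo"],
                          params$size_bins[bi, "hi"], params$npp, params))
        }
      }, error = function(e) {
        log_note("engine failure in window (skipped): ", conditionMessage(e))
        NULL
      })
      if (is.null(ms)) next
      for (bi in seq_along(ms)) {
        m <- ms[[bi]]
        if (is.null(m) || !nrow(m)) next
        k <- k + 1L
        acc[[k]] <- cbind(m, region_index = ri,
                          window_offset = win$offset[wi],
                          bin_lo = params$size_bins[bi, "lo"],
                          pair_rank = seq_len(nrow(m)))
      }
    }
  }
  if (!k) return(NULL)
  m <- do.call(rbind, acc)
  df <- as.data.frame(m[, PAIR_COLS, drop = FALSE])
  df$region_index <- as.integer(m[, "region_index"])
  df$window_offset <- as.integer(m[, "window_offset"])
  df$bin_lo <- as.integer(m[, "bin_lo"])
  df$pair_rank <- as.integer(m[, "pair_rank"])

  # filter per region (coordinates are region-local until here), then shift
  # to genomic coordinates. The filter verdict depends only on the pair, so
  # it is computed once per unique primer quadruple and mapped back to the
  # (heavily overlapping) window occurrences.
  parts <- lapply(split(df, df$region_index), function(d) {
    reg <- regions[[d$region_index[1]]]
    key <- paste(d$fwd_start, d$fwd_end, d$rev_start, d$rev_end)
    uniq <- d[!duplicated(key), , drop = FALSE]
    passed <- filter_pairs(uniq, reg$seq, params)
    m <- match(key, paste(passed$fwd_start, passed$fwd_end,
                          passed$rev_start, passed$rev_end))
    out <- d[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    out$length <- passed$length[m]
    out$repeat_fraction <- passed$repeat_fraction[m]
    out$fwd_seq <- passed$fwd_seq[m]
    out$rev_seq <- passed$rev_seq[m]
    if (nrow(out)) {
      for (col in c("fwd_start", "fwd_end", "rev_start", "rev_end",
                    "start", "end")) {
        out[[col]] <- as.integer(out[[col]]) + reg$start
      }
      out$chrom <- reg$chrom
      out$pair_key <- paste(out$chrom, out$fwd_start, out$fwd_end,
                            out$rev_start, out$rev_end, sep = ":")
    } else out$pair_key <- character(0)
    out
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  if (!nrow(df)) return(NULL)
  df
}

#' @export
print.arm_store <- function(x, ...) {
  cat("<arm_store> gene", attr(x, "gene_id"), "-", nrow(x), "arms")
  if (isTRUE(attr(x, "no_arms"))) cat(" [no suitable primer pairs]")
  cat("\n")
  if (nrow(x)) utils::str(as.data.frame(x)[1:min(3, nrow(x)), 1:6])
  invisible(x)
}

#' Coverage statistics of an arm store over a target interval
#'
#' \code{sequence_coverage} is the fraction of target bases inside at least
#' one arm; \code{average_depth} the mean per-base arm count;
#' \code{average_penalty} the mean pair penalty of the arms (reported as
#' \code{NA}, not 0, for an empty store); \code{depth_per_penalty} their
#' ratio, the quality-adjusted depth used to tune SS and NPP.
#'
#' @param arms an \code{arm_store} (or arm data frame).
#' @param target_start,target_end 0-based half-open target interval.
#' @return list with \code{sequence_coverage}, \code{average_depth},
#'   \code{average_penalty}, \code{depth_per_penalty}, \code{n_arms}.
#' @export
coverage_stats <- function(arms, target_start, target_end) {
  len <- as.integer(target_end) - as.integer(target_start)
  stopifnot(len > 0)
  if (!nrow(arms)) {
    return(list(sequence_coverage = 0, average_depth = 0,
                average_penalty = NA_real_, depth_per_penalty = NA_real_,
                n_arms = 0L))
  }
  s <- pmax(as.integer(arms$start), as.integer(target_start)) - as.integer(target_start)
  e <- pmin(as.integer(arms$end), as.integer(target_end)) - as.integer(target_start)
  ok <- e > s
  delta <- integer(len + 1L)
  if (any(ok)) {
    add <- tabulate(s[ok] + 1L, nbins = len + 1L)
    sub <- tabulate(e[ok] + 1L, nbins = len + 1L)
    delta <- add - sub
  }
  depth <- cumsum(delta)[seq_len(len)]
  pen <- mean(arms$penalty)
  list(sequence_coverage = mean(depth > 0),
       average_depth = mean(depth),
       average_penalty = pen,
       depth_per_penalty = if (pen > 0) mean(depth) / pen else NA_real_,
       n_arms = nrow(arms))
}

#' Coverage statistics across a grid of SS and NPP values
#'
#' Computes the full grid from a single engine run at the finest step size
#' and largest NPP: because the engine is deterministic, window sets at a
#' coarser step (a multiple of the finest) are a subset of the fine window
#' set, and the top-k pairs of a window are the first k of its top-N list.
#' The derived grid is therefore identical to running each combination
#' independently (asserted in the test suite).
#'
#' @param gene_id gene label for the store.
#' @param regions list of \code{\link{target_region}} objects.
#' @param targets data frame with \code{start}, \code{end}: the focus
#'   intervals over which coverage is measured.
#' @param ss_values step sizes; every value must be a multiple of the
#'   smallest.
#' @param npp_values NPP values.
#' @param params base \code{design_params}.
#' @param engine a \code{primer_engine}.
#' @return data frame with one row per (ss, npp) combination and the
#'   \code{\link{coverage_stats}} columns.
#' @export
coverage_sweep <- function(gene_id, regions, targets,
                           ss_values = c(25, 50, 100),
                           npp_values = c(5, 10, 25, 50),
                           params = design_params(), engine = builtin_engine()) {
  ss_values <- sort(as.integer(ss_values)); npp_values <- sort(as.integer(npp_values))
  if (any(ss_values %% ss_values[1] != 0)) {
    stop("every ss value must be a multiple of the smallest")
  }
  base <- design_params_update(params, ss = ss_values[1], npp = max(npp_values))
  occ <- .arm_occurrences(regions, base, engine)
  grid <- expand.grid(ss = ss_values, npp = npp_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- grid$ss[i]; npp <- grid$npp[i]
    if (is.null(occ)) {
      stats <- aggregate_coverage(
        as_arm_store(data.frame(chrom = character(), start = integer(),
                                end = integer(), penalty = numeric()),
                     params = params), targets)
      return(cbind(grid[i, ], as.data.frame(stats)))
    }
    ok <- occ$pair_rank <= npp
    for (ri in seq_along(regions)) {
      in_reg <- occ$region_index == ri
      win <- windows(nchar(regions[[ri]]$seq), params$sw, ss)
      ok[in_reg] <- ok[in_reg] & occ$window_offset[in_reg] %in% win$offset
    }
    sub <- .dedupe_occurrences(occ[ok, , drop = FALSE])
    stats <- aggregate_coverage(sub, targets)
    cbind(grid[i, ], as.data.frame(stats))
  })
  do.call(rbind, res)
}

# pooled coverage over several target intervals (base-weighted)
aggregate_coverage <- function(arms, targets) {
  per <- lapply(seq_len(nrow(targets)), function(i)
    coverage_stats(arms, targets$start[i], targets$end[i]))
  w <- targets$end - targets$start
  cov <- sum(vapply(per, `[[`, 0, "sequence_coverage") * w) / sum(w)
  dep <- sum(vapply(per, `[[`, 0, "average_depth") * w) / sum(w)
  pen <- mean(arms$penalty)
  list(sequence_coverage = cov, average_depth = dep,
       average_penalty = if (nrow(arms)) pen else NA_real_,
       depth_per_penalty = if (nrow(arms) && pen > 0) dep / pen else NA_real_,
       n_arms = nrow(arms))
}

# modify selected fields of a design_params, revalidating
design_params_update <- function(params, ...) {
  over <- list(...)
  vals <- unclass(params)
  vals$size_bins <- NULL
  vals$primer_len <- params$primer_len
  vals[names(over)] <- over
  do.call(design_params, vals[names(formals(design_params))])
}
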