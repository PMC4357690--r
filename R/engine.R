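# Built-in primer-design engine.
#
# The engine contract: an object of class "primer_engine" with two function
# fields,
#   prepare(seq, params)                      -> opaque context
#   design(ctx, offset, size, lo, hi, npp, params) -> numeric matrix of pairs
# where `seq` is the (soft-masked) region sequence, `offset`/`size` delimit a
# window in 0-based region coordinates, and [lo, hi] is an inclusive product
# length range. The matrix columns are
#   fwd_start fwd_end rev_start rev_end start end penalty fwd_tm rev_tm
# all intervals 0-based half-open in region coordinates, at most `npp` rows,
# ranked by pair penalty. Any engine honouring this contract (e.g. a wrapper
# around an external primer designer) can be passed wherever an `engine`
# argument appears.
#
# The built-in engine scores one best primer per start (forward) and per end
# (reverse) position: candidate primers of length 18-30 are rejected if any
# base is repeat-masked or N or if they contain a mononucleotide run longer
# than 3; survivors are scored by |Tm - 60| + |length - 20| and pairs by the
# sum of primer penalties plus 0.1 * |Tm_fwd - Tm_rev|. Deterministic ties
# are broken by shorter primer, then leftmost coordinates.

PAIR_COLS <- c("fwd_start", "fwd_end", "rev_start", "rev_end",
               "start", "end", "penalty", "fwd_tm", "rev_tm")

#' Built-in deterministic primer engine
#'
#' Constructs the package's native primer-design engine: nearest-neighbor
#' melting-temperature scoring (optimum 60 degC) with a primer-length
#' optimum of 20 nt, hard constraints of 18-30 nt primer length, no
#' repeat-masked or N base in a primer, and no mononucleotide run longer
#' than 3. Fully deterministic: identical sequence and parameters give
#' identical output.
#'
#' @param opt_tm optimal primer melting temperature (degrees Celsius).
#' @param opt_len optimal primer length (nt).
#' @param wt_len weight of the length deviation in the primer penalty.
#' @param wt_tm_diff weight of the forward/reverse Tm difference in the
#'   pair penalty.
#' @return an object of class \code{primer_engine}.
#' @examples
#' eng <- builtin_engine()
#' p <- design_params()
#' seq <- paste(rep("ACGTTGCAGTCAGGTCAATGCTAGCAATCGCAT", 40), collapse = "")
#' pairs <- design_in_window(seq, c(700, 749), npp = 5, engine = eng, params = p)
#' @export
builtin_engine <- function(opt_tm = 60, opt_len = 20, wt_len = 1, wt_tm_diff = 0.1) {
  structure(list(
    name = "builtin",
    opt_tm = opt_tm, opt_len = opt_len, wt_len = wt_len, wt_tm_diff = wt_tm_diff,
    prepare = function(seq, params) .builtin_prepare(seq, params, opt_tm, opt_len, wt_len),
    design = function(ctx, offset, size, lo, hi, npp, params)
      .builtin_design(ctx, offset, size, lo, hi, npp, wt_tm_diff),
    # optional fast path: all size bins of one window in a single pass;
    # output identical to bin-wise design() calls
    design_bins = function(ctx, offset, size, bins, npp, params)
      .builtin_design_bins(ctx, offset, size, bins, npp, wt_tm_diff)
  ), class = "primer_engine")
}

#' @export
print.primer_engine <- function(x, ...) {
  cat("<primer_engine>", x$name, "\n")
  invisible(x)
}

# Per-position candidate tables for one region.
# Forward table F is indexed by primer start, reverse table R by primer end
# (both 1-based internally); each holds the best valid primer length and its
# penalty/Tm. Reverse primers are scored on the genomic (plus) strand segment:
# the nearest-neighbor duplex Tm, the masked-base and N constraints and the
# mononucleotide-run constraint are all strand-symmetric.
.builtin_prepare <- function(seq, params, opt_tm, opt_len, wt_len) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  up <- toupper(x)
  code <- match(up, .NN_BASES)                      # NA for N / other
  masked <- x %in% c("a", "c", "g", "t", "n") | up == "N"
  bad <- masked | is.na(code)
  cb <- c(0, cumsum(bad))
  # positions starting a 4-mononucleotide run
  if (n >= 4) {
    b4 <- up[1:(n - 3)] == up[2:(n - 2)] & up[2:(n - 2)] == up[3:(n - 1)] &
      up[3:(n - 1)] == up[4:n]
  } else b4 <- logical(0)
  c4 <- c(0, cumsum(b4))
  # NN step sums (invalid steps contribute 0; such primers are dropped via `bad`)
  if (n >= 2) {
    idx <- (code[-n] - 1L) * 4L + code[-1L]
    dh <- .NN_DH[idx]; dh[is.na(dh)] <- 0
    ds <- .NN_DS[idx]; ds[is.na(ds)] <- 0
  } else dh <- ds <- numeric(0)
  cdh <- c(0, cumsum(dh)); cds <- c(0, cumsum(ds))
  at <- code %in% c(1L, 4L)                          # terminal A/T
  denom_k <- .TM_R * log(.TM_DNAC)

  lens <- params$primer_len[1]:params$primer_len[2]
  Fpen <- Rpen <- rep(NA_real_, n)
  Flen <- Rlen <- rep(NA_integer_, n)
  Ftm <- Rtm <- rep(NA_real_, n)
  for (l in lens) {
    if (l > n) break
    s <- seq_len(n - l + 1L)                         # 1-based starts
    e <- s + l - 1L                                  # 1-based ends
    ok <- (cb[e + 1L] - cb[s]) == 0
    if (l >= 4L) ok <- ok & (c4[pmax(e - 3L, 1L)] - c4[s]) == 0
    if (!any(ok)) next
    ends_at <- at[s] + at[e]
    dH <- .TM_INIT_DH + (cdh[e] - cdh[s]) + .TM_AT_DH * ends_at
    dS <- .TM_INIT_DS + (cds[e] - cds[s]) + .TM_AT_DS * ends_at +
      0.368 * (l - 1) * log(.TM_NA)
    # round to 1e-6 degC: keeps penalty comparisons and tie-breaks stable
    # against cumulative-sum floating noise (position independence)
    tm <- round(1000 * dH / (dS + denom_k) - 273.15, 6L)
    pen <- round(abs(tm - opt_tm) + wt_len * abs(l - opt_len), 6L)
    pen[!ok] <- NA_real_
    upd <- ok & (is.na(Fpen[s]) | pen < Fpen[s])
    if (any(upd)) {
      su <- s[upd]
      Fpen[su] <- pen[upd]; Flen[su] <- l; Ftm[su] <- tm[upd]
    }
    upd <- ok & (is.na(Rpen[e]) | pen < Rpen[e])
    if (any(upd)) {
      eu <- e[upd]
      Rpen[eu] <- pen[upd]; Rlen[eu] <- l; Rtm[eu] <- tm[upd]
    }
  }
  list(n = n, Fpen = Fpen, Flen = Flen, Ftm = Ftm,
       Rpen = Rpen, Rlen = Rlen, Rtm = Rtm)
}

# All valid (start, end) product candidates with length in [lo, hi] inside
# the window; returns list(sm, jm, pen) of 1-based product start/end and
# pair penalty, unranked.
.builtin_candidates <- function(ctx, offset, size, lo, hi, wt_tm_diff) {
  w0 <- as.integer(offset)                           # 0-based window start
  wend <- w0 + as.integer(size)                      # 0-based exclusive end
  if (lo > size) return(NULL)
  hi <- min(hi, size)
  smin <- w0 + 1L                                    # 1-based product starts
  smax <- w0 + as.integer(size) - lo + 1L
  s_all <- smin:smax
  s_all <- s_all[!is.na(ctx$Fpen[s_all])]
  if (!length(s_all)) return(NULL)
  L <- lo:hi
  sm <- rep(s_all, each = length(L))
  jm <- sm + rep(L, times = length(s_all)) - 1L      # 1-based product ends
  keep <- jm <= wend & !is.na(ctx$Rpen[jm])
  if (!any(keep)) return(NULL)
  sm <- sm[keep]; jm <- jm[keep]
  pen <- round(ctx$Fpen[sm] + ctx$Rpen[jm] +
                 wt_tm_diff * abs(ctx$Ftm[sm] - ctx$Rtm[jm]), 6L)
  list(sm = sm, jm = jm, pen = pen)
}

.builtin_pair_matrix <- function(ctx, sm, jm, pen) {
  cbind(fwd_start = sm - 1L, fwd_end = sm - 1L + ctx$Flen[sm],
        rev_start = jm - ctx$Rlen[jm], rev_end = jm,
        start = sm - 1L, end = jm,
        penalty = pen, fwd_tm = ctx$Ftm[sm], rev_tm = ctx$Rtm[jm])
}

# Top-npp primer pairs with product length in [lo, hi] (inclusive) inside the
# window [offset, offset + size) of the prepared region.
.builtin_design <- function(ctx, offset, size, lo, hi, npp, wt_tm_diff) {
  cand <- .builtin_candidates(ctx, offset, size, lo, hi, wt_tm_diff)
  if (is.null(cand)) return(NULL)
  ord <- order(cand$pen, cand$sm, cand$jm)
  ord <- ord[seq_len(min(npp, length(ord)))]
  .builtin_pair_matrix(ctx, cand$sm[ord], cand$jm[ord], cand$pen[ord])
}

# One pass over every size bin of a window; returns list of matrices, one
# per bin (NULL entries for empty bins). Identical to bin-wise .builtin_design.
.builtin_design_bins <- function(ctx, offset, size, bins, npp, wt_tm_diff) {
  cand <- .builtin_candidates(ctx, offset, size, min(bins[, "lo"]),
                              max(bins[, "hi"]), wt_tm_diff)
  out <- vector("list", nrow(bins))
  if (is.null(cand)) return(out)
  len <- cand$jm - cand$sm + 1L
  bi <- findInterval(len, bins[, "lo"])
  # exclude lengths falling in gaps between non-contiguous bins
  bi[bi < 1L | len > bins[pmax(bi, 1L), "hi"]] <- NA_integer_
  for (b in seq_len(nrow(bins))) {
    sel <- which(bi == b)
    if (!length(sel)) next
    ord <- sel[order(cand$pen[sel], cand$sm[sel], cand$jm[sel])]
    ord <- ord[seq_len(min(npp, length(ord)))]
    out[[b]] <- .builtin_pair_matrix(ctx, cand$sm[ord], cand$jm[ord],
                                     cand$pen[ord])
  }
  out
}

#' Design primer pairs inside one window
#'
#' Runs a primer engine on a single window sequence and one product size
#' range, returning at most \code{npp} ranked pairs. Engine failures are
#' logged and yield an empty result, never an error.
#'
#' @param window_seq window sequence (soft-masked; lowercase/N = repeat).
#' @param size_range length-2 vector, inclusive product length range.
#' @param npp maximum number of pairs to retain.
#' @param engine a \code{primer_engine}.
#' @param params a \code{design_params} object.
#' @return data frame of primer pairs (0-based half-open window coordinates,
#'   columns \code{fwd_start, fwd_end, rev_start, rev_end, start, end,
#'   penalty, fwd_tm, rev_tm}), ranked by penalty.
#' @export
design_in_window <- function(window_seq, size_range, npp = 50,
                             engine = builtin_engine(), params = design_params()) {
  stopifnot(length(size_range) == 2, size_range[1] <= size_range[2])
  m <- tryCatch({
    ctx <- engine$prepare(window_seq, params)
    engine$design(ctx, 0L, nchar(window_seq), as.integer(size_range[1]),
                  as.integer(size_range[2]), as.integer(npp), params)
  }, error = function(e) {
    log_note("engine failure in window (skipped): ", conditionMessage(e))
    NULL
  })
  if (is.null(m)) m <- matrix(numeric(0), 0, length(PAIR_COLS),
                              dimnames = list(NULL, PAIR_COLS))
  as.data.frame(m)
}
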