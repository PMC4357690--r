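# Knock-in scenario design: span arms, flank candidates, cluster-cluster
# matching, similarity grouping and ranking.
#
# A knock-in scenario pairs an exon-spanning arm with a flanking arm on one
# side: category LS = left-arm:span-arm, SR = span-arm:right-arm. The
# selection cassette integrates at the split point, the junction between the
# gap and the span arm, so the split distance is the distance from that
# junction to the nearest border of the target exon.

SCENARIO_COLS <- c("gene_id", "feature_chrom", "feature_start", "feature_end",
                   "category",
                   "arm1_start", "arm1_end", "arm1_fwd_seq", "arm1_rev_seq",
                   "arm1_penalty",
                   "arm2_start", "arm2_end", "arm2_fwd_seq", "arm2_rev_seq",
                   "arm2_penalty",
                   "gap", "gap_start", "gap_end", "split_distance",
                   "cumulative_length", "rank")

#' Arms spanning a target exon
#'
#' Arms covering the whole exon with at least \code{span_margin} (default
#' 20) bases outside each border. An exon longer than
#' \code{size_max - 2 * span_margin} can have no span arm.
#'
#' @param arms arm data frame (genomic coordinates).
#' @param exon_start,exon_end 0-based half-open exon interval.
#' @param span_margin minimum margin (nt).
#' @return the spanning subset of \code{arms}.
#' @export
find_span_arms <- function(arms, exon_start, exon_end, span_margin = 20L) {
  arms[arms$start <= exon_start - span_margin &
         arms$end >= exon_end + span_margin, , drop = FALSE]
}

#' Flank-arm candidates for one span arm
#'
#' Left candidates end at or before the span start with a gap strictly below
#' \code{max_gap}; right candidates start at or after the span end,
#' symmetrically. Overlapping arms (negative gap) are excluded.
#'
#' @param arms arm data frame.
#' @param span_start,span_end span-arm interval.
#' @param side \code{"left"} or \code{"right"}.
#' @param max_gap exclusive gap bound (default 700 nt).
#' @return subset of \code{arms} with a \code{gap} column.
#' @export
candidate_flank_arms <- function(arms, span_start, span_end,
                                 side = c("left", "right"), max_gap = 700L) {
  side <- match.arg(side)
  if (side == "left") {
    gap <- span_start - arms$end
  } else {
    gap <- arms$start - span_end
  }
  keep <- gap >= 0L & gap < max_gap
  out <- arms[keep, , drop = FALSE]
  out$gap <- gap[keep]
  rownames(out) <- NULL
  out
}

# TRUE where position pos lies strictly inside any interval of `others`
.inside_any <- function(pos, others) {
  hit <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(others))) {
    hit <- hit | (pos > others$start[r] & pos < others$end[r])
  }
  hit
}

# screening shared by matching and the brute-force oracle: valid (span,
# flank) combinations for one exon. `others` = the gene's other exons.
.valid_pairs <- function(span, flank, side, exon_start, exon_end, others,
                         params) {
  ns <- nrow(span); nf <- nrow(flank)
  if (!ns || !nf) return(NULL)
  # arm-level exclusion first (terminus strictly inside another exon)
  if (nrow(others)) {
    span_ok <- !(.inside_any(span$start, others) | .inside_any(span$end, others))
    flank_ok <- !(.inside_any(flank$start, others) | .inside_any(flank$end, others))
  } else {
    span_ok <- rep(TRUE, ns); flank_ok <- rep(TRUE, nf)
  }
  si0 <- which(span_ok); fi0 <- which(flank_ok)
  if (!length(si0) || !length(fi0)) return(NULL)
  # expand only gap-feasible combinations: the flank's inner end must lie in
  # a max_gap-wide window at the span's near end (sorted lookup, not a full
  # cross product)
  if (side == "left") {
    fpos <- flank$end[fi0]          # gap = span.start - flank.end in [0, max_gap)
    spos <- span$start[si0]
  } else {
    fpos <- flank$start[fi0]        # gap = flank.start - span.end in [0, max_gap)
    spos <- span$end[si0]
  }
  fo <- order(fpos); fsort <- fpos[fo]
  if (side == "left") {
    hi <- findInterval(spos, fsort)                   # fpos <= span.start
    lo <- findInterval(spos - params$max_gap, fsort)  # fpos > span.start - max_gap
  } else {
    hi <- findInterval(spos + params$max_gap - 1L, fsort)  # fpos < span.end + max_gap
    lo <- findInterval(spos - 1L, fsort)                   # fpos >= span.end
  }
  cnt <- pmax(hi - lo, 0L)
  if (!sum(cnt)) return(NULL)
  si <- rep(si0, cnt)
  fi <- fi0[fo[sequence(cnt) + rep(lo, cnt)]]
  if (side == "left") {
    gap <- span$start[si] - flank$end[fi]
    gap_s <- flank$end[fi]; gap_e <- span$start[si]
    split <- exon_start - span$start[si]
  } else {
    gap <- flank$start[fi] - span$end[si]
    gap_s <- span$end[si]; gap_e <- flank$start[fi]
    split <- span$end[si] - exon_end
  }
  ok <- gap >= 0L & gap < params$max_gap & split >= params$span_margin
  # no other exon may intersect the gap
  if (nrow(others)) {
    for (r in seq_len(nrow(others))) {
      ok <- ok & !(others$start[r] < gap_e & gap_s < others$end[r])
    }
  }
  if (!any(ok)) return(NULL)
  # plain list, not data.frame: these can be millions of rows
  list(si = si[ok], fi = fi[ok], gap = gap[ok],
       gap_start = gap_s[ok], gap_end = gap_e[ok], split = split[ok])
}

.make_scenarios <- function(span, flank, pairs, side, gene_id, chrom,
                            exon_start, exon_end) {
  if (is.null(pairs) || !length(pairs$si)) return(empty_scenarios())
  s <- span[pairs$si, ]; f <- flank[pairs$fi, ]
  if (side == "left") { a1 <- f; a2 <- s } else { a1 <- s; a2 <- f }
  data.frame(
    gene_id = gene_id, feature_chrom = chrom,
    feature_start = exon_start, feature_end = exon_end,
    category = if (side == "left") "LS" else "SR",
    arm1_start = a1$start, arm1_end = a1$end,
    arm1_fwd_seq = a1$fwd_seq, arm1_rev_seq = a1$rev_seq,
    arm1_penalty = a1$penalty,
    arm2_start = a2$start, arm2_end = a2$end,
    arm2_fwd_seq = a2$fwd_seq, arm2_rev_seq = a2$rev_seq,
    arm2_penalty = a2$penalty,
    gap = pairs$gap, gap_start = pairs$gap_start, gap_end = pairs$gap_end,
    split_distance = pairs$split,
    cumulative_length = (a1$end - a1$start) + (a2$end - a2$start),
    rank = NA_integer_, stringsAsFactors = FALSE
  )
}

empty_scenarios <- function() {
  df <- data.frame(gene_id = integer(), feature_chrom = character(),
                   feature_start = integer(), feature_end = integer(),
                   category = character(),
                   arm1_start = integer(), arm1_end = integer(),
                   arm1_fwd_seq = character(), arm1_rev_seq = character(),
                   arm1_penalty = numeric(),
                   arm2_start = integer(), arm2_end = integer(),
                   arm2_fwd_seq = character(), arm2_rev_seq = character(),
                   arm2_penalty = numeric(),
                   gap = integer(), gap_start = integer(), gap_end = integer(),
                   split_distance = integer(), cumulative_length = integer(),
                   rank = integer(), stringsAsFactors = FALSE)
  df
}

#' Scenario ordering key
#'
#' Lexicographic scenario priority: smaller gap, then smaller split
#' distance, then larger cumulative arm length, then leftmost construct
#' start as the deterministic tie-break. Knock-out scenarios carry
#' \code{split_distance = 0}, reducing the key to gap, cumulative length,
#' position.
#'
#' @param scenarios scenario data frame.
#' @return integer permutation ordering the scenarios best-first.
#' @export
score_key <- function(scenarios) {
  order(scenarios$gap, scenarios$split_distance,
        -scenarios$cumulative_length, scenarios$arm1_start,
        scenarios$arm2_start)
}

#' Group similar scenarios and keep the best of each group
#'
#' Two scenarios are connected when they share an identical arm (same
#' interval in the same position) or when both corresponding arms differ by
#' at most \code{end_tolerance} bases at each end. Within every connected
#' component of the resulting undirected graph only the best scenario (by
#' \code{\link{score_key}}) survives.
#'
#' @param scenarios scenario data frame (one category of one exon).
#' @param end_tolerance per-end similarity tolerance (nt).
#' @return the surviving subset, ordered best-first.
#' @export
group_similar <- function(scenarios, end_tolerance = 5L) {
  n <- nrow(scenarios)
  if (n <= 1L) return(scenarios)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  near <- function(s1, e1, s2, e2, tol)
    abs(s1 - s2) <= tol & abs(e1 - e2) <= tol
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    identical_arm <-
      (scenarios$arm1_start[i] == scenarios$arm1_start[j] &
         scenarios$arm1_end[i] == scenarios$arm1_end[j]) |
      (scenarios$arm2_start[i] == scenarios$arm2_start[j] &
         scenarios$arm2_end[i] == scenarios$arm2_end[j])
    similar_both <-
      near(scenarios$arm1_start[i], scenarios$arm1_end[i],
           scenarios$arm1_start[j], scenarios$arm1_end[j], end_tolerance) &
      near(scenarios$arm2_start[i], scenarios$arm2_end[i],
           scenarios$arm2_start[j], scenarios$arm2_end[j], end_tolerance)
    for (k in j[identical_arm | similar_both]) union_(i, k)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ord <- score_key(scenarios)
  best <- ord[!duplicated(comp[ord])]
  out <- scenarios[sort(best), , drop = FALSE]
  out <- out[score_key(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match span and flank clusters into candidate scenarios
#'
#' Every arm of every span cluster is screened against every arm of every
#' flank cluster (gap in [0, max_gap), no other exon of the gene inside the
#' gap, no arm terminus strictly inside another exon, split distance at
#' least the span margin); exactly the single best surviving candidate per
#' cluster pair (by \code{\link{score_key}}) is retained.
#'
#' @param span_arms clustered span arms (from \code{\link{cluster_arms}}).
#' @param flank_arms clustered flank arms.
#' @param side \code{"left"} or \code{"right"}.
#' @param gene_id,chrom scenario annotation.
#' @param exon_start,exon_end target exon interval.
#' @param other_exons data frame of the gene's other exons (\code{start},
#'   \code{end}).
#' @param params a \code{design_params}.
#' @return scenario data frame, one row per productive cluster pair.
#' @export
match_clusters <- function(span_arms, flank_arms, side, gene_id, chrom,
                           exon_start, exon_end, other_exons,
                           params = design_params()) {
  pairs <- .valid_pairs(span_arms, flank_arms, side, exon_start, exon_end,
                        other_exons, params)
  if (is.null(pairs) || !length(pairs$si)) return(empty_scenarios())
  # single best candidate per (span cluster, flank cluster), by score order
  ncl_f <- max(flank_arms$cluster)
  key <- (span_arms$cluster[pairs$si] - 1L) * ncl_f +
    flank_arms$cluster[pairs$fi]
  cum <- (span_arms$end[pairs$si] - span_arms$start[pairs$si]) +
    (flank_arms$end[pairs$fi] - flank_arms$start[pairs$fi])
  a1s <- if (side == "left") flank_arms$start[pairs$fi] else
    span_arms$start[pairs$si]
  a2s <- if (side == "left") span_arms$start[pairs$si] else
    flank_arms$start[pairs$fi]
  ord <- order(pairs$gap, pairs$split, -cum, a1s, a2s)
  best <- ord[!duplicated(key[ord])]
  best <- best[order(key[best])]
  res <- .make_scenarios(span_arms, flank_arms, lapply(pairs, `[`, best),
                         side, gene_id, chrom, exon_start, exon_end)
  rownames(res) <- NULL
  res
}

#' Design knock-in scenarios for one exon or exon projection
#'
#' Full per-feature pipeline: span-arm identification, DBSCAN clustering of
#' span/left/right arms, cluster-cluster matching (LS and SR separately),
#' similarity grouping, ranking by \code{\link{score_key}}, and the cap of
#' \code{params$max_scenarios} per category (at most 10 scenarios total with
#' the default 5).
#'
#' @param gene_id gene the feature belongs to.
#' @param chrom chromosome.
#' @param exon_start,exon_end target feature interval (0-based half-open).
#' @param arms \code{arm_store} of the gene.
#' @param other_exons data frame (\code{start}, \code{end}) of the gene's
#'   other exons, used by the exclusion rules; the target feature itself
#'   must not be listed.
#' @param params a \code{design_params}.
#' @return scenario data frame with final per-category ranks; zero rows when
#'   no span arm or no valid pair exists.
#' @export
design_knockin <- function(gene_id, chrom, exon_start, exon_end, arms,
                           other_exons = data.frame(start = integer(),
                                                    end = integer()),
                           params = design_params()) {
  span <- find_span_arms(arms, exon_start, exon_end, params$span_margin)
  if (!nrow(span)) return(empty_scenarios())
  left <- arms[arms$end <= exon_start - params$span_margin &
                 arms$end > min(span$start) - params$max_gap, , drop = FALSE]
  right <- arms[arms$start >= exon_end + params$span_margin &
                  arms$start < max(span$end) + params$max_gap, , drop = FALSE]
  span_cl <- cluster_arms(span, "span", params$cluster_eps, params$cluster_min_pts)
  res <- list()
  for (side in c("left", "right")) {
    flank <- if (side == "left") left else right
    if (!nrow(flank)) next
    flank_cl <- cluster_arms(flank, side, params$cluster_eps, params$cluster_min_pts)
    cand <- match_clusters(span_cl, flank_cl, side, gene_id, chrom,
                           exon_start, exon_end, other_exons, params)
    if (!nrow(cand)) next
    cand <- group_similar(cand, params$end_tolerance)
    cand <- cand[seq_len(min(params$max_scenarios, nrow(cand))), , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    res[[side]] <- cand
  }
  if (!length(res)) return(empty_scenarios())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
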