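# Knock-out scenario design: partial exon deletion, whole-exon excision, and
# complementary stop-codon knock-ins.
#
# Knock-outs use the plain exon database (no compression or projections) and
# are restricted to eligible exons: present in every transcript variant of
# the gene and of length not divisible by 3 (see
# \code{\link{knockout_eligible_exons}}). Partial deletion places both arm
# termini strictly inside the exon (split point inside the exon); whole-exon
# excision, attempted only for exons of at most 700 bp, removes the exon
# plus more than 20 bases on each side.

.assert_eligible <- function(exon) {
  if (!isTRUE(exon$eligible)) {
    stop("exon is not knock-out eligible (present in all transcripts and ",
         "length %% 3 != 0 required); pre-filter with knockout_eligible_exons()")
  }
}

# shared tail of both knock-out modes: cluster left/right arms, keep the
# smallest-gap design per cluster pair, rank, group similar, cap at 5.
.ko_match_and_rank <- function(left, right, gene_id, chrom, exon, mode,
                               min_gap, max_gap, params) {
  if (!nrow(left) || !nrow(right)) return(empty_scenarios())
  left_cl <- cluster_arms(left, "left", params$cluster_eps, params$cluster_min_pts)
  right_cl <- cluster_arms(right, "right", params$cluster_eps, params$cluster_min_pts)
  li <- rep(seq_len(nrow(left_cl)), times = nrow(right_cl))
  ri <- rep(seq_len(nrow(right_cl)), each = nrow(left_cl))
  gap <- right_cl$start[ri] - left_cl$end[li]
  ok <- gap >= min_gap & gap < max_gap
  if (!any(ok)) return(empty_scenarios())
  li <- li[ok]; ri <- ri[ok]; gap <- gap[ok]
  # the smallest-gap design per (left cluster, right cluster)
  key <- (left_cl$cluster[li] - 1L) * max(right_cl$cluster) +
    right_cl$cluster[ri]
  cum <- (left_cl$end[li] - left_cl$start[li]) +
    (right_cl$end[ri] - right_cl$start[ri])
  ord <- order(gap, -cum, left_cl$start[li], right_cl$start[ri])
  best <- ord[!duplicated(key[ord])]
  best <- best[order(key[best])]
  la <- left_cl[li[best], ]; ra <- right_cl[ri[best], ]
  res <- data.frame(
    gene_id = gene_id, feature_chrom = chrom,
    feature_start = exon$start, feature_end = exon$end,
    category = mode,
    arm1_start = la$start, arm1_end = la$end,
    arm1_fwd_seq = la$fwd_seq, arm1_rev_seq = la$rev_seq,
    arm1_penalty = la$penalty,
    arm2_start = ra$start, arm2_end = ra$end,
    arm2_fwd_seq = ra$fwd_seq, arm2_rev_seq = ra$rev_seq,
    arm2_penalty = ra$penalty,
    gap = gap[best], gap_start = la$end, gap_end = ra$start,
    split_distance = 0L,
    cumulative_length = cum[best],
    rank = NA_integer_, stringsAsFactors = FALSE
  )
  res <- group_similar(res, params$end_tolerance)
  res <- res[seq_len(min(params$max_scenarios, nrow(res))), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$gap_mod3 <- res$gap %% 3L
  rownames(res) <- NULL
  res
}

#' Partial-deletion knock-out scenarios for one eligible exon
#'
#' Left arms end strictly inside the exon and right arms start strictly
#' inside it, so the split point lies within the exon and the deleted
#' segment is the gap. Per cluster pair the smallest-gap design is kept;
#' ranking minimizes the gap, then maximizes cumulative arm length. At most
#' \code{params$max_scenarios} designs are returned; the exported
#' \code{gap_mod3} column reports the deleted length modulo 3 for user
#' judgement (no frame filter is applied).
#'
#' @param gene_id,chrom annotation of the exon.
#' @param exon list with \code{start}, \code{end} (0-based half-open) and
#'   logical \code{eligible}; an ineligible exon is an error.
#' @param arms \code{arm_store} of the gene.
#' @param params a \code{design_params}.
#' @return scenario data frame (category \code{"partial_deletion"}).
#' @export
design_partial_deletion <- function(gene_id, chrom, exon, arms,
                                    params = design_params()) {
  .assert_eligible(exon)
  left <- arms[arms$end > exon$start & arms$end < exon$end, , drop = FALSE]
  right <- arms[arms$start > exon$start & arms$start < exon$end, , drop = FALSE]
  .ko_match_and_rank(left, right, gene_id, chrom, exon, "partial_deletion",
                     min_gap = 0L, max_gap = params$max_gap, params = params)
}

#' Whole-exon excision knock-out scenarios
#'
#' Attempted only when the exon is at most \code{params$whole_exon_max_len}
#' (700) bases: left arms end more than \code{span_margin} (20) bases before
#' the exon start and right arms start more than 20 bases after the exon end
#' (strict margins), with the inner arm ends within \code{max_gap} of the
#' exon borders. The deletion interval therefore contains the whole exon
#' plus more than 20 bases on each side.
#'
#' @inheritParams design_partial_deletion
#' @return scenario data frame (category \code{"whole_exon"}); empty,
#'   without attempting, for exons longer than the cap.
#' @export
design_whole_exon <- function(gene_id, chrom, exon, arms,
                              params = design_params()) {
  .assert_eligible(exon)
  if (exon$end - exon$start > params$whole_exon_max_len) {
    return(empty_scenarios())
  }
  m <- params$span_margin
  left <- arms[exon$start - arms$end > m &
                 exon$start - arms$end < params$max_gap, , drop = FALSE]
  right <- arms[arms$start - exon$end > m &
                  arms$start - exon$end < params$max_gap, , drop = FALSE]
  .ko_match_and_rank(left, right, gene_id, chrom, exon, "whole_exon",
                     min_gap = (exon$end - exon$start) + 2L * (m + 1L),
                     max_gap = (exon$end - exon$start) + 2L * params$max_gap,
                     params = params)
}

#' Knock-in scenarios reusable as stop-codon knock-outs
#'
#' Any knock-in scenario whose target feature contains an eligible exon can
#' introduce one or more premature stop codons into that exon. Returns the
#' exon's knock-in scenarios flagged as stop-codon knock-out candidates.
#'
#' @param exon list with \code{start}, \code{end}, \code{eligible}.
#' @param knockin_results knock-in scenario data frame for the gene (any set
#'   of features).
#' @return the scenarios whose feature interval contains the exon, with a
#'   \code{stop_codon_candidate} column; zero rows when none exist.
#' @export
complementary_knockin <- function(exon, knockin_results) {
  .assert_eligible(exon)
  if (!nrow(knockin_results)) {
    out <- knockin_results
    out$stop_codon_candidate <- logical(0)
    return(out)
  }
  keep <- knockin_results$feature_start <= exon$start &
    knockin_results$feature_end >= exon$end
  out <- knockin_results[keep, , drop = FALSE]
  out$stop_codon_candidate <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' All knock-out designs for one eligible exon
#'
#' Convenience wrapper running both deletion modes and the complementary
#' knock-in lookup; reports whether any option exists for the exon.
#'
#' @inheritParams design_partial_deletion
#' @param knockin_results optional knock-in scenarios of the gene for the
#'   complementary lookup.
#' @return list with \code{scenarios} (both modes, bound), \code{complementary}
#'   (flagged knock-ins) and logical \code{has_option}.
#' @export
design_knockout <- function(gene_id, chrom, exon, arms,
                            knockin_results = empty_scenarios(),
                            params = design_params()) {
  pd <- design_partial_deletion(gene_id, chrom, exon, arms, params)
  we <- design_whole_exon(gene_id, chrom, exon, arms, params)
  if (!("gap_mod3" %in% names(pd))) pd$gap_mod3 <- integer(0)
  if (!("gap_mod3" %in% names(we))) we$gap_mod3 <- integer(0)
  sc <- rbind(pd, we)
  comp <- complementary_knockin(exon, knockin_results)
  list(scenarios = sc, complementary = comp,
       has_option = nrow(sc) > 0L || nrow(comp) > 0L)
}
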