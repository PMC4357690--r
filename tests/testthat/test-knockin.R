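# Knock-in designer: span arms, flank candidates, scoring, grouping,
# matching, and oracle equivalence of the full per-exon pipeline.

test_that("span arms must clear the exon by the 20-base margin on both sides", {
  exon_s <- 100; exon_e <- 200
  # third arm is deliberately undersized (margin probe), skip length checks
  arms <- make_arms(c(80, 81, 60), c(1000, 1000, 219), penalty = 1:3,
                    check = FALSE)
  sp <- find_span_arms(arms, exon_s, exon_e)
  # [80,1000): margins 20 and 800 -> span; [81,1000): margin 19 -> no;
  # [60,219): right margin 19 -> no
  expect_equal(sp$start, 80)
  # an exon longer than 1160 can have no 1200 bp span arm with margins
  long <- make_arms(0, 1200)
  expect_equal(nrow(find_span_arms(long, 30, 30 + 1161)), 0)
})

test_that("flank candidates respect the strict 700-base reach and no overlap", {
  span_s <- 5000; span_e <- 5900
  arms <- make_arms(c(4100, 3601, 3600, 4500), c(5000, 4301, 4300, 5100),
                    check = FALSE)
  left <- candidate_flank_arms(arms, span_s, span_e, "left")
  # end 5000: gap 0 in; end 4301: gap 699 in; end 4300: gap 700 out;
  # end 5100 overlaps the span -> out
  expect_setequal(left$gap, c(0, 699))
  right <- candidate_flank_arms(make_arms(c(5900, 6599, 6600), c(6700, 7400, 7400)),
                                span_s, span_e, "right")
  expect_setequal(right$gap, c(0, 699))
})

test_that("score_key orders by gap, split distance, cumulative length, position", {
  sc <- data.frame(gap = c(10, 0, 0, 0, 0),
                   split_distance = c(20, 40, 20, 20, 20),
                   cumulative_length = c(2400, 2400, 2000, 2200, 2200),
                   arm1_start = c(1, 1, 1, 5, 1),
                   arm2_start = 1)
  expect_equal(score_key(sc), c(5, 4, 3, 2, 1))
})

test_that("group_similar keeps one scenario per connected component", {
  base <- data.frame(
    category = "LS",
    arm1_start = c(100, 103, 106, 500), arm1_end = c(900, 903, 906, 1300),
    arm2_start = c(1000, 1003, 1006, 1400), arm2_end = c(2000, 2003, 2006, 2400),
    gap = c(0, 3, 6, 0), split_distance = 20,
    cumulative_length = c(1800, 1800, 1800, 1800)
  )
  # chain: 1~2 (diff 3), 2~3 (diff 3), 1!~3 (diff 6); 4 is isolated
  out <- group_similar(base, end_tolerance = 5)
  expect_equal(nrow(out), 2)
  expect_true(100 %in% out$arm1_start)            # best of the chain (gap 0)
  expect_true(500 %in% out$arm1_start)
  # sharing one identical arm connects scenarios even if the other differs
  two <- base[c(1, 1), ]
  two$arm1_start[2] <- 300; two$arm1_end[2] <- 1000; two$gap[2] <- 0
  out2 <- group_similar(two, end_tolerance = 5)
  expect_equal(nrow(out2), 1)
  # both ends differing by 6 at one end -> both survive
  far <- base[1:2, ]
  far$arm1_start[2] <- 106; far$arm2_start[2] <- 1006
  far$arm1_end[2] <- 906; far$arm2_end[2] <- 2006
  out3 <- group_similar(far, end_tolerance = 5)
  expect_equal(nrow(out3), 2)
})

test_that("match_clusters keeps the single best candidate per cluster pair", {
  # one span cluster (1 arm), one left cluster (2 arms, gaps 0 and 30)
  span <- cluster_arms(make_arms(1000, 2000), "span")
  left <- cluster_arms(make_arms(c(200, 170), c(1000, 970)), "left")
  got <- match_clusters(span, left, "left", 1L, "1", 1100, 1180,
                        data.frame(start = integer(), end = integer()))
  expect_equal(nrow(got), 1)
  expect_equal(got$gap, 0)
  # a cluster pair whose every combination has an exon in the gap yields none
  left2 <- cluster_arms(make_arms(200, 950), "left")
  got2 <- match_clusters(span, left2, "left", 1L, "1", 1100, 1180,
                         data.frame(start = 960, end = 990), params = design_params())
  expect_equal(nrow(got2), 0)
})

test_that("per-exon knock-in equals brute force on sparse hand-placed arms", {
  # arms far apart (> eps): clustering is singleton, so the heuristic must
  # reproduce the exhaustive enumeration exactly
  p <- design_params()
  exon_s <- 10000; exon_e <- 10100
  arms <- make_arms(
    starts = c(9900, 9700, 8800, 8500, 10950, 11300, 8300, 9090),
    ends   = c(10800, 10700, 9650, 9400, 11800, 12200, 9050, 9890),
    penalty = c(1, 2, 3, 4, 5, 6, 7, 8))
  others <- data.frame(start = c(8000, 12500), end = c(8090, 12600))
  got <- design_knockin(1L, "1", exon_s, exon_e, arms, others, p)
  want <- oracle_knockin(exon_s, exon_e, arms, others, p)
  expect_equal(nrow(got), nrow(want))
  for (col in c("category", "arm1_start", "arm1_end", "arm2_start",
                "arm2_end", "gap", "split_distance", "cumulative_length",
                "rank")) {
    expect_equal(got[[col]], want[[col]], info = col)
  }
  expect_knockin_invariants(got, exon_s, exon_e, others, p)
})

test_that("exon with no span arm yields an empty result", {
  arms <- make_arms(c(200, 1500), c(1000, 2400))
  got <- design_knockin(1L, "1", 5000, 5100, arms)
  expect_equal(nrow(got), 0)
})

test_that("dense random arm sets: caps, invariants, dissimilarity, rank-1 optimality", {
  p <- design_params()
  set.seed(31)
  for (rep in 1:4) {
    exon_s <- 10000; exon_e <- 10000 + sample(60:200, 1)
    n <- 120
    starts <- exon_s + sample(-3000:2800, n, replace = TRUE)
    lens <- sample(700:1200, n, replace = TRUE)
    arms <- make_arms(starts, starts + lens, penalty = runif(n))
    others <- data.frame(start = exon_s - 4000, end = exon_s - 3950)
    got <- design_knockin(1L, "1", exon_s, exon_e, arms, others, p)
    expect_knockin_invariants(got, exon_s, exon_e, others, p)
    # no two emitted scenarios of one category are similar
    for (cat in unique(got$category)) {
      sub <- got[got$category == cat, ]
      if (nrow(sub) > 1) {
        expect_equal(nrow(group_similar(sub, p$end_tolerance)), nrow(sub))
      }
    }
    want <- oracle_knockin(exon_s, exon_e, arms, others, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
      next
    }
    # the heuristic's rank-1 scenario per category is the global optimum,
    # and no emitted scenario outranks its brute-force counterpart
    for (cat in unique(want$category)) {
      w <- want[want$category == cat, ]
      g <- got[got$category == cat, ]
      expect_equal(g$gap[1], w$gap[1])
      expect_equal(g$split_distance[1], w$split_distance[1])
      expect_equal(g$cumulative_length[1], w$cumulative_length[1])
      for (r in seq_len(min(nrow(g), nrow(w)))) {
        better <- g$gap[r] < w$gap[r] ||
          (g$gap[r] == w$gap[r] && g$split_distance[r] < w$split_distance[r]) ||
          (g$gap[r] == w$gap[r] && g$split_distance[r] == w$split_distance[r] &&
             g$cumulative_length[r] > w$cumulative_length[r])
        expect_false(better)
      }
    }
  }
})
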