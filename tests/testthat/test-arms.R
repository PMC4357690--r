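# Arm factory: windows, filters, the per-gene store, coverage statistics.

test_that("window enumeration follows the step/remainder rules", {
  expect_equal(windows(1300, 1300, 50)$offset, 0)
  expect_equal(windows(1400, 1300, 50)$offset, c(0, 50, 100))
  # remainder: final window anchored at the region end
  expect_equal(windows(1430, 1300, 50)$offset, c(0, 50, 100, 130))
  w <- windows(1000, 1300, 50)
  expect_equal(nrow(w), 1)
  expect_equal(w$size, 1000)
})

test_that("filter_pairs applies the three arm filters with exact boundaries", {
  # region: 1000 bases; positions 0..249 masked (lowercase)
  region <- paste0(tolower(rand_seq(250, seed = 31)),
                   substr(rand_seq(1000, seed = 32), 251, 1000))
  p <- design_params()
  pairs <- data.frame(
    fwd_start = c(300L, 100L, 300L, 240L),
    fwd_end   = c(320L, 120L, 320L, 260L),
    rev_start = c(970L, 970L, 970L, 970L),
    rev_end   = c(990L, 990L, 990L, 990L),
    start     = c(300L, 100L, 250L, 240L),
    end       = c(990L, 990L, 990L, 990L),
    penalty = 1, fwd_tm = 60, rev_tm = 60
  )
  # row 1: clean primers, product [300,990) has 0% mask -> kept
  # row 2: forward primer inside the masked tract -> dropped
  # row 3: product [250,990) touches no mask -> kept
  # row 4: forward primer straddles the mask boundary -> dropped
  out <- filter_pairs(pairs, region, p)
  expect_equal(out$start, c(300, 250))

  # product repeat fraction boundary: 25% exactly kept, >25% dropped
  n_mask <- 250
  reg2 <- paste0(tolower(rand_seq(n_mask, seed = 33)),
                 substr(rand_seq(2000, seed = 34), n_mask + 1, 2000))
  pairs2 <- data.frame(
    fwd_start = c(1200L, 1200L), fwd_end = c(1220L, 1220L),
    rev_start = c(1950L, 1950L), rev_end = c(1970L, 1970L),
    start = c(1200L, 1200L), end = c(1970L, 1970L),
    penalty = 1, fwd_tm = 60, rev_tm = 60
  )
  # masked tract mid-product, clear of both primers
  base <- rand_seq(2000, seed = 35)
  mask_tract <- function(seq, from1, len) {
    paste0(substr(seq, 1, from1 - 1),
           tolower(substr(seq, from1, from1 + len - 1)),
           substr(seq, from1 + len, nchar(seq)))
  }
  # product [1200,1970) is 770 bp; 193/770 = 0.2506 > 0.25 -> dropped
  out25 <- filter_pairs(pairs2[1, ], mask_tract(base, 1301, 193), p)
  expect_equal(nrow(out25), 0)
  # 192/770 = 0.2494 <= 0.25 -> kept
  out24 <- filter_pairs(pairs2[1, ], mask_tract(base, 1301, 192), p)
  expect_equal(nrow(out24), 1)
  expect_lte(out24$repeat_fraction, 0.25)
  # 25% exactly is kept ("not more than 25%"): 770 * 0.25 = 192.5 is not an
  # integer, so check the boundary on a 800 bp product (200 masked)
  pairs3 <- pairs2[1, ]
  pairs3$rev_start <- 1980L; pairs3$rev_end <- 2000L; pairs3$end <- 2000L
  out200 <- filter_pairs(pairs3, mask_tract(base, 1301, 200), p)
  expect_equal(nrow(out200), 1)
  expect_equal(out200$repeat_fraction, 0.25)
  out201 <- filter_pairs(pairs3, mask_tract(base, 1301, 201), p)
  expect_equal(nrow(out201), 0)

  # primer containing N -> dropped
  regN <- rand_seq(2000, seed = 38)
  substr(regN, 1210, 1210) <- "N"
  outN <- filter_pairs(pairs2[1, ], regN, p)
  expect_equal(nrow(outN), 0)

  # mononucleotide run of 4 in a primer -> dropped
  regA <- rand_seq(2000, seed = 39)
  substr(regA, 1205, 1208) <- "AAAA"
  outA <- filter_pairs(pairs2[1, ], regA, p)
  expect_equal(nrow(outA), 0)
})

test_that("build_arm_database dedupes identical primer quadruples and flags empty stores", {
  g <- genome_store(c("1" = rand_seq(12000, seed = 41)))
  p <- fast_params()
  reg <- target_region(g, "1", 5000, 5100)
  store <- build_arm_database(1L, list(reg), p)
  expect_s3_class(store, "arm_store")
  expect_gt(nrow(store), 0)
  key <- paste(store$fwd_start, store$fwd_end, store$rev_start, store$rev_end)
  expect_false(any(duplicated(key)))
  # overlapping windows produce duplicate pairs pre-dedupe; the store must
  # keep each at its lowest penalty (penalty is per-pair deterministic here)
  expect_true(all(store$length >= 700 & store$length <= 1200))
  expect_true(all(store$repeat_fraction <= 0.25))
  expect_true(all(store$fwd_end <= store$rev_start))

  # fully masked neighbourhood -> empty store, flagged
  gm <- genome_store(c("1" = tolower(rand_seq(12000, seed = 42))))
  regm <- target_region(gm, "1", 5000, 5100)
  storem <- build_arm_database(2L, list(regm), p)
  expect_equal(nrow(storem), 0)
  expect_true(attr(storem, "no_arms"))
})

test_that("arm database equals window-by-window enumeration on a micro region", {
  g <- genome_store(c("1" = rand_seq(9000, seed = 43)))
  p <- fast_params()
  reg <- target_region(g, "1", 4000, 4080)
  store <- build_arm_database(1L, list(reg), p)

  # exhaustive oracle: run the public single-window designer over every
  # window and bin, filter, dedupe by quadruple keeping min penalty
  win <- windows(nchar(reg$seq), p$sw, p$ss)
  acc <- list()
  for (wi in seq_len(nrow(win))) {
    wseq <- substr(reg$seq, win$offset[wi] + 1, win$offset[wi] + win$size[wi])
    for (bi in seq_len(nrow(p$size_bins))) {
      pr <- design_in_window(wseq, p$size_bins[bi, ], npp = p$npp, params = p)
      if (!nrow(pr)) next
      for (col in c("fwd_start", "fwd_end", "rev_start", "rev_end",
                    "start", "end")) {
        pr[[col]] <- pr[[col]] + win$offset[wi]
      }
      acc[[length(acc) + 1]] <- pr
    }
  }
  all_pairs <- do.call(rbind, acc)
  all_pairs <- filter_pairs(all_pairs, reg$seq, p)
  key <- paste(all_pairs$fwd_start, all_pairs$fwd_end,
               all_pairs$rev_start, all_pairs$rev_end)
  ord <- order(all_pairs$penalty)
  all_pairs <- all_pairs[ord, ]
  all_pairs <- all_pairs[!duplicated(key[ord]), ]
  expect_equal(nrow(store), nrow(all_pairs))
  expect_setequal(paste(store$start, store$end),
                  paste(all_pairs$start + reg$start, all_pairs$end + reg$start))
})

test_that("coverage statistics count covered bases and depth correctly", {
  arms <- make_arms(1000, 2000)
  cs <- coverage_stats(arms, 1000, 3000)
  expect_equal(cs$sequence_coverage, 0.5)
  expect_equal(cs$average_depth, 0.5)
  # duplicated extent: coverage unchanged, depth doubled
  arms2 <- make_arms(c(1000, 1000), c(2000, 2000), penalty = c(1, 2))
  cs2 <- coverage_stats(arms2, 1000, 3000)
  expect_equal(cs2$sequence_coverage, 0.5)
  expect_equal(cs2$average_depth, 1.0)
  # empty store: zero coverage, penalty reported missing
  cs0 <- coverage_stats(make_arms(integer(0), integer(0)), 0, 100)
  expect_equal(cs0$sequence_coverage, 0)
  expect_equal(cs0$average_depth, 0)
  expect_true(is.na(cs0$average_penalty))
})

test_that("store construction is deterministic", {
  g <- genome_store(c("1" = rand_seq(11000, seed = 44)))
  p <- fast_params()
  reg <- target_region(g, "1", 5000, 5060)
  s1 <- build_arm_database(1L, list(reg), p)
  s2 <- build_arm_database(1L, list(reg), p)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("coverage sweep matches independent runs and shows the expected trends", {
  g <- genome_store(c("1" = rand_seq(15000, seed = 45)))
  p <- design_params(npp = 10)
  reg <- target_region(g, "1", 6000, 6120)
  targets <- data.frame(start = 6000, end = 6120)
  sweep <- coverage_sweep(1L, list(reg), targets, ss_values = c(50, 100),
                          npp_values = c(2, 10), params = p)
  # equivalence: each grid cell equals an independent run at that (ss, npp)
  for (i in seq_len(nrow(sweep))) {
    pi <- design_params(ss = sweep$ss[i], npp = sweep$npp[i])
    si <- build_arm_database(1L, list(reg), pi)
    ci <- coverage_stats(si, 6000, 6120)
    expect_equal(sweep$sequence_coverage[i], ci$sequence_coverage)
    expect_equal(sweep$average_depth[i], ci$average_depth)
    expect_equal(sweep$n_arms[i], ci$n_arms)
  }
  # trends: finer step never loses coverage; more pairs never lose depth
  for (np in unique(sweep$npp)) {
    sub <- sweep[sweep$npp == np, ]
    expect_gte(sub$sequence_coverage[sub$ss == 50],
               sub$sequence_coverage[sub$ss == 100])
  }
  for (s in unique(sweep$ss)) {
    sub <- sweep[sweep$ss == s, ]
    sub <- sub[order(sub$npp), ]
    expect_true(all(diff(sub$average_depth) >= 0))
  }
})
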