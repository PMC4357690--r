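# Annotation parsing, exon compression, projection and eligibility.

test_that("parse_ccds keeps exactly the Public records with a GeneID", {
  path <- write_ccds(list(
    tx("CCDS1.1", 10, c(100, 300), c(200, 400)),
    tx("CCDS2.1", 10, c(100, 300), c(200, 401)),
    tx("CCDS3.1", 11, 1000, 1100, status = "Withdrawn"),
    tx("CCDS4.1", 12, 2000, 2100, status = "Public, under review"),
    tx("CCDS5.1", 13, 3000, 3100, status = "Reviewed, update pending")
  ))
  gms <- parse_ccds(path)
  expect_equal(n_transcripts(gms), 2)
  expect_equal(n_genes(gms), 1)
  expect_equal(n_exons(gms), 4)
  expect_setequal(gms$transcripts$ccds_id, c("CCDS1.1", "CCDS2.1"))
  # CCDS inclusive ends converted to half-open
  expect_equal(sort(unique(gms$exons$end)), c(200, 400, 401))
})

test_that("empty table (header only) parses to an empty set without error", {
  path <- write_ccds(list())
  gms <- parse_ccds(path)
  expect_s3_class(gms, "GeneModelSet")
  expect_equal(n_transcripts(gms), 0)
  expect_equal(n_exons(gms), 0)
  expect_equal(annotation_summary(gms)$projections, 0)
})

test_that("malformed input is reported precisely", {
  path <- write_ccds(list(tx("CCDS1.1", 10, 100, 200)))
  lines <- readLines(path)
  writeLines(c(lines, "too\tfew\tfields"), path)
  expect_error(parse_ccds(path), "line 3")

  path2 <- tempfile()
  writeLines(sub("\tccds_status", "\tstatus_oops", readLines(write_ccds(list(
    tx("CCDS1.1", 10, 100, 200))))), path2)
  expect_error(parse_ccds(path2), "ccds_status")

  # unparsable locations in a Public record: skipped with a warning
  path3 <- write_ccds(list(tx("CCDS1.1", 10, 100, 200)))
  lines <- readLines(path3)
  bad <- sub("\\[100-199\\]", "[not-coords]", lines[2])
  writeLines(c(lines[1], bad,
               sub("CCDS1.1", "CCDS9.1", lines[2])), path3)
  expect_warning(gms <- parse_ccds(path3), "unparsable")
  expect_equal(n_transcripts(gms), 1)
})

test_that("compress_exons merges identical coordinates and tracks CCDS ids", {
  path <- write_ccds(list(
    tx("A", 10, c(100, 500), c(200, 600)),
    tx("B", 10, c(100, 500), c(201, 600))
  ))
  gms <- parse_ccds(path)
  ue <- compress_exons(gms, 10)
  expect_equal(nrow(ue), 3)                      # [100,200), [100,201), [500,600)
  shared <- ue[ue$start == 500, ]
  expect_equal(shared$ccds_ids, "A,B")
  expect_equal(ue$n_ccds[ue$end == 200], 1)
  expect_error(compress_exons(gms, 999), "unknown gene_id")
})

test_that("three transcripts sharing all exons compress to one transcript's exons", {
  starts <- c(100, 700, 1500); ends <- c(250, 800, 1650)
  path <- write_ccds(list(tx("A", 10, starts, ends), tx("B", 10, starts, ends),
                          tx("C", 10, starts, ends)))
  gms <- parse_ccds(path)
  ue <- compress_exons(gms, 10)
  # brute-force dedupe oracle
  raw <- unique(paste(rep(starts, 3), rep(ends, 3)))
  expect_equal(nrow(ue), length(raw))
  expect_true(all(ue$n_ccds == 3))
})

test_that("exon occurrences are conserved through compression", {
  path <- write_ccds(list(
    tx("A", 10, c(100, 500, 900), c(200, 600, 980)),
    tx("B", 10, c(100, 520), c(200, 600)),
    tx("C", 11, c(5000, 6000), c(5100, 6100))
  ))
  gms <- parse_ccds(path)
  total <- 0
  for (gid in unique(gms$transcripts$gene_id)) {
    ue <- compress_exons(gms, gid)
    total <- total + sum(ue$n_ccds)
  }
  expect_equal(total, n_exons(gms))              # no exon lost or duplicated
})

test_that("project_exons merges transitively and keeps outermost coordinates", {
  path <- write_ccds(list(
    tx("A", 10, c(100, 500), c(200, 600)),
    tx("B", 10, c(150, 590, 5000), c(250, 700, 5100))
  ))
  gms <- parse_ccds(path)
  pr <- project_exons(gms, 10)
  # [100,200)+[150,250) -> [100,250); [500,600)+[590,700) -> [500,700)
  expect_equal(pr$start, c(100, 500, 5000))
  expect_equal(pr$end, c(250, 700, 5100))
  expect_equal(pr$n_members, c(2L, 2L, 1L))
  expect_equal(pr$commonality, c(2L, 2L, 1L))
  # every member exon inside its projection; length >= max member length
  ue <- compress_exons(gms, 10)
  for (i in seq_len(nrow(pr))) {
    mem <- ue[pr$members[[i]], ]
    expect_true(all(mem$start >= pr$start[i] & mem$end <= pr$end[i]))
    expect_gte(pr$end[i] - pr$start[i], max(mem$end - mem$start))
  }
  expect_error(project_exons(gms, 999), "unknown gene_id")
})

test_that("chained overlaps produce a single projection (interval-union oracle)", {
  path <- write_ccds(list(
    tx("A", 10, c(100, 150), c(200, 250)),
    tx("B", 10, 240, 300)
  ))
  gms <- parse_ccds(path)
  pr <- project_exons(gms, 10)
  expect_equal(nrow(pr), 1)
  expect_equal(c(pr$start, pr$end), c(100, 300))
})

test_that("adjacent but non-overlapping exons are not merged", {
  path <- write_ccds(list(tx("A", 10, c(100, 200), c(200, 300))))
  gms <- parse_ccds(path)
  pr <- project_exons(gms, 10)
  expect_equal(nrow(pr), 2)
})

test_that("projection is idempotent (projections re-projected are a fixed point)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    s <- sort(sample(100:5000, n))
    e <- s + sample(50:400, n, replace = TRUE)
    path <- write_ccds(list(tx("A", 10, s, e[order(s)])))
    gms <- tryCatch(parse_ccds(path), error = function(e) NULL)
    if (is.null(gms)) next                       # overlapping within one tx: skip draw
    pr <- project_exons(gms, 10)
    path2 <- write_ccds(list(tx("A", 10, pr$start, pr$end)))
    pr2 <- project_exons(parse_ccds(path2), 10)
    expect_equal(pr2$start, pr$start)
    expect_equal(pr2$end, pr$end)
  }
})

test_that("knockout eligibility requires all transcripts and length % 3 != 0", {
  path <- write_ccds(list(
    tx("A", 10, c(1000, 3000, 5000), c(1100, 3099, 5100)),
    tx("B", 10, c(1000, 3000), c(1100, 3099))
  ))
  gms <- parse_ccds(path)
  elig <- knockout_eligible_exons(gms, 10)
  # 1000-1100: len 100 (mod 3 = 1), in both -> eligible
  # 3000-3099: len 99, in both -> ineligible (frame preserved)
  # 5000-5100: len 100 but only in A -> ineligible
  expect_equal(nrow(elig), 1)
  expect_equal(elig$start, 1000)
  expect_error(knockout_eligible_exons(gms, 999), "unknown gene_id")
})

test_that("single-transcript genes: every exon is trivially shared", {
  path <- write_ccds(list(tx("A", 10, c(100, 700), c(200, 799))))
  gms <- parse_ccds(path)
  elig <- knockout_eligible_exons(gms, 10)
  # len 100 (mod 3 = 1) eligible; len 99 frame-preserving
  expect_equal(nrow(elig), 1)
  expect_equal(elig$start, 100)
})

test_that("eligibility is decided from the table alone (no genome access)", {
  path <- write_ccds(list(tx("A", 10, 100, 200)))
  gms <- parse_ccds(path)
  # no genome_store exists in this scope at all; the call must still work
  expect_silent(elig <- knockout_eligible_exons(gms, 10))
  expect_equal(nrow(elig), 1)
})

test_that("projections export as 0-based half-open BED", {
  path <- write_ccds(list(tx("A", 10, c(100, 150), c(200, 250))))
  gms <- parse_ccds(path)
  bed <- tempfile(fileext = ".bed")
  write_projections_bed(gms, bed)
  rec <- read.delim(bed, header = FALSE)
  expect_equal(rec$V2, 100)
  expect_equal(rec$V3, 250)
})
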