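# Shared fixture builders and independent oracles. Oracles are deliberately
# written as plain enumeration (loops, full cross products, igraph
# components) so they share no code path with the package pipeline.

options(raavarms.quiet = TRUE)

# a plain random unmasked sequence
rand_seq <- function(n, seed = 1, gc = 0.45) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# hand-placed arm store from product intervals
make_arms <- function(starts, ends, penalty = seq_along(starts),
                      chrom = "1", check = TRUE) {
  as_arm_store(data.frame(chrom = rep(chrom, length.out = length(starts)),
                          start = as.integer(starts),
                          end = as.integer(ends),
                          penalty = rep(as.numeric(penalty),
                                        length.out = length(starts))),
               gene_id = 1L, check = check)
}

# fast-but-small design parameters for pipeline-level tests
fast_params <- function(...) design_params(ss = 100L, npp = 5L, ...)

# write a CCDS-dialect table from a list of transcripts
# (each: list(ccds_id, gene_id, gene, status, strand, starts, ends))
write_ccds <- function(txs, path = tempfile(fileext = ".txt"), chrom = "1") {
  header <- paste("#chromosome", "nc_accession", "gene", "gene_id", "ccds_id",
                  "ccds_status", "cds_strand", "cds_from", "cds_to",
                  "cds_locations", "match_type", sep = "\t")
  lines <- vapply(txs, function(tx) {
    locs <- paste(sprintf("%d-%d", tx$starts, tx$ends - 1L), collapse = ", ")
    paste(chrom, "NC_TEST", tx$gene, tx$gene_id, tx$ccds_id, tx$status,
          tx$strand, min(tx$starts), max(tx$ends) - 1L,
          paste0("[", locs, "]"), "Identical", sep = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  path
}

tx <- function(ccds_id, gene_id, starts, ends, status = "Public",
               gene = paste0("G", gene_id), strand = "+") {
  list(ccds_id = ccds_id, gene_id = gene_id, gene = gene, status = status,
       strand = strand, starts = as.integer(starts), ends = as.integer(ends))
}

# ---- independent DBSCAN oracle: textbook density reachability on a full
# ---- Chebyshev distance matrix
oracle_dbscan <- function(points, eps, min_pts) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(integer(0))
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(points))) {
    d <- pmax(d, abs(outer(points[, j], points[, j], "-")))
  }
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in order(points[, 1], if (ncol(points) > 1) points[, 2] else seq_len(n))) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    frontier <- i
    while (length(frontier)) {
      labels[frontier] <- cl
      nxt <- unique(unlist(lapply(frontier[core[frontier]],
                                  function(p) which(nb[p, ]))))
      frontier <- setdiff(nxt[labels[nxt] == 0L], integer(0))
      frontier <- frontier[labels[frontier] == 0L]
    }
  }
  labels
}

# canonical partition representation (set of sorted member vectors),
# noise points as singletons labelled NA
partition_of <- function(labels) {
  groups <- split(seq_along(labels), labels)
  unname(lapply(groups[order(vapply(groups, min, 0L))], sort))
}

# ---- independent knock-in oracle: full enumeration over all valid arm
# ---- pairs, similarity grouping via igraph, rank by the published priority
oracle_score_order <- function(df) {
  order(df$gap, df$split_distance, -df$cumulative_length,
        df$arm1_start, df$arm2_start)
}

oracle_similar_graph_best <- function(df, tol = 5L) {
  n <- nrow(df)
  if (n <= 1) return(df)
  edges <- list()
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    ident <- (df$arm1_start[i] == df$arm1_start[j] &
                df$arm1_end[i] == df$arm1_end[j]) |
      (df$arm2_start[i] == df$arm2_start[j] &
         df$arm2_end[i] == df$arm2_end[j])
    sim <- abs(df$arm1_start[i] - df$arm1_start[j]) <= tol &
      abs(df$arm1_end[i] - df$arm1_end[j]) <= tol &
      abs(df$arm2_start[i] - df$arm2_start[j]) <= tol &
      abs(df$arm2_end[i] - df$arm2_end[j]) <= tol
    hit <- j[ident | sim]
    if (length(hit)) edges[[i]] <- rbind(i, hit)
  }
  edges <- if (length(edges)) as.integer(unlist(edges)) else integer(0)
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  ord <- oracle_score_order(df)
  keep <- ord[!duplicated(comp[ord])]
  out <- df[sort(keep), , drop = FALSE]
  out[oracle_score_order(out), , drop = FALSE]
}

oracle_knockin <- function(exon_s, exon_e, arms, others, params) {
  as_ <- arms$start; ae <- arms$end
  inside_other <- function(pos) {
    for (r in seq_len(nrow(others))) {
      if (pos > others$start[r] && pos < others$end[r]) return(TRUE)
    }
    FALSE
  }
  res <- list()
  for (side in c("left", "right")) {
    acc_a1s <- acc_a1e <- acc_a2s <- acc_a2e <- integer(0)
    acc_gap <- acc_split <- integer(0)
    for (i in seq_len(length(as_))) {       # span candidate
      if (!(as_[i] <= exon_s - params$span_margin &&
            ae[i] >= exon_e + params$span_margin)) next
      if (inside_other(as_[i]) || inside_other(ae[i])) next
      for (j in seq_len(length(as_))) {     # flank candidate
        if (side == "left") {
          gap <- as_[i] - ae[j]
          gs <- ae[j]; ge <- as_[i]
          split <- exon_s - as_[i]
        } else {
          gap <- as_[j] - ae[i]
          gs <- ae[i]; ge <- as_[j]
          split <- ae[i] - exon_e
        }
        if (gap < 0 || gap >= params$max_gap) next
        if (split < params$span_margin) next
        bad <- inside_other(as_[j]) || inside_other(ae[j])
        if (!bad) for (r in seq_len(nrow(others))) {
          if (others$start[r] < ge && gs < others$end[r]) { bad <- TRUE; break }
        }
        if (bad) next
        if (side == "left") {
          acc_a1s <- c(acc_a1s, as_[j]); acc_a1e <- c(acc_a1e, ae[j])
          acc_a2s <- c(acc_a2s, as_[i]); acc_a2e <- c(acc_a2e, ae[i])
        } else {
          acc_a1s <- c(acc_a1s, as_[i]); acc_a1e <- c(acc_a1e, ae[i])
          acc_a2s <- c(acc_a2s, as_[j]); acc_a2e <- c(acc_a2e, ae[j])
        }
        acc_gap <- c(acc_gap, gap); acc_split <- c(acc_split, split)
      }
    }
    if (!length(acc_gap)) next
    df <- data.frame(
      category = if (side == "left") "LS" else "SR",
      arm1_start = acc_a1s, arm1_end = acc_a1e,
      arm2_start = acc_a2s, arm2_end = acc_a2e,
      gap = acc_gap, split_distance = acc_split,
      cumulative_length = (acc_a1e - acc_a1s) + (acc_a2e - acc_a2s))
    df <- oracle_similar_graph_best(df, params$end_tolerance)
    df <- df[seq_len(min(params$max_scenarios, nrow(df))), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    res[[side]] <- df
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- independent knock-out oracle (partial deletion / whole exon)
oracle_knockout <- function(exon_s, exon_e, arms, params,
                            mode = c("partial_deletion", "whole_exon")) {
  mode <- match.arg(mode)
  m <- params$span_margin
  as_ <- arms$start; ae <- arms$end
  if (mode == "partial_deletion") {
    lm <- which(ae > exon_s & ae < exon_e)     # left arm ends inside
    rm_ <- which(as_ > exon_s & as_ < exon_e)  # right arm starts inside
  } else {
    if (exon_e - exon_s > params$whole_exon_max_len) return(NULL)
    lm <- which(exon_s - ae > m & exon_s - ae < params$max_gap)
    rm_ <- which(as_ - exon_e > m & as_ - exon_e < params$max_gap)
  }
  if (!length(lm) || !length(rm_)) return(NULL)
  li <- rep(lm, times = length(rm_))
  ri <- rep(rm_, each = length(lm))
  gap <- as_[ri] - ae[li]
  ok <- if (mode == "partial_deletion") gap >= 0 & gap < params$max_gap
        else rep(TRUE, length(gap))
  if (!any(ok)) return(NULL)
  li <- li[ok]; ri <- ri[ok]; gap <- gap[ok]
  df <- data.frame(
    category = mode,
    arm1_start = as_[li], arm1_end = ae[li],
    arm2_start = as_[ri], arm2_end = ae[ri],
    gap = gap, split_distance = 0L,
    cumulative_length = (ae[li] - as_[li]) + (ae[ri] - as_[ri]))
  df <- oracle_similar_graph_best(df, params$end_tolerance)
  df <- df[seq_len(min(params$max_scenarios, nrow(df))), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# common invariant assertions for emitted knock-in scenarios
expect_knockin_invariants <- function(sc, exon_s, exon_e, others, params) {
  if (!nrow(sc)) return(invisible(NULL))
  expect_true(all(sc$gap >= 0 & sc$gap < params$max_gap))
  expect_true(all(sc$split_distance >= params$span_margin))
  expect_true(all(sc$arm1_end <= sc$gap_start | sc$arm1_end <= sc$arm2_start))
  span_start <- ifelse(sc$category == "LS", sc$arm2_start, sc$arm1_start)
  span_end <- ifelse(sc$category == "LS", sc$arm2_end, sc$arm1_end)
  expect_true(all(span_start <= exon_s - params$span_margin))
  expect_true(all(span_end >= exon_e + params$span_margin))
  expect_true(all(sc$arm1_end <= sc$arm2_start))      # arms never overlap
  for (r in seq_len(nrow(others))) {
    expect_false(any(others$start[r] < sc$gap_end & sc$gap_start < others$end[r]))
    for (col in c("arm1_start", "arm1_end", "arm2_start", "arm2_end")) {
      expect_false(any(sc[[col]] > others$start[r] & sc[[col]] < others$end[r]))
    }
  }
  for (cat in unique(sc$category)) {
    expect_lte(sum(sc$category == cat), params$max_scenarios)
  }
}
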