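test_that("global alignment handles identical and nested sequences", {
  p <- align_pair("ACGT", "ACGT")
  expect_identical(length(p$a), 4L)
  expect_identical(p$overlap, 4L)
  expect_equal(pairwise_identity(p)$identity, 1)

  p <- align_pair("ACGT", "ACG")
  expect_identical(length(p$a), 4L)
  expect_identical(sum(p$b == "-"), 1L)
  expect_identical(p$overlap, 3L)
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("alignment score matches an independent Gotoh DP oracle", {
  set.seed(31)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
    # derived copy with substitutions and an indel
    b <- mutate_at(a, sample(100, 6))
    b <- paste0(substr(b, 1, 40), substr(b, 44, 100))
    expect_equal(align_pair(a, b)$score, nw_score_oracle(a, b))
  }
})

test_that("identity uses the shorter sequence's unambiguous length", {
  a <- paste(rep("ACGTACGTAC", 10), collapse = "")
  b <- mutate_at(a, c(5, 25, 77))                 # 97/100 matches
  p <- pair_from_alignment(a, b)
  expect_equal(pairwise_identity(p)$identity, 0.97)
  expect_identical(pairwise_identity(p)$overlap, 100L)

  # ambiguity codes count neither as match nor as site
  pn <- pair_from_alignment("ACGN", "ACGT")
  expect_equal(pairwise_identity(pn)$identity, 1)  # 3 matches / min(3, 4)
  expect_identical(pn$overlap, 3L)

  all_n <- pair_from_alignment("NNNN", "ACGT")
  expect_true(is.na(pairwise_identity(all_n)$identity))
})

test_that("a 2% substitution pair has identity near 0.98", {
  set.seed(7)
  anc <- random_coding_sequence(650)
  der <- mutate_at(anc, sample(650, 13))
  p <- pair_from_alignment(anc, der)
  expect_equal(pairwise_identity(p)$identity, 1 - 13 / 650)
  expect_equal(p_distance(p), 13 / 650)
})

test_that("K2P distance matches its closed form and saturates to NA", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.1))
  expect_equal(k2p_distance(0.1, 0.05), 0.170182, tolerance = 1e-5)
  expect_true(is.na(k2p_distance(0.45, 0.1)))   # 1 - 2P - Q = 0
  expect_true(is.na(k2p_distance(0.2, 0.5)))    # 1 - 2Q = 0
})

test_that("K2P is close to p at small divergence and never below it", {
  set.seed(12)
  anc <- random_coding_sequence(650)
  der <- mutate_at(anc, sample(650, 13))        # p = 0.02
  p <- pair_from_alignment(anc, der)
  d_p <- p_distance(p)
  d_k <- k2p_distance(site_counts(p))
  expect_equal(d_p, 0.02)
  expect_lt(d_k - d_p, 0.005)
  expect_gte(d_k, d_p)

  # property: correction inflates for any valid site counts
  for (i in 1:50) {
    P <- runif(1, 0, 0.25); Q <- runif(1, 0, 0.25)
    expect_gte(k2p_distance(P, Q), P + Q - 1e-12)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, and match a per-pair oracle", {
  set.seed(5)
  anc <- random_coding_sequence(650)
  res <- c(anc, replicate(19, evolve_sequence(anc, runif(1, 0.01, 0.3))))
  recs <- seq_records(paste0("s", 1:20), res)
  for (metric in c("p", "k2p", "identity")) {
    dm <- build_distance_matrix(recs, metric, aligned = TRUE)
    expect_equal(dm, t(dm), ignore_attr = TRUE)
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0, na.rm = TRUE))
    # element-wise brute-force recomputation through the pair API
    for (k in 1:10) {
      i <- sample(20, 1); j <- sample(setdiff(1:20, i), 1)
      pair <- pair_from_alignment(res[i], res[j])
      want <- switch(metric, p = p_distance(pair),
                     k2p = k2p_distance(site_counts(pair)),
                     identity = 1 - pairwise_identity(pair)$identity)
      expect_equal(dm[i, j], want)
    }
  }
  # cross-check K2P and p against ape::dist.dna on the same alignment
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(res), "")))
  rownames(bin) <- recs$id
  expect_equal(unname(build_distance_matrix(recs, "k2p", aligned = TRUE)),
               unname(as.matrix(ape::dist.dna(bin, "K80",
                                              pairwise.deletion = TRUE))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(build_distance_matrix(recs, "p", aligned = TRUE)),
               unname(as.matrix(ape::dist.dna(bin, "raw",
                                              pairwise.deletion = TRUE))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group mean distances reproduce hand-constructed cells", {
  # two morpho-species whose every cross pair is at distance 0.355
  ids <- paste0("s", 1:4)
  dm <- matrix(0.355, 4, 4, dimnames = list(ids, ids))
  dm[1, 2] <- dm[2, 1] <- 0.094
  dm[3, 4] <- dm[4, 3] <- 0.125
  diag(dm) <- 0
  groups <- setNames(c("Oph2", "Oph2", "Prio1", "Prio1"), ids)
  tab <- group_mean_distances(dm, groups)
  get <- function(g1, g2) tab$mean_pct[tab$group1 == g1 & tab$group2 == g2]
  expect_equal(get("Oph2", "Oph2"), 9.4)
  expect_equal(get("Prio1", "Prio1"), 12.5)
  expect_equal(get("Oph2", "Prio1"), 35.5)
})

test_that("group means equal brute-force pair enumeration; singletons are NA", {
  set.seed(77)
  n <- 12
  ids <- paste0("s", 1:n)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  dm[lower.tri(dm)] <- runif(n * (n - 1) / 2)
  dm <- dm + t(dm)
  groups <- setNames(sample(c("a", "b", "c"), n, replace = TRUE), ids)
  groups[1] <- "solo"; groups[-1][groups[-1] == "solo"] <- "a"
  tab <- group_mean_distances(dm, groups)
  for (r in seq_len(nrow(tab))) {
    g1 <- tab$group1[r]; g2 <- tab$group2[r]
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gi <- groups[ids[i]]; gj <- groups[ids[j]]
      if ((gi == g1 && gj == g2) || (gi == g2 && gj == g1))
        vals <- c(vals, dm[i, j])
    }
    if (g1 == g2 && sum(groups == g1) < 2) expect_true(is.na(tab$mean_pct[r]))
    else expect_equal(tab$mean_pct[r], 100 * mean(vals))
  }
  expect_error(group_mean_distances(dm, groups[-2]), "unlabeled")
})
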