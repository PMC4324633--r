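cm_fixture <- function() {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 0, 2))
  colnames(m) <- paste0("m", 1:3)
  m
}

test_that("cosine similarity attains its documented extremes and hand value", {
  m <- cm_fixture()
  s <- cosine_similarity_matrix(m)
  expect_equal(s["a", "b"], 0.5)            # (1,1,0).(1,0,1)/2
  expect_equal(s["a", "c"], 0)              # disjoint MOTU sets
  expect_equal(s["b", "c"], sqrt(0.5))
  expect_equal(unname(diag(s)), c(1, 1, 1)) # identical vectors
  s2 <- cosine_similarity_matrix(rbind(a = c(2, 4), b = c(1, 2)))
  expect_equal(s2["a", "b"], 1)             # same orientation
  expect_error(cosine_similarity_matrix(rbind(a = c(1, 0), z = c(0, 0))),
               "all-zero.*z")
  expect_error(cosine_similarity_matrix(rbind(a = c(1, -1), b = c(1, 0))),
               "negative")
})

test_that("geographic distances: Euclidean degrees and haversine sanity", {
  st <- data.frame(station_id = c("p", "q", "r"),
                   latitude = c(0, 3, 0), longitude = c(0, 4, 0))
  g <- geographic_distance_matrix(st)
  expect_equal(g["p", "q"], 5)
  expect_equal(g["p", "r"], 0)
  # area centers are ~1300 km apart (great circle, within 15%)
  centers <- data.frame(station_id = c("german", "french"),
                        latitude = c(12.2, 14.05),
                        longitude = c(-117.8, -130.1))
  h <- geographic_distance_matrix(centers, "haversine_km")
  expect_lt(abs(h["german", "french"] - 1300) / 1300, 0.15)
})

test_that("nMDS embeds embeddable configurations at (near) zero stress", {
  ids <- c("a", "b", "c")
  eq <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(eq) <- 0
  fit <- nmds(eq, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-3)               # equilateral triangle
  expect_equal(unname(colMeans(fit$coordinates)), c(0, 0), tolerance = 1e-8)

  set.seed(9)
  xy <- matrix(rnorm(20), 10, 2)
  dm <- as.matrix(dist(xy))
  dimnames(dm) <- list(paste0("p", 1:10), paste0("p", 1:10))
  fit <- nmds(dm, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)               # self-embedding recovery

  # generic random dissimilarities over 8 points (untied) need > 2 dims
  ids <- paste0("q", 1:8)
  hi <- matrix(0, 8, 8, dimnames = list(ids, ids))
  set.seed(44)
  hi[lower.tri(hi)] <- runif(28, 0.5, 1.5)
  hi <- hi + t(hi)
  fit <- nmds(hi, n_restarts = 10, seed = 1)
  expect_gt(fit$stress, 0)
  expect_error(nmds(eq, k = 3), "smaller")
})

test_that("ANOSIM attains R = 1 at maximal separation and matches vegan", {
  ids <- paste0("s", 1:6)
  g <- setNames(rep(c("x", "y"), each = 3), ids)
  dm <- matrix(0, 6, 6, dimnames = list(ids, ids))
  within <- c(0.1, 0.12, 0.14)
  k <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    dm[i, j] <- dm[j, i] <-
      if (g[i] == g[j]) within[(k <- k + 1) %% 3 + 1] else 0.8 + i / 100 + j / 50
  }
  res <- anosim(dm, g, n_permutations = 199, seed = 1)
  expect_equal(res$statistic, 1)
  veg <- vegan::anosim(as.dist(dm), factor(g), permutations = 19)
  expect_equal(res$statistic, unname(veg$statistic))
})

test_that("ANOSIM permutation p matches exhaustive enumeration on 2+2 samples", {
  set.seed(33)
  ids <- paste0("s", 1:4)
  dm <- matrix(0, 4, 4, dimnames = list(ids, ids))
  dm[lower.tri(dm)] <- runif(6)
  dm <- dm + t(dm)
  g <- setNames(c("x", "x", "y", "y"), ids)
  res <- anosim(dm, g, exact = TRUE)
  # oracle: enumerate all 4! label arrangements independently
  perms <- perms_oracle(4)
  stats <- apply(perms, 1, function(p) anosim_R_oracle(dm, g[p]))
  expect_equal(res$statistic, anosim_R_oracle(dm, unname(g)))
  expect_equal(res$p_value, mean(stats >= res$statistic - 1e-12))
  expect_error(anosim(dm, setNames(c("x", "x", "x", "y"), ids)), "size 1")
})

test_that("ANOSIM is near zero on unstructured distances and reproducible", {
  set.seed(55)
  ids <- paste0("s", 1:12)
  g <- setNames(rep(c("x", "y"), 6), ids)
  rs <- replicate(30, {
    dm <- matrix(0, 12, 12, dimnames = list(ids, ids))
    dm[lower.tri(dm)] <- runif(66)
    dm <- dm + t(dm)
    anosim(dm, g, n_permutations = 99, seed = 7)$statistic
  })
  expect_lt(abs(mean(rs)), 0.1)
  dm <- matrix(0, 12, 12, dimnames = list(ids, ids))
  dm[lower.tri(dm)] <- runif(66)
  dm <- dm + t(dm)
  r1 <- anosim(dm, g, n_permutations = 99, seed = 3)
  r2 <- anosim(dm, g, n_permutations = 99, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Mantel r is exact on self-correlation and matches vegan", {
  set.seed(21)
  ids <- paste0("s", 1:8)
  m1 <- matrix(0, 8, 8, dimnames = list(ids, ids))
  m1[lower.tri(m1)] <- runif(28)
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 8, 8, dimnames = list(ids, ids))
  m2[lower.tri(m2)] <- runif(28)
  m2 <- m2 + t(m2)
  expect_equal(mantel(m1, m1 * 2, 99, seed = 1)$statistic, 1)
  res <- mantel(m1, m2, 199, seed = 1)
  veg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 19)
  expect_equal(res$statistic, veg$statistic)
  expect_error(mantel(m1, m2[c(2:8, 1), c(2:8, 1)]), "labels")
  expect_error(mantel(m1[1:3, 1:3], m2[1:3, 1:3]), "at least 4")
  expect_error(mantel(m1, m1 * 0), "variance")
})

test_that("Mantel permutation p matches exhaustive enumeration over 5! relabelings", {
  set.seed(77)
  ids <- paste0("s", 1:5)
  mk <- function() {
    m <- matrix(0, 5, 5, dimnames = list(ids, ids))
    m[lower.tri(m)] <- runif(10)
    m + t(m)
  }
  m1 <- mk(); m2 <- mk()
  res <- mantel(m1, m2, exact = TRUE, tail = "greater")
  perms <- perms_oracle(5)
  stats <- apply(perms, 1, function(p) mantel_r_oracle(m1, m2[p, p]))
  expect_equal(res$statistic, mantel_r_oracle(m1, m2))
  expect_equal(res$p_value, mean(stats >= res$statistic - 1e-12))
  res2 <- mantel(m1, m2, exact = TRUE, tail = "less")
  expect_equal(res2$p_value, mean(stats <= res2$statistic + 1e-12))
})

test_that("permutation p-values are reproducible bit-for-bit given a seed", {
  set.seed(10)
  ids <- paste0("s", 1:9)
  m1 <- matrix(0, 9, 9, dimnames = list(ids, ids))
  m1[lower.tri(m1)] <- runif(36); m1 <- m1 + t(m1)
  m2 <- matrix(0, 9, 9, dimnames = list(ids, ids))
  m2[lower.tri(m2)] <- runif(36); m2 <- m2 + t(m2)
  a <- mantel(m1, m2, 499, seed = 42)
  b <- mantel(m1, m2, 499, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$statistic, b$statistic)
})
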