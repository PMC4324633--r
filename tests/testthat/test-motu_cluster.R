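# Short fixed-length sequences keep these clustering fixtures exact: with
# 500 bp and min_overlap 400, an x% constructed divergence is x% identity.
make_seqs <- function(...) {
  res <- c(...)
  seq_records(paste0("s", seq_along(res)), res)
}

base_seq <- function(len = 500, seed = 2) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("identical sequences collapse to one cluster", {
  a <- base_seq()
  recs <- make_seqs(a, a, a, a, a)
  motus <- greedy_cluster(recs, cluster_config(), aligned = TRUE)
  expect_identical(nrow(motus$clusters), 1L)
  expect_identical(motus$clusters$size, 5L)
  expect_identical(motus$clusters$representative_id, "s1")
})

test_that("first-hit assignment at 97% splits a 96% neighbour off", {
  a <- base_seq(500)
  b <- mutate_at(a, 1:10)        # 98% to a
  cc <- mutate_at(a, 101:120)    # 96% to a; 94-96% to b
  recs <- make_seqs(a, b, cc)
  motus <- greedy_cluster(recs, cluster_config(0.97, 400), aligned = TRUE)
  expect_identical(nrow(motus$clusters), 2L)
  got <- split(motus$membership$member_id, motus$membership$cluster_id)
  expect_setequal(got[[1]], c("s1", "s2"))
  expect_setequal(got[[2]], "s3")
})

test_that("sequences shorter than min_overlap are excluded with a warning", {
  a <- base_seq(500)
  recs <- make_seqs(a, substr(a, 1, 300))
  expect_warning(motus <- greedy_cluster(recs, cluster_config(), aligned = FALSE),
                 "shorter")
  expect_identical(motus$excluded_ids, "s2")
  expect_identical(nrow(motus$clusters), 1L)
})

test_that("empty input yields an empty table", {
  recs <- seq_records(character(0), character(0))
  motus <- greedy_cluster(recs, cluster_config())
  expect_identical(nrow(motus$clusters), 0L)
  expect_identical(nrow(motus$membership), 0L)
})

test_that("clustering is an exhaustive disjoint partition that recovers ground truth", {
  sim <- simulate_dataset(sim_config(seed = 21))
  motus <- greedy_cluster(sim$records, cluster_config(), aligned = TRUE)
  # partition property
  expect_setequal(motus$membership$member_id, sim$records$id)
  expect_identical(anyDuplicated(motus$membership$member_id), 0L)
  expect_equal(sum(motus$clusters$size), nrow(sim$records))
  # representative is a member of its own cluster
  rep_cl <- motus$membership$cluster_id[
    match(motus$clusters$representative_id, motus$membership$member_id)]
  expect_identical(rep_cl, motus$clusters$cluster_id)
  # recovery of the generating partition
  truth <- sim$truth$partition[motus$membership$member_id]
  expect_equal(adjusted_rand_index(motus$membership$cluster_id, truth), 1)
  # members sit within threshold identity of their representative
  codes <- lapply(sim$records$residues, encode <- function(s)
    match(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
  names(codes) <- sim$records$id
  for (k in seq_len(nrow(motus$clusters))) {
    rep_id <- motus$clusters$representative_id[k]
    members <- motus$membership$member_id[motus$membership$cluster_id == k]
    for (m in members) {
      idn <- mean(codes[[m]] == codes[[rep_id]])
      expect_gte(idn, 0.97)
    }
  }
})

test_that("raising the threshold never decreases the cluster count", {
  sim <- simulate_dataset(sim_config(seed = 8, s_true = 120))
  counts <- vapply(c(0.80, 0.85, 0.90, 0.95, 0.99), function(t)
    nrow(greedy_cluster(sim$records, cluster_config(t, 400),
                        aligned = TRUE)$clusters), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("abundance matrix tallies member counts per station", {
  a <- base_seq()
  recs <- make_seqs(a, a, a)
  motus <- greedy_cluster(recs, cluster_config(), aligned = TRUE)
  sm <- setNames(rep("EBS01", 3), recs$id)
  cm <- build_abundance_matrix(motus, sm)
  expect_equal(unname(cm), matrix(3L, 1, 1))
  expect_error(build_abundance_matrix(motus, sm[-2]), "s2")
})

test_that("abundance matrix equals a direct group-by tally on synthetic data", {
  sim <- simulate_dataset(sim_config(seed = 31))
  motus <- greedy_cluster(sim$records, cluster_config(), aligned = TRUE)
  sm <- setNames(sim$records$station_id, sim$records$id)
  cm <- build_abundance_matrix(motus, sm)
  expect_equal(sort(unname(colSums(cm))), sort(motus$clusters$size))
  expect_equal(sum(cm), nrow(sim$records))
  for (k in sample(ncol(cm), 5)) {
    members <- motus$membership$member_id[
      motus$membership$cluster_id == as.integer(colnames(cm)[k])]
    tal <- table(sm[members])
    expect_equal(cm[names(tal), k], unname(as.integer(tal)),
                 ignore_attr = TRUE)
  }
})

test_that("MOTU summary partitions shared and exclusive clusters by area", {
  # all-singleton one-station case
  set.seed(4)
  res <- replicate(4, paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                            collapse = ""))
  recs <- seq_records(paste0("s", 1:4), res)
  motus <- suppressWarnings(greedy_cluster(recs, cluster_config(0.97, 400),
                                           aligned = TRUE))
  sm <- setNames(rep("EBS01", 4), recs$id)
  am <- c(EBS01 = "german")
  s <- summarize_motus(motus, sm, am)
  expect_equal(s$shared, 0)
  expect_equal(s$n_singletons, s$n_motus)
  expect_equal(s$exclusive$german, s$n_motus)

  # synthetic data vs set-algebra oracle
  sim <- simulate_dataset(sim_config(seed = 13))
  motus <- greedy_cluster(sim$records, cluster_config(), aligned = TRUE)
  sm <- setNames(sim$records$station_id, sim$records$id)
  am <- setNames(sim$stations$license_area, sim$stations$station_id)
  s <- summarize_motus(motus, sm, am)
  areas_by_cluster <- lapply(
    split(am[sm[motus$membership$member_id]], motus$membership$cluster_id),
    unique)
  expect_equal(s$n_motus, length(areas_by_cluster))
  expect_equal(s$shared, sum(lengths(areas_by_cluster) == 2))
  expect_equal(s$exclusive$german,
               sum(vapply(areas_by_cluster, identical, TRUE, "german")))
  expect_equal(s$exclusive$french,
               sum(vapply(areas_by_cluster, identical, TRUE, "french")))
  expect_equal(s$n_singletons + s$n_multi, s$n_motus)
  expect_equal(s$shared_multi + s$exclusive_multi$german +
                 s$exclusive_multi$french, s$n_multi)
})
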