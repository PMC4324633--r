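# Independent brute-force oracles used to validate package operations.
# These deliberately reimplement each computation by a different route.

# Gotoh affine-gap global alignment score: a gap run of length L costs
# |gap_open| + (L - 1) * |gap_extend| (first residue opens the gap).
nw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  go <- -gap_open; ge <- -gap_extend
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + (i - 1) * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + (j - 1) * ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge,
                             Y[i, j + 1] - go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - ge,
                             X[i + 1, j] - go)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Branch-by-branch unweighted UniFrac: classify every edge by the present
# tips below it (via phangorn::Descendants), dropping edges that subtend
# no present tip or every present tip (the root-to-LCA path).
unifrac_oracle <- function(tree, incidence, a, b) {
  tips_a <- incidence$tip_id[incidence$sample_id == a]
  tips_b <- incidence$tip_id[incidence$sample_id == b]
  if (setequal(tips_a, tips_b)) return(0)
  present <- union(tips_a, tips_b)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc[[e]]]
    below <- intersect(tips, present)
    if (length(below) == 0 || length(below) == length(present)) next
    den <- den + tree$edge.length[e]
    has_a <- length(intersect(below, tips_a)) > 0
    has_b <- length(intersect(below, tips_b)) > 0
    if (xor(has_a, has_b)) num <- num + tree$edge.length[e]
  }
  if (den == 0) 0 else num / den
}

# Permutations by recursive insertion (independent of the package's
# lexicographic generator).
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))
  }))
}

# Naive ANOSIM R: explicit double loop over sample pairs.
anosim_R_oracle <- function(dm, g) {
  n <- nrow(dm)
  d <- c(); between <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, dm[i, j]); between <- c(between, g[i] != g[j])
    }
  }
  r <- rank(d)
  (mean(r[between]) - mean(r[!between])) / (length(d) / 2)
}

# Naive Mantel r over explicit pair loops.
mantel_r_oracle <- function(m1, m2) {
  n <- nrow(m1)
  v1 <- c(); v2 <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) { v1 <- c(v1, m1[i, j]); v2 <- c(v2, m2[i, j]) }
  }
  stats::cor(v1, v2)
}

# Random rooted tree with branch lengths, tips labeled t1..tn.
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tree$edge.length <- stats::runif(length(tree$edge.length), 0.1, 2)
  tree
}

# Sequence records at controlled pairwise divergence, built by point
# substitutions at fixed positions (no RNG needed).
mutate_at <- function(seq, positions, to = "A") {
  v <- strsplit(seq, "")[[1]]
  v[positions] <- vapply(v[positions], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], "")
  paste(v, collapse = "")
}
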