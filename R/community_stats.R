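#' Cosine similarity between MOTU abundance vectors
#'
#' For stations `a`, `b` with abundance vectors `x_a`, `x_b`,
#' `S(a,b) = sum(x_a * x_b) / (||x_a|| * ||x_b||)`. With nonnegative counts
#' the similarity lies in \[0, 1\]: 0 for stations sharing no MOTUs, 1 for
#' identical composition. Being a measure of vector direction it does not
#' down-weight rare MOTUs, which suits singleton-heavy samples from
#' non-quantitative gear.
#'
#' @param cm Community matrix, rows = samples, columns = MOTUs, counts >= 0.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
cosine_similarity_matrix <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("community matrix has negative entries")
  norms <- sqrt(rowSums(cm^2))
  zero <- rownames(cm)[norms == 0]
  if (length(zero)) stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  s <- tcrossprod(cm / norms)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  attr(s, "metric") <- "cosine_similarity"
  s
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' @param s Similarity matrix in \[0, 1\].
#' @return `1 - s` with zero diagonal.
#' @export
sim_to_dist <- function(s) {
  d <- 1 - s
  diag(d) <- 0
  attr(d, "metric") <- paste0("1-", attr(s, "metric"))
  d
}

#' Geographic distance matrix between stations
#'
#' `euclidean_degrees` (default) is the plain Euclidean distance on decimal
#' degrees, `sqrt(dlat^2 + dlon^2)`; `haversine_km` is the great-circle
#' distance in kilometres, provided as an isotropic sanity alternative
#' since a degree of longitude at 12-14 degrees N is shorter than a degree
#' of latitude.
#'
#' @param stations Station table with `station_id`, `latitude`, `longitude`.
#' @param mode `"euclidean_degrees"` or `"haversine_km"`.
#' @return A symmetric distance matrix labeled by station id.
#' @export
geographic_distance_matrix <- function(stations,
                                       mode = c("euclidean_degrees",
                                                "haversine_km")) {
  mode <- match.arg(mode)
  ids <- stations$station_id
  if (mode == "euclidean_degrees") {
    m <- as.matrix(stats::dist(cbind(stations$latitude, stations$longitude)))
  } else {
    m <- geosphere::distm(cbind(stations$longitude, stations$latitude),
                          fun = geosphere::distHaversine) / 1000
  }
  dimnames(m) <- list(ids, ids)
  attr(m, "metric") <- mode
  m
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's nMDS (stress-1) of a dissimilarity matrix, via
#' [vegan::metaMDS] with random restarts under a fixed seed; the best
#' (lowest-stress) configuration is returned with its coordinates centered
#' at the origin. Similarity matrices must be converted first with
#' [sim_to_dist()].
#'
#' @param dm Symmetric dissimilarity matrix.
#' @param k Embedding dimension (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param max_iter Maximum iterations per start.
#' @param seed RNG seed.
#' @return A list with `coordinates` (samples x k), `stress` (Kruskal
#'   stress-1 in \[0, 1\]), `k`, `n_restarts`, `seed`.
#' @export
nmds <- function(dm, k = 2, n_restarts = 50, max_iter = 300, seed = 1) {
  check_square_labeled(dm, "dm")
  if (k >= nrow(dm)) stop("k must be smaller than the number of samples")
  fit <- with_seed_(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = n_restarts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE))))
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  list(coordinates = coords, stress = fit$stress, k = k,
       n_restarts = n_restarts, seed = seed)
}

rank_lower_ <- function(dm) rank(lower_tri_(dm))

anosim_stat_ <- function(rnk, between) {
  n2 <- length(rnk)                       # n(n-1)/2 unordered pairs
  (mean(rnk[between]) - mean(rnk[!between])) / (n2 / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's one-way ANOSIM: all off-diagonal dissimilarities are ranked
#' (average ranks for ties) and
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)`,
#' so that `R = 1` when every between-group pair is more dissimilar than
#' every within-group pair and `R` is near 0 under no structure. The
#' p-value permutes group labels over samples and uses the add-one
#' convention `(count of permuted R >= observed + 1) / (n_permutations + 1)`;
#' with `exact = TRUE` all label permutations are enumerated instead and
#' the p-value is the exact tail fraction (identity included).
#'
#' @param dm Symmetric dissimilarity matrix.
#' @param groups Named vector mapping sample id to group (>= 2 groups, each
#'   with >= 2 samples).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exact Enumerate all permutations (n <= 8).
#' @return A `perm_test` list: `statistic`, `p_value`, `n_permutations`,
#'   `seed`, `method`.
#' @export
anosim <- function(dm, groups, n_permutations = 999, seed = 1,
                   exact = FALSE) {
  check_square_labeled(dm, "dm")
  ids <- rownames(dm)
  if (!all(ids %in% names(groups))) stop("every sample needs a group")
  g <- as.character(groups[ids])
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("group(s) of size 1: ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  n <- length(g)
  rnk <- rank_lower_(dm)
  pair_i <- row(diag(n))[lower.tri(diag(n))]
  pair_j <- col(diag(n))[lower.tri(diag(n))]
  obs <- anosim_stat_(rnk, g[pair_i] != g[pair_j])
  stat_for <- function(perm) {
    gp <- g[perm]
    anosim_stat_(rnk, gp[pair_i] != gp[pair_j])
  }
  if (exact) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, stat_for)
    p <- mean(stats >= obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stats <- with_seed_(seed, vapply(seq_len(n_permutations),
                                     function(i) stat_for(sample.int(n)),
                                     numeric(1)))
    p <- (sum(stats >= obs - 1e-12) + 1) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed, method = "ANOSIM (Clarke R)"),
            class = "perm_test")
}

#' Mantel test between two distance (or similarity) matrices
#'
#' The statistic is the Pearson product-moment correlation `r` over the
#' lower-triangle entries; the null distribution is generated by
#' simultaneous row/column permutation of the second matrix. Matrices are
#' correlated exactly as given (a similarity matrix may be supplied
#' directly; the sign of `r` then reflects that orientation). The default
#' tail is one-sided in the direction of the observed `r`; the add-one
#' convention is used for random permutations, and `exact = TRUE`
#' enumerates all permutations (identity included).
#'
#' @param m1,m2 Labeled symmetric matrices over the same samples, in the
#'   same order.
#' @param n_permutations Number of random permutations (default 5000).
#' @param seed RNG seed.
#' @param tail `"observed"` (one-tailed in the observed direction),
#'   `"greater"`, `"less"`, or `"two"`.
#' @param exact Enumerate all permutations (n <= 8).
#' @return A `perm_test` list: `statistic`, `p_value`, `n_permutations`,
#'   `seed`, `tail`, `method`.
#' @export
mantel <- function(m1, m2, n_permutations = 5000, seed = 1,
                   tail = c("observed", "greater", "less", "two"),
                   exact = FALSE) {
  tail <- match.arg(tail)
  check_square_labeled(m1, "m1"); check_square_labeled(m2, "m2")
  if (!identical(rownames(m1), rownames(m2)))
    stop("m1 and m2 must share labels in the same order")
  n <- nrow(m1)
  if (n < 4L) stop("mantel needs at least 4 samples")
  v1 <- lower_tri_(m1)
  if (stats::sd(v1) == 0 || stats::sd(lower_tri_(m2)) == 0)
    stop("zero variance in a matrix triangle")
  obs <- stats::cor(v1, lower_tri_(m2))
  r_for <- function(perm) stats::cor(v1, lower_tri_(m2[perm, perm]))
  if (exact) {
    perms <- all_permutations(n)
    stats_ <- apply(perms, 1L, r_for)
    n_perm <- nrow(perms)
    count <- function(keep) mean(keep)
  } else {
    stats_ <- with_seed_(seed, vapply(seq_len(n_permutations),
                                      function(i) r_for(sample.int(n)),
                                      numeric(1)))
    n_perm <- n_permutations
    count <- function(keep) (sum(keep) + 1) / (n_permutations + 1)
  }
  eps <- 1e-12
  p <- switch(tail,
    observed = if (obs >= 0) count(stats_ >= obs - eps)
               else count(stats_ <= obs + eps),
    greater = count(stats_ >= obs - eps),
    less = count(stats_ <= obs + eps),
    two = count(abs(stats_) >= abs(obs) - eps))
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed, tail = tail, method = "Mantel (Pearson r)"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      " (", x$n_permutations, " permutations, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
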