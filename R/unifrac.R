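#' Unweighted UniFrac distance between two samples
#'
#' Fraction of tree branch length leading exclusively to tips of one of the
#' two samples, among the branch length leading to any tip of either
#' sample. Branches subtending no tip of either sample are ignored, and
#' branches above the lowest common ancestor of the present tips are
#' excluded from numerator and denominator alike.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param incidence Data frame with columns `tip_id`, `sample_id` (a tip
#'   may occur in several samples), or a named list tip -> sample ids.
#' @param a,b Sample ids.
#' @return A distance in \[0, 1\].
#' @export
unweighted_unifrac_pair <- function(tree, incidence, a, b) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  inc <- as_incidence_(incidence)
  tips_a <- inc$tip_id[inc$sample_id == a]
  tips_b <- inc$tip_id[inc$sample_id == b]
  if (length(tips_a) + length(tips_b) == 0L)
    stop("both samples are empty: ", a, ", ", b)
  present <- union(tips_a, tips_b)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) stop("incidence tips not in tree: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (setequal(tips_a, tips_b)) return(0)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  in_a <- in_b <- numeric(nnode)
  in_a[match(tips_a, tree$tip.label)] <- 1
  in_b[match(tips_b, tree$tip.label)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; c <- po$edge[e, 2L]
    in_a[p] <- in_a[p] + in_a[c]
    in_b[p] <- in_b[p] + in_b[c]
  }
  child <- po$edge[, 2L]
  below <- in_a[child] + in_b[child] > 0
  n_present_a <- sum(in_a[seq_len(ntip)] > 0)
  n_present_b <- sum(in_b[seq_len(ntip)] > 0)
  # edges whose child subtends every present tip lie on the root-to-LCA path
  all_below <- in_a[child] == n_present_a & in_b[child] == n_present_b
  use <- below & !all_below
  has_a <- in_a[child][use] > 0
  has_b <- in_b[child][use] > 0
  len <- po$edge.length[use]
  unique_len <- sum(len[xor(has_a, has_b)])
  total_len <- sum(len)
  if (total_len == 0) return(0)
  unique_len / total_len
}

as_incidence_ <- function(incidence) {
  if (is.data.frame(incidence)) {
    stopifnot(all(c("tip_id", "sample_id") %in% names(incidence)))
    return(incidence)
  }
  data.frame(tip_id = rep(names(incidence), lengths(incidence)),
             sample_id = unlist(incidence, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Pairwise unweighted UniFrac matrix over samples
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param incidence As in [unweighted_unifrac_pair()].
#' @param samples Sample ids to include; default all samples in the
#'   incidence. Samples with no tips on the tree are dropped with a warning.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
unifrac_matrix <- function(tree, incidence, samples = NULL) {
  inc <- as_incidence_(incidence)
  inc <- inc[inc$tip_id %in% tree$tip.label, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(inc$sample_id))
  empty <- samples[!samples %in% inc$sample_id]
  if (length(empty)) {
    warning("dropping sample(s) with no tips: ",
            paste(empty, collapse = ", "))
    samples <- setdiff(samples, empty)
  }
  if (length(samples) < 2L) stop("need at least 2 non-empty samples")
  n <- length(samples)
  m <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        unweighted_unifrac_pair(tree, inc, samples[i], samples[j])
    }
  }
  attr(m, "metric") <- "unweighted_unifrac"
  m
}
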