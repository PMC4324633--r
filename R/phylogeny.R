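#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (Studier-Keppler criterion) on a
#' labeled distance matrix, with negative branch lengths clamped to zero
#' and the final unrooted tree midpoint-rooted so that it can feed UniFrac,
#' which requires a root. Matrices containing undefined (`NA`) entries are
#' refused with the offending pairs listed.
#'
#' @param dm Labeled symmetric distance matrix with at least 3 taxa.
#' @param root `"midpoint"` (default) or `"none"` for the raw unrooted tree.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm, root = c("midpoint", "none")) {
  root <- match.arg(root)
  check_square_labeled(dm, "dm")
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(dm)) {
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    stop("distance matrix has undefined entries for pair(s): ",
         paste(utils::head(paste(rownames(dm)[bad[, 1]],
                                 colnames(dm)[bad[, 2]], sep = "/"), 5),
               collapse = ", "))
  }
  tree <- ape::nj(stats::as.dist(dm))
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (root == "midpoint") tree <- phangorn::midpoint(tree)
  tree
}
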