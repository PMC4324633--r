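#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index computed from the contingency table;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) return(1)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Concordance between genotypic clusters and morpho-species labels
#'
#' Only MOTUs represented by more than one sequence are examined (the
#' single-specimen clusters cannot be checked morphologically). Members
#' without a usable label (`NA`, empty, or "species indet") are skipped
#' with a warning. A MOTU is `concordant` when all its labeled members
#' share one morpho-label and that label occurs in no other multi-member
#' MOTU; a MOTU spanning several labels is `lumped`; a pure MOTU whose
#' label also occurs elsewhere is `split` (the morpho-species is divided
#' across clusters). Concordance is thus one-to-one between MOTUs and
#' labels. The adjusted Rand index between the two partitions is reported
#' over the labeled members of multi-member MOTUs.
#'
#' @param motus A `motu_table`.
#' @param labels Named vector mapping sequence id to morpho-label.
#' @return A `concordance_report`: `verdicts` (data frame per MOTU),
#'   `counts`, `ari`, `offending` (data frame of split/lumped MOTU-label
#'   pairs).
#' @export
compare_partitions <- function(motus, labels) {
  mem <- motus$membership
  sizes <- table(mem$cluster_id)
  multi <- as.integer(names(sizes)[sizes > 1L])
  mem <- mem[mem$cluster_id %in% multi, , drop = FALSE]
  lab <- unname(labels[mem$member_id])
  usable <- !is.na(lab) & nzchar(lab) &
    !grepl("^species indet", lab, ignore.case = TRUE)
  if (any(!usable))
    warning(sum(!usable), " member(s) of multi-member MOTUs without a ",
            "usable morpho-label skipped")
  mem <- mem[usable, , drop = FALSE]
  lab <- lab[usable]
  if (nrow(mem) == 0L) {
    return(structure(list(
      verdicts = data.frame(cluster_id = integer(), verdict = character(),
                            labels = character(), stringsAsFactors = FALSE),
      counts = c(concordant = 0L, split = 0L, lumped = 0L),
      ari = NA_real_,
      offending = data.frame(cluster_id = integer(), morpho_label = character(),
                             stringsAsFactors = FALSE)),
      class = "concordance_report"))
  }
  by_cluster <- split(lab, mem$cluster_id)
  label_clusters <- split(mem$cluster_id, lab)
  verdict <- character(length(by_cluster))
  labstr <- vapply(by_cluster, function(x)
    paste(sort(unique(x)), collapse = "; "), "")
  for (i in seq_along(by_cluster)) {
    ls <- unique(by_cluster[[i]])
    if (length(ls) > 1L) verdict[i] <- "lumped"
    else if (length(unique(label_clusters[[ls]])) > 1L) verdict[i] <- "split"
    else verdict[i] <- "concordant"
  }
  verdicts <- data.frame(cluster_id = as.integer(names(by_cluster)),
                         verdict = verdict, labels = labstr,
                         stringsAsFactors = FALSE)
  off <- verdicts[verdicts$verdict != "concordant", c("cluster_id", "labels")]
  names(off)[2] <- "morpho_label"
  rownames(off) <- NULL
  structure(list(
    verdicts = verdicts,
    counts = c(concordant = sum(verdict == "concordant"),
               split = sum(verdict == "split"),
               lumped = sum(verdict == "lumped")),
    ari = adjusted_rand_index(mem$cluster_id, lab),
    offending = off), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance of genotypic clusters vs morpho-species:\n")
  cat(sprintf("  concordant %d, split %d, lumped %d (ARI %.3f)\n",
              x$counts["concordant"], x$counts["split"], x$counts["lumped"],
              x$ari))
  if (nrow(x$offending)) {
    cat("  discordant cases:\n")
    for (i in seq_len(nrow(x$offending)))
      cat(sprintf("    cluster %d <-> %s\n", x$offending$cluster_id[i],
                  x$offending$morpho_label[i]))
  }
  invisible(x)
}

#' Re-cluster across identity thresholds and score concordance
#'
#' Re-runs greedy clustering on the same input at each threshold
#' (descending, e.g. 0.97, 0.90, 0.80 as used when lowering the barcoding
#' threshold to chase discordant morpho-species) and reports cluster counts
#' and concordance per threshold.
#'
#' @param records A sequence record table.
#' @param labels Named vector id -> morpho-label.
#' @param thresholds Descending identity thresholds in (0, 1].
#' @param min_overlap Passed to [cluster_config()].
#' @param aligned Passed to [greedy_cluster()].
#' @return A data frame: `threshold`, `n_clusters`, `ari`, `n_concordant`,
#'   `n_split`, `n_lumped`.
#' @export
threshold_sweep <- function(records, labels, thresholds = c(0.97, 0.90, 0.80),
                            min_overlap = 400L, aligned = FALSE) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1),
            !is.unsorted(rev(thresholds)))
  out <- lapply(thresholds, function(t) {
    motus <- greedy_cluster(records, cluster_config(t, min_overlap),
                            aligned = aligned)
    rep <- suppressWarnings(compare_partitions(motus, labels))
    data.frame(threshold = t, n_clusters = nrow(motus$clusters),
               ari = rep$ari,
               n_concordant = unname(rep$counts["concordant"]),
               n_split = unname(rep$counts["split"]),
               n_lumped = unname(rep$counts["lumped"]))
  })
  do.call(rbind, out)
}
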