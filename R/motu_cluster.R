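#' Clustering configuration
#'
#' @param threshold Identity fraction in (0, 1]; default 0.97, the standard
#'   COI barcoding threshold.
#' @param min_overlap Minimum aligned overlap in bases, also the minimum
#'   sequence length for admission; default 400.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(threshold = 0.97, min_overlap = 400L) {
  stopifnot(threshold > 0, threshold <= 1, min_overlap >= 1)
  structure(list(threshold = threshold, min_overlap = as.integer(min_overlap),
                 tie_break = "first_hit"),
            class = "cluster_config")
}

#' Greedy incremental clustering of sequences into MOTUs
#'
#' Sequences are sorted by decreasing length (ties kept in input order) and
#' processed one by one: each sequence is compared to the existing cluster
#' representatives in cluster-creation order and joins the first one whose
#' identity is at least `threshold` with aligned overlap at least
#' `min_overlap`; otherwise it founds a new cluster and becomes its
#' representative. Identities are computed exactly (no word-filter
#' heuristic), so the procedure is deterministic for a fixed input order.
#' Sequences shorter than `min_overlap` are excluded with a warning.
#'
#' @param records A sequence record table.
#' @param config A [cluster_config()].
#' @param aligned Treat residues as rows of one multiple alignment (equal
#'   length, columns compared directly); otherwise pairs are globally
#'   aligned on demand.
#' @param scoring Aligner scoring when `aligned = FALSE`.
#' @return A `motu_table`: list with `clusters` (data frame `cluster_id`,
#'   `representative_id`, `size`), `membership` (data frame `member_id`,
#'   `cluster_id`, in assignment order), `config`, and `excluded_ids`.
#' @export
greedy_cluster <- function(records, config = cluster_config(),
                           aligned = FALSE, scoring = align_scoring()) {
  short <- records$length < config$min_overlap
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than min_overlap excluded")
  }
  excluded <- records$id[short]
  records <- records[!short, , drop = FALSE]
  n <- nrow(records)
  if (n == 0L) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(), representative_id = character(),
                            size = integer(), stringsAsFactors = FALSE),
      membership = data.frame(member_id = character(), cluster_id = integer(),
                              stringsAsFactors = FALSE),
      config = config, excluded_ids = excluded), class = "motu_table"))
  }
  if (aligned && length(unique(nchar(records$residues))) != 1L)
    stop("aligned = TRUE requires equal-length residues")
  ord <- order(-records$length)          # stable: ties keep input order
  records <- records[ord, , drop = FALSE]
  codes <- lapply(records$residues, encode_bases)
  nbase <- vapply(codes, function(v) sum(v > 0L), integer(1))

  rep_idx <- integer(0)                  # row index of each representative
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (k in seq_along(rep_idx)) {
      r <- rep_idx[k]
      if (aligned) {
        va <- codes[[i]]; vb <- codes[[r]]
        ok <- va > 0L & vb > 0L
        overlap <- sum(ok)
        if (overlap < config$min_overlap) next
        idn <- sum(va[ok] == vb[ok]) / min(nbase[i], nbase[r])
      } else {
        pair <- align_pair(records$residues[i], records$residues[r], scoring)
        pi <- pairwise_identity(pair)
        overlap <- pi$overlap
        if (overlap < config$min_overlap || is.na(pi$identity)) next
        idn <- pi$identity
      }
      if (idn >= config$threshold) { hit <- k; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_idx)
    }
    assign[i] <- hit
  }
  clusters <- data.frame(
    cluster_id = seq_along(rep_idx),
    representative_id = records$id[rep_idx],
    size = as.integer(tabulate(assign, length(rep_idx))),
    stringsAsFactors = FALSE)
  structure(list(
    clusters = clusters,
    membership = data.frame(member_id = records$id, cluster_id = assign,
                            stringsAsFactors = FALSE),
    config = config, excluded_ids = excluded), class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  cat("MOTU table:", nrow(x$clusters), "clusters over",
      nrow(x$membership), "sequences",
      sprintf("(threshold %.2f, min overlap %d)\n",
              x$config$threshold, x$config$min_overlap))
  cat(" singletons:", sum(x$clusters$size == 1L), "\n")
  invisible(x)
}

#' Station-by-MOTU abundance matrix
#'
#' @param motus A `motu_table`.
#' @param sample_map Named character vector mapping sequence id to
#'   station id (or a data frame with columns `id`, `station_id`).
#' @return An integer matrix, rows = stations, columns = MOTU cluster ids.
#' @export
build_abundance_matrix <- function(motus, sample_map) {
  if (is.data.frame(sample_map))
    sample_map <- stats::setNames(sample_map$station_id, sample_map$id)
  ids <- motus$membership$member_id
  unmapped <- ids[!ids %in% names(sample_map) | is.na(sample_map[ids])]
  if (length(unmapped)) stop("sequence(s) without station: ",
                             paste(utils::head(unmapped, 5), collapse = ", "))
  st <- sample_map[ids]
  tab <- table(station = st, motu = motus$membership$cluster_id)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Summary accounting of a MOTU partition
#'
#' Reports MOTU totals, singletons (exactly one sequence), and the
#' shared/exclusive split across license areas, in both the
#' all-MOTUs and multi-sequence-only framings.
#'
#' @param motus A `motu_table`.
#' @param sample_map Named vector id -> station (or data frame `id`,
#'   `station_id`).
#' @param area_map Named vector station -> license area.
#' @return A list of counts.
#' @export
summarize_motus <- function(motus, sample_map, area_map) {
  if (is.data.frame(sample_map))
    sample_map <- stats::setNames(sample_map$station_id, sample_map$id)
  areas <- sort(unique(unname(area_map)))
  member_area <- area_map[sample_map[motus$membership$member_id]]
  per_cluster <- split(member_area, motus$membership$cluster_id)
  per_cluster <- per_cluster[order(as.integer(names(per_cluster)))]
  sizes <- lengths(per_cluster)
  area_sets <- lapply(per_cluster, unique)
  n_areas <- lengths(area_sets)
  count_split <- function(keep) {
    shared <- sum(n_areas[keep] > 1L)
    excl <- vapply(areas, function(a)
      sum(n_areas[keep] == 1L &
            vapply(area_sets[keep], `[[`, "", 1L) == a), numeric(1))
    list(shared = shared, exclusive = as.list(excl))
  }
  all_f <- count_split(rep(TRUE, length(sizes)))
  multi_f <- count_split(sizes > 1L)
  list(
    n_motus = length(sizes),
    n_singletons = sum(sizes == 1L),
    n_multi = sum(sizes > 1L),
    singleton_fraction = mean(sizes == 1L),
    shared = all_f$shared, exclusive = all_f$exclusive,
    shared_multi = multi_f$shared, exclusive_multi = multi_f$exclusive)
}

#' Write a MOTU table to TSV files
#'
#' Emits `<prefix>_members.tsv` (cluster_id, member_id) and
#' `<prefix>_clusters.tsv` (per-cluster summary).
#'
#' @param motus A `motu_table`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_motu_table <- function(motus, prefix) {
  p1 <- paste0(prefix, "_members.tsv")
  p2 <- paste0(prefix, "_clusters.tsv")
  utils::write.table(motus$membership[, c("cluster_id", "member_id")], p1,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(motus$clusters, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
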