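#' Default alignment scoring
#'
#' Match/mismatch scores and affine gap penalties for the internal global
#' aligner: the first residue of a gap run costs `-gap_open`, each further
#' residue `-gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A named list.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -0.5) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Globally align two sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) of two sequence
#' records or raw strings. When a precomputed multiple alignment is
#' available, use [pair_from_alignment()] on its rows instead.
#'
#' @param a,b Sequence records (single-row data frames) or character strings.
#' @param scoring Scoring scheme from [align_scoring()].
#' @return An `aligned_pair`: list with character vectors `a`, `b` (aligned
#'   columns, gaps as `"-"`), the alignment `score`, and `overlap`, the
#'   number of columns where both entries are unambiguous bases.
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  sa <- if (is.data.frame(a)) a$residues[1L] else a
  sb <- if (is.data.frame(b)) b$residues[1L] else b
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gsub("-", "", sa)),
    Biostrings::DNAString(gsub("-", "", sb)),
    type = "global", substitutionMatrix = sm,
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  new_aligned_pair(pa, pb, score = Biostrings::score(aln))
}

#' Build an aligned pair from two rows of a multiple alignment
#'
#' @param a,b Equal-length aligned strings (gaps as `"-"`).
#' @return An `aligned_pair` (see [align_pair()]).
#' @export
pair_from_alignment <- function(a, b) {
  sa <- if (is.data.frame(a)) a$residues[1L] else a
  sb <- if (is.data.frame(b)) b$residues[1L] else b
  if (nchar(sa) != nchar(sb))
    stop("aligned sequences must have equal length")
  new_aligned_pair(strsplit(sa, "")[[1L]], strsplit(sb, "")[[1L]])
}

new_aligned_pair <- function(a, b, score = NA_real_) {
  va <- BASE_CODE[as.integer(charToRaw(paste(a, collapse = "")))]
  vb <- BASE_CODE[as.integer(charToRaw(paste(b, collapse = "")))]
  structure(list(a = a, b = b, code_a = va, code_b = vb,
                 overlap = sum(va > 0L & vb > 0L), score = score),
            class = "aligned_pair")
}

#' Site counts for the Kimura 2-parameter model
#'
#' Counts compared sites (both entries unambiguous A/C/G/T), transitions
#' (A–G, C–T) and transversions among them, plus the proportions `P` and `Q`
#' entering the K2P distance. Gap and ambiguity columns are dropped
#' (pairwise deletion).
#'
#' @param pair An `aligned_pair`.
#' @return A list with `n_sites`, `n_transitions`, `n_transversions`,
#'   `P`, `Q`.
#' @export
site_counts <- function(pair) {
  va <- pair$code_a; vb <- pair$code_b
  ok <- va > 0L & vb > 0L
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  mism <- va != vb
  # among mismatches, code sums 4 (A+G) and 6 (C+T) are the transitions
  s <- va[mism] + vb[mism]
  ts <- sum(s == 4L | s == 6L)
  tv <- sum(mism) - ts
  list(n_sites = n, n_transitions = ts, n_transversions = tv,
       P = if (n > 0L) ts / n else NA_real_,
       Q = if (n > 0L) tv / n else NA_real_)
}

#' Pairwise identity of an aligned pair
#'
#' Identity is the number of identical unambiguous columns divided by the
#' unambiguous length of the shorter sequence (the global-identity
#' convention of greedy clustering tools); `overlap` is the number of
#' columns with unambiguous bases on both sides, used by the minimum
#' length-coverage rule.
#'
#' @param pair An `aligned_pair`.
#' @return A list with `identity` (`NA` if the overlap is zero) and
#'   `overlap`.
#' @export
pairwise_identity <- function(pair) {
  va <- pair$code_a; vb <- pair$code_b
  ok <- va > 0L & vb > 0L
  matches <- sum(va[ok] == vb[ok])
  denom <- min(sum(va > 0L), sum(vb > 0L))
  if (denom == 0L || sum(ok) == 0L)
    return(list(identity = NA_real_, overlap = sum(ok)))
  list(identity = matches / denom, overlap = sum(ok))
}

#' Uncorrected p-distance
#'
#' Proportion of differing sites among compared sites (pairwise deletion of
#' gap/ambiguous columns). Returns `NA` if no sites are comparable.
#'
#' @param pair An `aligned_pair`.
#' @return A proportion in \[0, 1\], or `NA`.
#' @export
p_distance <- function(pair) {
  sc <- site_counts(pair)
  if (sc$n_sites == 0L) return(NA_real_)
  (sc$n_transitions + sc$n_transversions) / sc$n_sites
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions. Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are undefined and return `NA`.
#'
#' @param counts A list from [site_counts()], or a numeric `P`.
#' @param Q Transversion proportion when `counts` is numeric.
#' @return Distance in substitutions/site, or `NA`.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (is.list(counts)) {
    P <- counts$P; Q <- counts$Q
  } else P <- counts
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Labeled pairwise distance matrix over sequence records
#'
#' Computes every pairwise distance under a metric, with pairwise deletion
#' of gap/ambiguous sites. With `aligned = TRUE` the residues are taken as
#' rows of one multiple alignment (all equal length) and columns are
#' compared directly; otherwise each pair is globally aligned first. The
#' two modes are never mixed in one matrix. Undefined pairs (saturation,
#' zero overlap) are recorded as `NA` with a warning.
#'
#' @param records A sequence record table.
#' @param metric `"p"`, `"k2p"`, or `"identity"` (distance `1 - identity`).
#' @param aligned Treat residues as pre-aligned MSA rows.
#' @param scoring Scoring for the internal aligner when `aligned = FALSE`.
#' @return A symmetric matrix with zero diagonal, ids as dimnames, and a
#'   `"metric"` attribute.
#' @export
build_distance_matrix <- function(records, metric = c("p", "k2p", "identity"),
                                  aligned = FALSE,
                                  scoring = align_scoring()) {
  metric <- match.arg(metric)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  if (aligned && length(unique(nchar(records$residues))) != 1L)
    stop("aligned = TRUE requires equal-length residues")
  m <- matrix(0, n, n, dimnames = list(records$id, records$id))
  codes <- if (aligned) lapply(records$residues, encode_bases)
  nbase <- if (aligned) vapply(codes, function(v) sum(v > 0L), integer(1))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (aligned) {
        # fast columnwise path over precomputed base codes
        va <- codes[[i]]; vb <- codes[[j]]
        ok <- va > 0L & vb > 0L
        ns <- sum(ok)
        if (ns == 0L) { m[i, j] <- m[j, i] <- NA_real_; next }
        va <- va[ok]; vb <- vb[ok]
        mism <- va != vb
        d <- switch(metric,
          p = sum(mism) / ns,
          k2p = {
            s <- va[mism] + vb[mism]
            ts <- sum(s == 4L | s == 6L)
            k2p_distance(ts / ns, (sum(mism) - ts) / ns)
          },
          identity = 1 - sum(!mism) / min(nbase[i], nbase[j]))
      } else {
        pair <- align_pair(records$residues[i], records$residues[j], scoring)
        d <- switch(metric,
          p = p_distance(pair),
          k2p = k2p_distance(site_counts(pair)),
          identity = 1 - pairwise_identity(pair)$identity)
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  if (anyNA(m)) warning(sum(is.na(m)) / 2, " pair(s) with undefined ",
                        metric, " distance (recorded as NA)")
  attr(m, "metric") <- metric
  m
}

#' Within- and between-group mean distances
#'
#' Averages a distance matrix over unordered intra-group pairs (within) and
#' all cross pairs (between), reported in percent. Singleton groups have an
#' undefined within mean (`NA`).
#'
#' @param dm A labeled symmetric distance matrix.
#' @param groups Named character vector mapping every id to a group.
#' @return A data frame with `group1`, `group2` (equal on within rows),
#'   `mean_pct` and `n_pairs`.
#' @export
group_mean_distances <- function(dm, groups) {
  check_square_labeled(dm, "dm")
  ids <- rownames(dm)
  if (!all(ids %in% names(groups)))
    stop("unlabeled ids: ",
         paste(setdiff(ids, names(groups)), collapse = ", "))
  g <- groups[ids]
  gl <- sort(unique(g))
  out <- list()
  for (a in seq_along(gl)) {
    for (b in a:length(gl)) {
      ia <- which(g == gl[a]); ib <- which(g == gl[b])
      if (a == b) {
        if (length(ia) < 2L) { vals <- NA_real_; np <- 0L }
        else {
          sub <- dm[ia, ia, drop = FALSE]
          vals <- mean(sub[lower.tri(sub)])
          np <- length(ia) * (length(ia) - 1L) / 2L
        }
      } else {
        vals <- mean(dm[ia, ib])
        np <- length(ia) * length(ib)
      }
      out[[length(out) + 1L]] <- data.frame(
        group1 = gl[a], group2 = gl[b],
        mean_pct = 100 * vals, n_pairs = np, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
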