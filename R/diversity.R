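#' Chao1 abundance-based richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` when doubletons are present,
#' switching to the bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`
#' when `F2 = 0` (standard software behaviour). The standard deviation uses
#' the matching Chao variance formula. Chao estimators are lower bounds on
#' true richness.
#'
#' @param abundances Integer vector of per-MOTU abundances (zeros dropped).
#' @return A `richness_estimate` list: `S_obs`, `N`, `F1`, `F2`,
#'   `estimate`, `sd`, `estimator`.
#' @export
chao1 <- function(abundances) {
  x <- as.integer(abundances)
  if (any(x < 0)) stop("abundances must be nonnegative")
  x <- x[x > 0L]
  if (length(x) == 0L) stop("no observed MOTUs")
  S <- length(x); F1 <- sum(x == 1L); F2 <- sum(x == 2L)
  if (F2 > 0L) {
    est <- S + F1^2 / (2 * F2)
    r <- F1 / F2
    v <- F2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else if (F1 > 0L) {
    est <- S + F1 * (F1 - 1) / 2
    v <- F1 * (F1 - 1) / 2 + F1 * (2 * F1 - 1)^2 / 4 - F1^4 / (4 * est)
  } else {
    est <- S; v <- 0
  }
  structure(list(S_obs = S, N = sum(x), F1 = F1, F2 = F2,
                 estimate = est, sd = sqrt(max(v, 0)),
                 estimator = "Chao1"),
            class = "richness_estimate")
}

#' Chao2 incidence-based richness estimator
#'
#' As [chao1()] but on presence/absence over samples: `Q1`, `Q2` are the
#' numbers of MOTUs present in exactly one and exactly two samples.
#'
#' @param incidence Logical/0-1 matrix, rows = MOTUs, columns = samples
#'   (>= 2 samples).
#' @return A `richness_estimate` with `Q1`, `Q2` in place of `F1`, `F2`.
#' @export
chao2 <- function(incidence) {
  inc <- as.matrix(incidence) > 0
  m <- ncol(inc)
  if (m < 2L) stop("chao2 needs at least 2 samples")
  freq <- rowSums(inc)
  freq <- freq[freq > 0]
  S <- length(freq); Q1 <- sum(freq == 1); Q2 <- sum(freq == 2)
  if (Q2 > 0) {
    est <- S + Q1^2 / (2 * Q2)
    r <- Q1 / Q2
    v <- Q2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else if (Q1 > 0) {
    est <- S + Q1 * (Q1 - 1) / 2
    v <- Q1 * (Q1 - 1) / 2 + Q1 * (2 * Q1 - 1)^2 / 4 - Q1^4 / (4 * est)
  } else {
    est <- S; v <- 0
  }
  structure(list(S_obs = S, N = sum(inc), Q1 = Q1, Q2 = Q2, m = m,
                 estimate = est, sd = sqrt(max(v, 0)),
                 estimator = "Chao2"),
            class = "richness_estimate")
}

#' First-order jackknife richness estimator
#'
#' `S_obs + Q1 (m - 1) / m` with `Q1` the number of MOTUs present in
#' exactly one of `m` samples. No standard deviation is reported.
#'
#' @param incidence Logical/0-1 matrix, rows = MOTUs, columns = samples.
#' @return A `richness_estimate`.
#' @export
jackknife1 <- function(incidence) {
  inc <- as.matrix(incidence) > 0
  m <- ncol(inc)
  if (m < 2L) stop("jackknife1 needs at least 2 samples")
  freq <- rowSums(inc)
  freq <- freq[freq > 0]
  S <- length(freq); Q1 <- sum(freq == 1)
  structure(list(S_obs = S, N = sum(inc), Q1 = Q1, m = m,
                 estimate = S + Q1 * (m - 1) / m, sd = NA_real_,
                 estimator = "Jackknife1"),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(x$estimator, ": S_obs = ", x$S_obs, ", estimate = ",
      round(x$estimate, 1),
      if (!is.na(x$sd)) paste0(" +/- ", round(x$sd, 1)) else "",
      " (%registration ", registration(x$S_obs, x$estimate), ")\n", sep = "")
  invisible(x)
}

#' Percent registration (proportion of expected richness recovered)
#'
#' `100 * S_obs / estimate`, rounded half-up to one decimal.
#'
#' @param S_obs Observed richness.
#' @param estimate Extrapolated richness (> 0).
#' @return A percentage with one decimal.
#' @export
registration <- function(S_obs, estimate) {
  stopifnot(estimate > 0)
  if (estimate < S_obs)
    warning("estimate below S_obs; upstream estimator is suspect")
  floor(100 * S_obs / estimate * 10 + 0.5) / 10
}

#' Table of richness estimates per license area
#'
#' Computes Chao1, Chao2 and Jackknife 1 with percent registration for each
#' license area from a station-by-MOTU abundance matrix, pooling stations
#' within an area for the abundance estimator and using stations as the
#' incidence samples.
#'
#' @param cm Station-by-MOTU count matrix.
#' @param area_map Named vector station -> license area.
#' @return A data frame, one row per area x estimator.
#' @export
richness_table <- function(cm, area_map) {
  areas <- sort(unique(unname(area_map[rownames(cm)])))
  out <- list()
  for (a in areas) {
    sub <- cm[names(area_map)[area_map == a & names(area_map) %in%
                                rownames(cm)], , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    ests <- list(chao1(colSums(sub)), chao2(t(sub) > 0), jackknife1(t(sub) > 0))
    for (e in ests) {
      out[[length(out) + 1L]] <- data.frame(
        area = a, estimator = e$estimator, S_obs = e$S_obs, N = sum(sub),
        estimate = e$estimate, sd = e$sd,
        registration_pct = registration(e$S_obs, e$estimate),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
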