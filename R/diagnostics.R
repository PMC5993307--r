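#' Assemble a bilateral cohort
#'
#' A cohort holds, per subject, one full set of coefficient maps per
#' breast, the disease group and (for cancer subjects) tumor laterality.
#'
#' @param subjects A list; each element a list with `id`, `group`
#'   (`"cancer"` or `"non_cancer"`), `laterality` (`"left"`, `"right"`,
#'   or `"none"`), and `left`/`right`: named lists of `hb_map`s (as
#'   returned by [transition_coefficients()]).
#' @return An object of class `hb_cohort`.
#' @export
hb_cohort <- function(subjects) {
  for (s in subjects) {
    stopifnot(all(c("id", "group", "laterality", "left", "right") %in% names(s)))
    if (!s$group %in% c("cancer", "non_cancer")) stop("unknown group label")
    if (s$group == "cancer" && !s$laterality %in% c("left", "right"))
      stop("cancer subjects need tumor laterality 'left' or 'right'")
    if (s$group == "non_cancer" && s$laterality != "none")
      stop("non-cancer subjects must have laterality 'none'")
  }
  structure(list(subjects = subjects), class = "hb_cohort")
}

#' @export
print.hb_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("hb_cohort: %d subjects (%d cancer, %d non-cancer)\n",
              length(grp), sum(grp == "cancer"), sum(grp == "non_cancer")))
  invisible(x)
}

.cohort_maps <- function(cohort, kind, side) {
  lapply(cohort$subjects, function(s) unclass(s[[side]][[kind]]))
}

# cell-wise mean over a list of 10x10 matrices, skipping NA
.cellwise_mean <- function(maps) {
  arr <- array(unlist(maps), dim = c(10, 10, length(maps)))
  apply(arr, c(1, 2), mean, na.rm = TRUE)
}

#' Laterality-corrected inter-breast difference metric
#'
#' For non-cancer and left-tumor subjects the metric is the relative
#' percent left-right difference
#' \deqn{Z = 100 (Y^l - Y^r) / Y^r.}
#' For right-tumor subjects, so that the tumor-bearing breast always
#' plays the "left" role, the breasts are exchanged after removing the
#' population left-right bias estimated from the non-cancer group
#' (cell-wise means \eqn{\bar Y^{NC}_l, \bar Y^{NC}_r}):
#' \deqn{Z = 100 \frac{[Y^r - \bar Y^{NC}_r + \bar Y^{NC}_l] -
#'   [Y^l - \bar Y^{NC}_l + \bar Y^{NC}_r]}
#'   {Y^l - \bar Y^{NC}_l + \bar Y^{NC}_r}.}
#'
#' @param cohort An [hb_cohort()].
#' @param kind Name of the coefficient map to use (e.g. `"k"`,
#'   `"k_phi_S"`), as stored in each subject's per-breast map list.
#' @param nc_reference Optional list with `left`, `right` 10 x 10
#'   matrices of non-cancer cell means; computed from the cohort's
#'   non-cancer subjects when omitted.
#' @return Named list of per-subject `hb_map`s of kind `Z` (percent);
#'   cells with zero denominator are `NA`.
#' @export
z_metric <- function(cohort, kind, nc_reference = NULL) {
  stopifnot(inherits(cohort, "hb_cohort"))
  grp <- vapply(cohort$subjects, `[[`, "", "group")
  if (is.null(nc_reference)) {
    nc <- cohort$subjects[grp == "non_cancer"]
    if (length(nc) == 0L)
      stop("no non-cancer subjects to form the reference means")
    nc_reference <- list(
      left = .cellwise_mean(lapply(nc, function(s) unclass(s$left[[kind]]))),
      right = .cellwise_mean(lapply(nc, function(s) unclass(s$right[[kind]]))))
  }
  out <- lapply(cohort$subjects, function(s) {
    Yl <- unclass(s$left[[kind]])
    Yr <- unclass(s$right[[kind]])
    if (identical(s$laterality, "right")) {
      num <- (Yr - nc_reference$right + nc_reference$left) -
             (Yl - nc_reference$left + nc_reference$right)
      den <- Yl - nc_reference$left + nc_reference$right
    } else {
      num <- Yl - Yr
      den <- Yr
    }
    z <- 100 * num / den
    z[!is.na(den) & den == 0] <- NA_real_
    hb_map(z, kind = "Z", units = "%")
  })
  stats::setNames(out, vapply(cohort$subjects, function(s) as.character(s$id), ""))
}

# per-subject inter-breast differences: tumor-minus-unaffected for cancer,
# left-minus-right for non-cancer
.breast_differences <- function(cohort, kind) {
  lapply(cohort$subjects, function(s) {
    Yl <- unclass(s$left[[kind]])
    Yr <- unclass(s$right[[kind]])
    if (identical(s$laterality, "right")) Yr - Yl else Yl - Yr
  })
}

#' Cell-wise group-comparison t-test map
#'
#' Per off-diagonal cell, a two-sided two-sample Student t-test (pooled
#' variance) comparing the tumor-minus-unaffected inter-breast
#' differences of the cancer group against the left-minus-right
#' differences of the non-cancer group.
#'
#' @param cohort An [hb_cohort()].
#' @param kind Coefficient map name (see [z_metric()]).
#' @return An `hb_map` of two-sided p-values (kind `pvalue`); cells with
#'   fewer than two defined values in either group are `NA`.
#' @export
group_difference_ttests <- function(cohort, kind) {
  stopifnot(inherits(cohort, "hb_cohort"))
  grp <- vapply(cohort$subjects, `[[`, "", "group")
  d <- .breast_differences(cohort, kind)
  dc <- array(unlist(d[grp == "cancer"]), dim = c(10, 10, sum(grp == "cancer")))
  dn <- array(unlist(d[grp == "non_cancer"]),
              dim = c(10, 10, sum(grp == "non_cancer")))
  p <- matrix(NA_real_, 10, 10)
  for (f in 1:10) for (i in 1:10) {
    if (f == i) next
    a <- dc[f, i, ]; a <- a[!is.na(a)]
    b <- dn[f, i, ]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p[f, i] <- if (mean(a) == mean(b)) 1 else NA_real_
      next
    }
    p[f, i] <- stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  hb_map(p, kind = "pvalue", units = "")
}

#' Rank-sum AUC for two samples (percent)
#'
#' Mann-Whitney identity with midrank tie handling:
#' `AUC = 100 * (R1 - n1 (n1 + 1) / 2) / (n1 n2)`, where `R1` is the rank
#' sum of the positive sample -- equal to the probability (in percent)
#' that a positive value exceeds a negative one, counting ties as half.
#'
#' @param positive,negative Numeric vectors (NA dropped).
#' @return AUC in percent, or `NA` if either sample is empty.
#' @export
rank_sum_auc <- function(positive, negative) {
  positive <- positive[!is.na(positive)]
  negative <- negative[!is.na(negative)]
  n1 <- length(positive); n2 <- length(negative)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(positive, negative))
  100 * (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC area-under-curve map for a diagnostic metric
#'
#' Per off-diagonal cell, the rank-sum AUC comparing the cancer group's
#' Z values (positive class) against the non-cancer group's. The stored
#' value is the raw oriented AUC; `fold = TRUE` returns
#' `max(AUC, 100 - AUC)` instead.
#'
#' @param Z_cancer,Z_noncancer Lists of per-subject `Z` maps
#'   (subsets of a [z_metric()] result).
#' @param fold Report the fold-oriented AUC (default `FALSE`).
#' @return An `hb_map` of kind `AUC` (percent).
#' @export
roc_auc_map <- function(Z_cancer, Z_noncancer, fold = FALSE) {
  zc <- array(unlist(lapply(Z_cancer, unclass)),
              dim = c(10, 10, length(Z_cancer)))
  zn <- array(unlist(lapply(Z_noncancer, unclass)),
              dim = c(10, 10, length(Z_noncancer)))
  a <- matrix(NA_real_, 10, 10)
  for (f in 1:10) for (i in 1:10) {
    if (f == i) next
    a[f, i] <- rank_sum_auc(zc[f, i, ], zn[f, i, ])
  }
  if (fold) a <- pmax(a, 100 - a)
  hb_map(a, kind = "AUC", units = "%")
}
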