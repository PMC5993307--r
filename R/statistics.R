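#' Observed state volume fractions
#'
#' Percentage of defined voxel-time samples occupied by each state,
#' i.e. the time-averaged fraction of tissue volume residing in each
#' state. Sums to 100 over the ten states.
#'
#' @param states An `hb_states` object or integer label matrix in `0:10`.
#' @return Numeric 10-vector of percentages (names `1:10`).
#' @export
volume_fractions <- function(states) {
  labels <- if (inherits(states, "hb_states")) states$labels else states
  defined <- labels[labels > 0L]
  if (length(defined) == 0L) stop("no defined samples")
  stats::setNames(100 * tabulate(defined, nbins = 10L) / length(defined),
                  1:10)
}

#' Volume fractions predicted by the first-order kinetic model
#'
#' Under first-order kinetics the occupancy of state j is proportional to
#' the dwell-weighted outflow from j:
#' \deqn{V_j = K \sum_i P_{ij} / k_{ij}, \quad
#'       K = 100 / \sum_j \sum_i P_{ij} / k_{ij},}
#' where maps are indexed (row = final, column = initial), so the sum for
#' state j runs down column j. Replacing `1/k` by `tau` gives the
#' equivalent matrix form \eqn{V = K \, \mathrm{diag}(P^\top \tau)}.
#'
#' @param P An `hb_map` of kind `P`.
#' @param k_or_tau An `hb_map` of kind `k` (any time unit) or `tau`;
#'   interpreted by its `kind` attribute.
#' @return List with `V` (10-vector of percentages) and `K`.
#' @export
predicted_volume_fractions <- function(P, k_or_tau) {
  Pv <- unclass(P)
  tv <- unclass(k_or_tau)
  if (identical(attr(k_or_tau, "kind"), "k")) tv <- 1 / tv
  w <- Pv * tv                       # P_ij * tau_ij, cell-wise
  w[is.na(w)] <- 0                   # missing cells contribute nothing
  raw <- colSums(w)                  # column j = outflow from state j
  tot <- sum(raw)
  if (tot == 0) stop("all cells missing or zero")
  K <- 100 / tot
  list(V = stats::setNames(K * raw, 1:10), K = K)
}

#' Mean relative percent discrepancy between observed and predicted
#' volume fractions
#'
#' @param V_obs,V_pred Numeric 10-vectors of percentages (`V_pred` may be
#'   a [predicted_volume_fractions()] result).
#' @return Mean over states of `100 * (V_obs - V_pred) / V_obs`; states
#'   with zero observed volume are excluded with a warning.
#' @export
model_discrepancy <- function(V_obs, V_pred) {
  if (is.list(V_pred)) V_pred <- V_pred$V
  stopifnot(length(V_obs) == length(V_pred))
  keep <- V_obs != 0
  if (!all(keep)) warning("states with zero observed volume excluded")
  mean(100 * (V_obs[keep] - V_pred[keep]) / V_obs[keep])
}

#' Mean component amplitudes per state
#'
#' Per-state means of the measured deviations over all samples in the
#' state, with the dependent components evaluated at the mean point
#' (exact for `dT`/`dE`/linearized `dS` by linearity).
#'
#' @param dD,dO Voxel x time matrices.
#' @param states Matching `hb_states` object or label matrix.
#' @param geometry An [hb_geometry()] object.
#' @return Data frame with columns `state`, `n`, `dD`, `dO`, `dT`, `dE`,
#'   `dS`; empty states carry `NA` means.
#' @export
state_mean_amplitudes <- function(dD, dO, states, geometry = hb_geometry()) {
  labels <- if (inherits(states, "hb_states")) states$labels else states
  stopifnot(identical(dim(labels), dim(dD)), identical(dim(dD), dim(dO)))
  idx <- factor(labels, levels = 1:10)
  n <- as.integer(table(idx))
  mD <- as.numeric(tapply(dD, idx, mean))
  mO <- as.numeric(tapply(dO, idx, mean))
  comp <- dependent_components(ifelse(is.na(mD), 0, mD),
                               ifelse(is.na(mO), 0, mO), geometry)
  data.frame(state = 1:10, n = n, dD = mD, dO = mO,
             dT = ifelse(is.na(mD), NA_real_, comp$dT),
             dE = ifelse(is.na(mD), NA_real_, comp$dE),
             dS = ifelse(is.na(mD), NA_real_, comp$dS))
}

#' Exchange-to-volume ratio of the state mean points
#'
#' Dimensionless ratio `dE / dT` of each state's mean point -- the
#' magnitude of the oxygen-exchange "stimulus" relative to the
#' blood-volume "response". Invariant to radial scaling of the mean.
#'
#' @param means A [state_mean_amplitudes()] data frame.
#' @return Numeric 10-vector; `NA` where `dT` is 0 or the state is empty.
#' @export
exchange_to_volume_ratio <- function(means) {
  r <- ifelse(!is.na(means$dT) & means$dT != 0, means$dE / means$dT, NA_real_)
  stats::setNames(r, means$state)
}

# common defined off-diagonal cells of two maps
.paired_offdiag <- function(mapA, mapB) {
  a <- off_diagonal(mapA)
  b <- off_diagonal(mapB)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no common defined off-diagonal cells")
  list(a = a[keep], b = b[keep], n = sum(keep))
}

#' Normalized root-mean-squared difference between two coefficient maps
#'
#' \deqn{\mathrm{nRMSD}(\alpha,\beta) =
#'   \sqrt{\sum(\alpha-\beta)^2 / [(\sum\alpha^2 + \sum\beta^2)/2]}}
#' over the common defined off-diagonal cells (90 for fully defined
#' maps). Zero iff the maps are equal; at most 2 (attained at
#' \eqn{\beta = -\alpha}); invariant to a common rescaling.
#'
#' @param mapA,mapB `hb_map`s (or 10 x 10 matrices) of the same kind.
#' @return Scalar with attribute `n_cells` (number of cells compared).
#' @export
nrmsd <- function(mapA, mapB) {
  p <- .paired_offdiag(mapA, mapB)
  denom <- (sum(p$a^2) + sum(p$b^2)) / 2
  if (denom == 0) return(structure(0, n_cells = p$n))
  structure(sqrt(sum((p$a - p$b)^2) / denom), n_cells = p$n)
}

#' Pearson correlation between two coefficient maps
#'
#' Spatial correlation of the common defined off-diagonal cells.
#'
#' @param mapA,mapB `hb_map`s (or 10 x 10 matrices).
#' @return Scalar with attribute `n_cells`.
#' @export
map_correlation <- function(mapA, mapB) {
  p <- .paired_offdiag(mapA, mapB)
  if (p$n < 3L) stop("need at least 3 common defined cells")
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("zero variance in a map's defined cells")
  structure(stats::cor(p$a, p$b), n_cells = p$n)
}

#' t-score of a tumor-pairing index against control pairings
#'
#' Expresses how far the similarity index for the tumor/unaffected
#' pairing lies from the three control-breast pairings, in units of
#' their SD (n-1 denominator): `(x - mean(controls)) / sd(controls)`.
#'
#' @param value_TU Index value for the tumor-vs-unaffected pairing.
#' @param values_controls Index values for the control pairings
#'   (typically 3: L-R, L-U, R-U).
#' @return Scalar t-score.
#' @export
tscore_index <- function(value_TU, values_controls) {
  stopifnot(length(values_controls) >= 2L)
  z <- stats::sd(values_controls)
  if (z == 0) stop("control pairings have zero spread")
  (value_TU - mean(values_controls)) / z
}

#' Mass-action regression of flux on amplitude difference
#'
#' Ordinary least-squares fit of the intrinsic flux to the difference
#' between post- and pre-transition mean amplitudes across the defined
#' off-diagonal cells. A linear dependence with slope near 1 indicates
#' the fluxes behave as first-order (mass-action) processes. Note that
#' when all three maps come from a single accumulator the identity
#' `phi = post - pre` makes the fit exact; slopes below 1 arise only when
#' the inputs are averaged independently (e.g. group-mean maps), so the
#' three maps are accepted as independent arguments.
#'
#' @param phi Flux `hb_map` (response).
#' @param pre_amp,post_amp Amplitude `hb_map`s (the predictor is their
#'   difference).
#' @return List with `slope`, `intercept`, `correlation`, `n_cells`.
#' @export
mass_action_regression <- function(phi, pre_amp, post_amp) {
  y <- off_diagonal(phi)
  x <- off_diagonal(post_amp) - off_diagonal(pre_amp)
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stop("need at least 3 defined cells")
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0) stop("degenerate predictor: amplitude difference constant")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       correlation = stats::cor(x, y),
       n_cells = sum(keep))
}
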