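#' Geometry of the ten-state hemoglobin coordinate system
#'
#' The co-varying hemoglobin signal is described by five components:
#' the two measured concentration deviations \eqn{\Delta O} (oxyHb) and
#' \eqn{\Delta D} (deoxyHb), and three dependent quantities -- total
#' hemoglobin \eqn{\Delta T = \Delta D + \Delta O}, tissue-oxygen exchange
#' \eqn{\Delta E = \Delta D - \Delta O}, and oxygen saturation
#' \eqn{\Delta S}. The zero sets of the five components are five straight
#' lines through the origin of the \eqn{(\Delta D, \Delta O)} plane,
#' partitioning it into ten angular sectors; each sector is one "Hb state"
#' with a unique realizable permutation of the five algebraic signs.
#'
#' `hb_geometry()` builds the configuration holding the mean tissue
#' oxygen saturation `s0` (percent) and baseline total hemoglobin
#' concentration `t0` (mol/L). `t0` enters only the saturation
#' *amplitude*; state assignment depends on `s0` alone.
#'
#' @param s0 Mean hemoglobin oxygen saturation in percent, in (0, 100).
#' @param t0 Baseline total hemoglobin concentration (mol/L), > 0.
#' @param saturation_mode `"linearized"` (default) computes the saturation
#'   deviation by first-order expansion, whose zero set is the straight
#'   demarcation line of the sector geometry; `"exact"` evaluates
#'   \eqn{100 (O_0 + \Delta O)/(T_0 + \Delta T) - S_0}.
#' @return An object of class `hb_geometry`: a list with elements `s0`,
#'   `t0`, `o0`, `d0`, `saturation_mode`.
#' @examples
#' g <- hb_geometry(s0 = 85)
#' demarcation_angle(85)
#' @export
hb_geometry <- function(s0 = 85, t0 = 1e-4,
                        saturation_mode = c("linearized", "exact")) {
  saturation_mode <- match.arg(saturation_mode)
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) ||
      s0 <= 0 || s0 >= 100)
    stop("`s0` must be a single finite value strictly between 0 and 100")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 <= 0)
    stop("`t0` must be a single positive finite value")
  structure(list(s0 = s0, t0 = t0,
                 o0 = t0 * s0 / 100, d0 = t0 * (100 - s0) / 100,
                 saturation_mode = saturation_mode),
            class = "hb_geometry")
}

#' @export
print.hb_geometry <- function(x, ...) {
  cat(sprintf("hb_geometry: S0 = %g%%, T0 = %g mol/L (%s saturation)\n",
              x$s0, x$t0, x$saturation_mode))
  cat(sprintf("  saturation demarcation at %.4f deg from the deoxyHb axis\n",
              demarcation_angle(x$s0)))
  invisible(x)
}

#' Inclination of the saturation demarcation line
#'
#' Angle, measured from the \eqn{\Delta D} (deoxyHb) axis, of the line on
#' which the saturation deviation is zero: \eqn{\tan^{-1}(S_0/(100-S_0))}.
#'
#' @param s0 Mean oxygen saturation in percent, in (0, 100).
#' @return Angle in degrees, in (0, 90).
#' @export
demarcation_angle <- function(s0) {
  if (!is.numeric(s0) || any(!is.finite(s0)) || any(s0 <= 0) || any(s0 >= 100))
    stop("`s0` must be strictly between 0 and 100")
  atan(s0 / (100 - s0)) * 180 / pi
}

#' Dependent components of the hemoglobin signal
#'
#' From the two measured deviations computes all five co-varying
#' components. The saturation deviation defaults to the first-order
#' linearization \deqn{\Delta S = (100/T_0)(\Delta O - (S_0/100)\Delta T),}
#' which has the same sign structure as the sector geometry; the exact
#' form is available through the geometry's `saturation_mode`.
#'
#' @param dD,dO Numeric vectors/matrices of deoxyHb and oxyHb deviations
#'   from their temporal means (mol/L); shapes must match.
#' @param geometry An [hb_geometry()] object.
#' @return A list with elements `dO`, `dD`, `dT`, `dE`, `dS` of the common
#'   input shape (component order O, D, T, E, S; `dS` in percent).
#' @export
dependent_components <- function(dD, dO, geometry = hb_geometry()) {
  stopifnot(inherits(geometry, "hb_geometry"))
  if (!identical(dim(dD), dim(dO)) || length(dD) != length(dO))
    stop("`dD` and `dO` must have identical shapes")
  if (any(!is.finite(dD)) || any(!is.finite(dO)))
    stop("non-finite values in input")
  dT <- dD + dO
  dE <- dD - dO
  if (geometry$saturation_mode == "exact") {
    tot <- geometry$t0 + dT
    if (any(tot <= 0))
      stop("invalid baseline: T0 + dT must be positive in exact mode")
    dS <- 100 * (geometry$o0 + dO) / tot - geometry$s0
  } else {
    dS <- (100 / geometry$t0) * (dO - (geometry$s0 / 100) * dT)
  }
  list(dO = dO, dD = dD, dT = dT, dE = dE, dS = dS)
}

# Sector boundaries (degrees, counter-clockwise from the +dD axis) and the
# state label of the half-open sector [boundary[k], boundary[k+1]).
# Labels run 6..10 counter-clockwise through the upper half-plane (dO > 0)
# and 1..5 through their antipodes; for the physiological regime S0 > 50
# (demarcation line between the dE = 0 and dD = 0 lines) this reproduces
# the canonical sign table.
.sector_geometry <- function(s0) {
  aS <- demarcation_angle(s0)
  half <- sort(unique(c(0, 45, aS, 90, 135)))
  k <- length(half)                       # 4 when S0 = 50 (lines coincide)
  list(bounds = c(half, half + 180),
       labels = as.integer(c(5 + 1:k, 1:k)))
}

#' Assign hemoglobin states from measured deviations
#'
#' Classifies each \eqn{(\Delta D, \Delta O)} sample into one of the ten
#' sectors of the state geometry. Sector membership is decided by the
#' direction angle `atan2(dO, dD)` binned into half-open arcs
#' `[lower, upper)` anchored at the five boundary lines, so samples lying
#' exactly on a boundary receive a deterministic label. The origin (both
#' deviations zero) has no direction and maps to the sentinel `0`.
#'
#' @param dD,dO Numeric vectors or matrices of equal shape (deviations
#'   from temporal means).
#' @param geometry An [hb_geometry()] object.
#' @return Integer labels in `0:10`, same shape as the input.
#' @export
assign_state <- function(dD, dO, geometry = hb_geometry()) {
  stopifnot(inherits(geometry, "hb_geometry"))
  if (!identical(dim(dD), dim(dO)) || length(dD) != length(dO))
    stop("`dD` and `dO` must have identical shapes")
  if (any(!is.finite(dD)) || any(!is.finite(dO)))
    stop("non-finite values in input")
  geo <- .sector_geometry(geometry$s0)
  theta <- atan2(dO, dD) * 180 / pi
  theta <- theta %% 360
  idx <- findInterval(theta, geo$bounds)
  idx[idx == 0L] <- 1L        # guard: theta is always in [0, 360)
  out <- geo$labels[idx]
  out[dD == 0 & dO == 0] <- 0L
  if (!is.null(dim(dD))) dim(out) <- dim(dD)
  out
}

#' Assign states across a voxel-by-time series
#'
#' Element-wise [assign_state()] over a voxel x time pair of matrices,
#' packaged with the sampling rate for downstream transition analysis.
#' Inputs are expected to be deviations from the temporal mean (i.e.
#' already detrended, see [linear_detrend()]).
#'
#' @param dD,dO Voxel x time numeric matrices of equal dimension.
#' @param geometry An [hb_geometry()] object.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `hb_states`: list with `labels` (integer
#'   matrix in `0:10`), `n_voxels`, `n_frames`, `sampling_rate`.
#' @export
assign_state_series <- function(dD, dO, geometry = hb_geometry(),
                                sampling_rate = 1.8) {
  if (!is.matrix(dD) || !is.matrix(dO) || !identical(dim(dD), dim(dO)))
    stop("`dD` and `dO` must be matrices of identical dimension")
  labels <- assign_state(dD, dO, geometry)
  structure(list(labels = labels,
                 n_voxels = nrow(dD), n_frames = ncol(dD),
                 sampling_rate = sampling_rate),
            class = "hb_states")
}

#' @export
print.hb_states <- function(x, ...) {
  tab <- tabulate(x$labels[x$labels > 0L], nbins = 10L)
  cat(sprintf("hb_states: %d voxels x %d frames at %g Hz (%d undefined samples)\n",
              x$n_voxels, x$n_frames, x$sampling_rate, sum(x$labels == 0L)))
  cat("  samples per state:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Canonical sign table of the ten states
#'
#' The algebraic sign (+1/-1) of each of the five components within each
#' state's sector, in component order (O, D, T, E, S). States 1--5 are the
#' antipodes (sign negations) of states 6--10.
#'
#' @param geometry An [hb_geometry()] object (any valid `s0` yields the
#'   same table; the geometry fixes only the sector widths).
#' @return A 10 x 5 integer matrix of +1/-1 with dimnames
#'   `state` x `c("O","D","T","E","S")`.
#' @export
state_sign_table <- function(geometry = hb_geometry()) {
  upper <- matrix(c(  # states 6..10, read off the sector interiors
    +1, +1, +1, +1, -1,   # 6
    +1, +1, +1, -1, -1,   # 7
    +1, +1, +1, -1, +1,   # 8
    +1, -1, +1, -1, +1,   # 9
    +1, -1, -1, -1, +1),  # 10
    nrow = 5, byrow = TRUE)
  tab <- rbind(-upper, upper)
  dimnames(tab) <- list(state = 1:10, component = c("O", "D", "T", "E", "S"))
  storage.mode(tab) <- "integer"
  tab
}

#' Enumerate the realizable sign patterns by angular sweep
#'
#' Sweeps directions around the origin at the requested angular
#' resolution, computes the five-component sign pattern at each direction
#' (skipping the boundary lines themselves), and returns the set of
#' distinct realizable patterns. Of the 32 conceivable five-sign
#' permutations only 10 are geometrically realizable for any
#' \eqn{0 < S_0 < 100}.
#'
#' @param geometry An [hb_geometry()] object.
#' @param angular_resolution Sweep step in degrees (default 0.01).
#' @return List with `n_realizable`, `patterns` (matrix of +1/-1 rows,
#'   one per realized pattern, ordered by the state label of the
#'   direction that produced it), and `states` (the corresponding labels).
#' @export
enumerate_realizable_states <- function(geometry = hb_geometry(),
                                        angular_resolution = 0.01) {
  stopifnot(angular_resolution > 0, angular_resolution <= 0.01)
  theta <- seq(0, 360, by = angular_resolution)
  dD <- cospi(theta / 180)
  dO <- sinpi(theta / 180)
  comp <- dependent_components(dD, dO, geometry)
  sgn <- cbind(O = sign(comp$dO), D = sign(comp$dD), T = sign(comp$dT),
               E = sign(comp$dE), S = sign(comp$dS))
  interior <- rowSums(sgn == 0) == 0      # drop directions on a boundary line
  sgn <- sgn[interior, , drop = FALSE]
  st <- assign_state(dD[interior], dO[interior], geometry)
  key <- sgn %*% 2L^(4:0)
  first <- !duplicated(key)
  ord <- order(st[first])
  patterns <- sgn[first, , drop = FALSE][ord, , drop = FALSE]
  states <- st[first][ord]
  rownames(patterns) <- states
  storage.mode(patterns) <- "integer"
  list(n_realizable = nrow(patterns), patterns = patterns, states = states)
}

#' Forced-sign regions of the component flux maps
#'
#' For component `X`, a transition from a state where `X` is below its
#' temporal mean into one where it is above must increase `X` (forced
#' positive flux), and conversely. Cells where the pre- and
#' post-transition signs agree are unconstrained.
#'
#' @param component One of `"O","D","T","E","S"`.
#' @param geometry An [hb_geometry()] object.
#' @return A 10 x 10 integer matrix (rows = final state, columns =
#'   initial state): +1 where flux is forced positive, -1 forced
#'   negative, 0 unconstrained; diagonal `NA`.
#' @export
flux_sign_regions <- function(component = c("O", "D", "T", "E", "S"),
                              geometry = hb_geometry()) {
  component <- match.arg(component)
  s <- state_sign_table(geometry)[, component]
  pre <- matrix(s, 10, 10, byrow = TRUE)   # column = initial state
  post <- matrix(s, 10, 10)                # row = final state
  out <- matrix(0L, 10, 10)
  out[pre < 0 & post > 0] <- 1L
  out[pre > 0 & post < 0] <- -1L
  diag(out) <- NA_integer_
  dimnames(out) <- list(to = 1:10, from = 1:10)
  out
}
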