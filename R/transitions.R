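#' Count state transitions with variable dwell times
#'
#' Scans every voxel's label series for direct transitions between
#' distinct states. Lag-resolved counts land in the 10 x 10 x N array
#' `A_TC` (row = final state f, column = initial state i, layer = dwell n
#' in frames); for each supplied component X, the accumulator `A_X`
#' receives the change X(post) - X(pre) between the first frames of the
#' post- and pre-transition intervals, and `pre_sum`/`post_sum` collect
#' the respective component values for the amplitude maps. Runs reaching
#' the end of the series without a change are not counted; undefined
#' labels (0) terminate the current run and contribute nothing.
#'
#' The lag dimension is allocated at `max(n_max, longest counted dwell)`,
#' so no transition is ever dropped for dwelling too long.
#'
#' @param states An [assign_state_series()] result (`hb_states`), or a
#'   plain integer voxel x time matrix with labels in `0:10`.
#' @param components Optional named list of voxel x time matrices
#'   (any subset of `O`, `D`, `T`, `E`, `S`, as produced by
#'   [dependent_components()]) sharing the label matrix's shape.
#' @param n_max Minimum number of lag layers to allocate (default 60).
#' @param sampling_rate Sampling rate in Hz; taken from `states` when it
#'   is an `hb_states` object.
#' @return An object of class `hb_accumulator`: list with `A_TC`, `A_X`
#'   (named list of component accumulators), `pre_sum`/`post_sum` (named
#'   lists of 10 x 10 matrices), `counts` (lag-summed 10 x 10 matrix),
#'   `n_transitions`, `N`, `sampling_rate`.
#' @export
accumulate_transitions <- function(states, components = NULL, n_max = 60L,
                                   sampling_rate = NULL) {
  if (inherits(states, "hb_states")) {
    if (is.null(sampling_rate)) sampling_rate <- states$sampling_rate
    labels <- states$labels
  } else {
    labels <- states
    if (is.null(sampling_rate)) sampling_rate <- 1.8
  }
  if (!is.matrix(labels)) stop("`states` must carry a voxel x time matrix")
  storage.mode(labels) <- "integer"
  if (ncol(labels) < 2L) stop("transition analysis needs n_frames >= 2")
  if (anyNA(labels) || any(labels < 0L) || any(labels > 10L))
    stop("labels must lie in 0..10")
  comp_names <- character(0)
  if (!is.null(components)) {
    comp_names <- names(components)
    if (is.null(comp_names) || any(!comp_names %in% c("O", "D", "T", "E", "S")))
      stop("`components` must be a named list with names among O, D, T, E, S")
    for (m in components)
      if (!is.matrix(m) || !identical(dim(m), dim(labels)))
        stop("every component matrix must match the label matrix's shape")
  }
  n_alloc <- max(as.integer(n_max), .max_counted_dwell(labels), 1L)
  raw <- .scan_transitions(labels, unname(as.list(components)), n_alloc)
  dimnames2 <- list(to = 1:10, from = 1:10)
  a_tc <- raw$a_tc
  counts <- matrix(rowSums(matrix(a_tc, 100L)), 10L, 10L, dimnames = dimnames2)
  a_x <- pre_sum <- post_sum <- stats::setNames(vector("list", length(comp_names)),
                                                comp_names)
  for (ci in seq_along(comp_names)) {
    a_x[[ci]] <- raw$a_x[[ci]]
    pre_sum[[ci]] <- matrix(raw$pre_sum[, (ci - 1L) * 10L + 1:10],
                            10L, 10L, dimnames = dimnames2)
    post_sum[[ci]] <- matrix(raw$post_sum[, (ci - 1L) * 10L + 1:10],
                             10L, 10L, dimnames = dimnames2)
  }
  structure(list(A_TC = a_tc, A_X = a_x,
                 pre_sum = pre_sum, post_sum = post_sum,
                 counts = counts, n_transitions = sum(counts),
                 N = n_alloc, sampling_rate = sampling_rate),
            class = "hb_accumulator")
}

#' @export
print.hb_accumulator <- function(x, ...) {
  cat(sprintf("hb_accumulator: %d transitions, lag depth N = %d, %g Hz\n",
              x$n_transitions, x$N, x$sampling_rate))
  if (length(x$A_X))
    cat("  components accumulated:", paste(names(x$A_X), collapse = ", "), "\n")
  invisible(x)
}

# ---- coefficient-map container -------------------------------------------

#' Construct a labelled 10 x 10 coefficient map
#'
#' @param values 10 x 10 numeric matrix (row = final state, column =
#'   initial state); the diagonal is masked to `NA`.
#' @param kind Coefficient kind label (e.g. `"P"`, `"tau"`, `"k"`,
#'   `"phi"`, `"m"`, `"k_phi"`, `"k_m"`, `"V"`, `"pre_amp"`, `"post_amp"`,
#'   `"Z"`, `"AUC"`, `"pvalue"`, `"asymmetry"`).
#' @param component Hb component the map refers to (`"O","D","T","E","S"`
#'   or `NA`).
#' @param units Unit label.
#' @return An `hb_map`: a numeric matrix with attributes `kind`,
#'   `component`, `units`.
#' @export
hb_map <- function(values, kind, component = NA_character_, units = "") {
  stopifnot(is.matrix(values), identical(dim(values), c(10L, 10L)))
  diag(values) <- NA_real_
  dimnames(values) <- list(to = 1:10, from = 1:10)
  structure(values, kind = kind, component = component, units = units,
            class = c("hb_map", "matrix", "array"))
}

#' @export
print.hb_map <- function(x, digits = 4, ...) {
  comp <- attr(x, "component")
  cat(sprintf("hb_map <%s%s>%s, %d defined cells\n", attr(x, "kind"),
              if (!is.na(comp)) paste0("_", comp) else "",
              if (nzchar(attr(x, "units"))) paste0(" [", attr(x, "units"), "]") else "",
              sum(!is.na(x)) ))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Off-diagonal values of a coefficient map
#'
#' @param x An `hb_map` or 10 x 10 matrix.
#' @return The 90 off-diagonal values (column-major order), `NA` where
#'   undefined.
#' @export
off_diagonal <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  unclass(x)[row(x) != col(x)]
}

# lag-summed count / component sums from an accumulator
.lag_sums <- function(a) {
  n_count <- matrix(rowSums(matrix(a$A_TC, 100L)), 10L, 10L)
  n_weight <- matrix(matrix(a$A_TC, 100L) %*% seq_len(a$N), 10L, 10L)
  list(count = n_count, weighted = n_weight)
}

.check_acc <- function(acc) {
  if (!inherits(acc, "hb_accumulator"))
    stop("expected an `hb_accumulator` (see accumulate_transitions())")
}

.get_component <- function(acc, component) {
  if (!component %in% names(acc$A_X))
    stop(sprintf("component %s was not accumulated", component))
  matrix(rowSums(matrix(acc$A_X[[component]], 100L)), 10L, 10L)
}

# ---- transition coefficients ---------------------------------------------

#' Transition probabilities (percent)
#'
#' Lag-summed counts for each ordered state pair, normalized so the 90
#' off-diagonal cells sum to exactly 100 -- placing maps from subjects
#' with different recording durations and voxel counts on a common scale.
#'
#' @param acc An [accumulate_transitions()] result.
#' @return An `hb_map` of kind `P` (percent).
#' @export
transition_probability <- function(acc) {
  .check_acc(acc)
  if (acc$n_transitions == 0L)
    stop("empty accumulator: no transitions recorded")
  hb_map(100 * acc$counts / acc$n_transitions, kind = "P", units = "%")
}

#' Mean dwell lag per transition type (frames)
#'
#' Count-weighted mean of the dwell lag for each ordered state pair;
#' cells with no recorded transitions are `NA`.
#'
#' @param acc An [accumulate_transitions()] result.
#' @return An `hb_map` of kind `tau` (frames), entries >= 1 where defined.
#' @export
mean_lag <- function(acc) {
  .check_acc(acc)
  s <- .lag_sums(acc)
  hb_map(ifelse(s$count > 0, s$weighted / s$count, NA_real_),
         kind = "tau", units = "frames")
}

#' Transition rate constants
#'
#' Reciprocal of the mean dwell lag, optionally converted from
#' frames^-1 to s^-1 by the sampling rate. Bounded above by the
#' sampling rate (dwell is at least one frame).
#'
#' @param acc An [accumulate_transitions()] result.
#' @param in_hz Convert to s^-1 (default `TRUE`).
#' @return An `hb_map` of kind `k`.
#' @export
rate_constants <- function(acc, in_hz = TRUE) {
  .check_acc(acc)
  tau <- unclass(mean_lag(acc))
  scale <- if (in_hz) acc$sampling_rate else 1
  hb_map(scale / tau, kind = "k", units = if (in_hz) "1/s" else "1/frame")
}

#' Intrinsic transition flux of a component
#'
#' Mean change in the component's concentration (or saturation) per
#' transition of each ordered type: the component accumulator divided by
#' the transition count, cell-wise. In cells where the component's sign
#' is opposite in the initial and final states the flux sign is forced
#' (negative-to-positive cells are strictly positive and conversely); see
#' [flux_sign_regions()].
#'
#' @param acc An [accumulate_transitions()] result with the component
#'   accumulated.
#' @param component One of `"O","D","T","E","S"`.
#' @return An `hb_map` of kind `phi` (mol/L, or percent for `S`).
#' @export
intrinsic_flux <- function(acc, component = c("O", "D", "T", "E", "S")) {
  .check_acc(acc)
  component <- match.arg(component)
  ax <- .get_component(acc, component)
  hb_map(ifelse(acc$counts > 0, ax / acc$counts, NA_real_),
         kind = "phi", component = component,
         units = if (component == "S") "%" else "mol/L")
}

#' Transition mass of a component
#'
#' Product of transition probability and intrinsic flux: the average
#' amount of the component moved by transitions of each type whenever
#' 100 transitions of all types occur.
#'
#' @param P An `hb_map` of kind `P`.
#' @param phi An `hb_map` of kind `phi`.
#' @return An `hb_map` of kind `m`.
#' @export
transition_mass <- function(P, phi) {
  hb_map(unclass(P) * unclass(phi), kind = "m",
         component = attr(phi, "component"), units = attr(phi, "units"))
}

#' Rate-weighted flux and mass coefficients
#'
#' Element-wise products `k * phi` and `k * m`, expressing the component
#' changes per unit time rather than per transition.
#'
#' @param k An `hb_map` of kind `k`.
#' @param phi An `hb_map` of kind `phi`.
#' @param m An `hb_map` of kind `m` (default `transition_mass(P, phi)`
#'   cannot be formed here, so pass it explicitly).
#' @return List with `k_phi` and `k_m` maps.
#' @export
weighted_coefficients <- function(k, phi, m) {
  comp <- attr(phi, "component")
  per <- sub("^1/", "", attr(k, "units"))
  u <- paste0(attr(phi, "units"), "/", per)
  list(k_phi = hb_map(unclass(k) * unclass(phi), kind = "k_phi",
                      component = comp, units = u),
       k_m = hb_map(unclass(k) * unclass(m), kind = "k_m",
                    component = comp, units = u))
}

#' Mean pre- and post-transition component amplitudes
#'
#' Average component value at the first frame of the pre-transition
#' interval (column = the state dwelt in) and at the first frame of the
#' post-transition interval (row = the state entered), per transition
#' type. The identity `post_amp - pre_amp = phi` holds exactly.
#'
#' @param acc An [accumulate_transitions()] result with the component
#'   accumulated.
#' @param component One of `"O","D","T","E","S"`.
#' @return List with `pre_amp` and `post_amp` maps.
#' @export
pre_post_amplitudes <- function(acc, component = c("O", "D", "T", "E", "S")) {
  .check_acc(acc)
  component <- match.arg(component)
  if (!component %in% names(acc$pre_sum))
    stop(sprintf("component %s was not accumulated", component))
  u <- if (component == "S") "%" else "mol/L"
  cnt <- acc$counts
  list(pre_amp = hb_map(ifelse(cnt > 0, acc$pre_sum[[component]] / cnt, NA_real_),
                        kind = "pre_amp", component = component, units = u),
       post_amp = hb_map(ifelse(cnt > 0, acc$post_sum[[component]] / cnt, NA_real_),
                         kind = "post_amp", component = component, units = u))
}

#' Ohm-analogy voltages of the transition network
#'
#' Treating the rate constant as a conductance and the transition
#' probability (or the transition mass) as a current, the voltage
#' analogue is `V = k / P` (or `V = k * phi / P` for a component-change
#' current). Cells with `P = 0` are undefined.
#'
#' @param k An `hb_map` of kind `k`.
#' @param P An `hb_map` of kind `P`.
#' @param phi Optional `hb_map` of kind `phi`; when supplied the
#'   component voltage `k * phi / P` is returned.
#' @return An `hb_map` of kind `V`.
#' @export
ohmic_voltages <- function(k, P, phi = NULL) {
  Pv <- unclass(P)
  Pv[Pv == 0] <- NA_real_
  if (is.null(phi))
    hb_map(unclass(k) / Pv, kind = "V_TC", units = attr(k, "units"))
  else
    hb_map(unclass(k) * unclass(phi) / Pv, kind = "V",
           component = attr(phi, "component"),
           units = paste0(attr(phi, "units"), "*", attr(k, "units")))
}

#' Asymmetry between reciprocal transitions
#'
#' For any coefficient map, the difference `Y(f,i) - Y(i,f)` between each
#' ordered pair and its reverse; the result is antisymmetric.
#'
#' @param Y An `hb_map` (or square matrix).
#' @return An `hb_map` of kind `asymmetry`.
#' @export
asymmetry_map <- function(Y) {
  v <- unclass(Y)
  hb_map(v - t(v), kind = "asymmetry", component = attr(Y, "component"),
         units = attr(Y, "units"))
}

#' All transition coefficient maps for one breast
#'
#' Convenience pipeline: assigns states, accumulates transitions with all
#' five components, and returns every coefficient map.
#'
#' @param dD,dO Detrended voxel x time matrices.
#' @param geometry An [hb_geometry()] object.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_max Minimum lag depth.
#' @param in_hz Report `k` in s^-1.
#' @return Named list: `P`, `tau`, `k`, and per component `phi_X`, `m_X`,
#'   `k_phi_X`, `k_m_X`, `pre_amp_X`, `post_amp_X`; plus `V_TC`,
#'   `states`, `accumulator`.
#' @export
transition_coefficients <- function(dD, dO, geometry = hb_geometry(),
                                    sampling_rate = 1.8, n_max = 60L,
                                    in_hz = TRUE) {
  states <- assign_state_series(dD, dO, geometry, sampling_rate)
  comp <- dependent_components(dD, dO, geometry)
  acc <- accumulate_transitions(states,
                                components = list(O = comp$dO, D = comp$dD,
                                                  T = comp$dT, E = comp$dE,
                                                  S = comp$dS),
                                n_max = n_max)
  P <- transition_probability(acc)
  tau <- mean_lag(acc)
  k <- rate_constants(acc, in_hz = in_hz)
  out <- list(P = P, tau = tau, k = k, V_TC = ohmic_voltages(k, P))
  for (X in c("O", "D", "T", "E", "S")) {
    phi <- intrinsic_flux(acc, X)
    m <- transition_mass(P, phi)
    w <- weighted_coefficients(k, phi, m)
    amps <- pre_post_amplitudes(acc, X)
    out[[paste0("phi_", X)]] <- phi
    out[[paste0("m_", X)]] <- m
    out[[paste0("k_phi_", X)]] <- w$k_phi
    out[[paste0("k_m_", X)]] <- w$k_m
    out[[paste0("pre_amp_", X)]] <- amps$pre_amp
    out[[paste0("post_amp_", X)]] <- amps$post_amp
  }
  out$states <- states
  out$accumulator <- acc
  out
}
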