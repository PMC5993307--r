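#' Configuration for the semi-Markov resting-state simulator
#'
#' The generator emulates resting-state hemoglobin fluctuations about a
#' zero temporal mean: per voxel an embedded jump chain moves between the
#' ten states, dwelling in each for a geometrically distributed number of
#' frames (the discrete-time analogue of first-order kinetics), and each
#' sample receives a (dD, dO) amplitude drawn inside its state's sector.
#'
#' Defaults reflect a resting-state breast recording: 1.8 Hz sampling,
#' five minutes of data (540 frames), mean dwells of 1.1--1.6 frames
#' (equivalent rate constants of about 1.1--1.6 s^-1), jump preferences
#' decaying with angular distance between sectors, and amplitude clouds
#' of a few micromolar.
#'
#' @param n_voxels,n_frames Series dimensions.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed; every simulation derived from this config is
#'   reproducible.
#' @param jump_matrix 10 x 10 matrix of next-state probabilities with the
#'   map convention (row = next state f, column = current state i):
#'   columns sum to 1, diagonal 0. Default favours transitions between
#'   angularly nearby sectors.
#' @param dwell_means Mean dwell in frames: a scalar, a 10-vector (per
#'   current state), or a 10 x 10 matrix per (f, i) pair; all entries
#'   >= 1.
#' @param amplitude_radius Mean distance from the origin (mol/L): scalar
#'   or per-state 10-vector.
#' @param amplitude_noise SD of the radial noise (mol/L).
#' @param geometry An [hb_geometry()] object.
#' @param disease_effect List with multipliers `dwell` and `amplitude`
#'   applied to the tumor-bearing breast of cancer subjects.
#' @return An object of class `hb_sim_config`.
#' @export
hb_sim_config <- function(n_voxels = 50L, n_frames = 540L,
                          sampling_rate = 1.8, seed = 1L,
                          jump_matrix = default_jump_matrix(),
                          dwell_means = seq(1.1, 1.6, length.out = 10),
                          amplitude_radius = 2e-6,
                          amplitude_noise = 5e-7,
                          geometry = hb_geometry(),
                          disease_effect = list(dwell = 0.8, amplitude = 1.5)) {
  stopifnot(n_voxels >= 1L, n_frames >= 2L, sampling_rate > 0)
  jump_matrix <- as.matrix(jump_matrix)
  if (!identical(dim(jump_matrix), c(10L, 10L)) ||
      any(abs(colSums(jump_matrix) - 1) > 1e-10) ||
      any(diag(jump_matrix) != 0) || any(jump_matrix < 0))
    stop("`jump_matrix` must be 10 x 10, non-negative, zero-diagonal, with columns summing to 1")
  dw <- dwell_means
  if (length(dw) == 1L) dw <- matrix(dw, 10, 10)
  else if (is.null(dim(dw)) && length(dw) == 10L)
    dw <- matrix(dw, 10, 10, byrow = TRUE)   # column = current state
  else if (!identical(dim(dw), c(10L, 10L)))
    stop("`dwell_means` must be a scalar, a 10-vector, or a 10 x 10 matrix")
  if (any(dw < 1)) stop("`dwell_means` must be >= 1 frame")
  if (length(amplitude_radius) == 1L) amplitude_radius <- rep(amplitude_radius, 10)
  stopifnot(length(amplitude_radius) == 10L, all(amplitude_radius > 0),
            amplitude_noise >= 0)
  structure(list(n_voxels = as.integer(n_voxels),
                 n_frames = as.integer(n_frames),
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 jump_matrix = jump_matrix, dwell_means = dw,
                 amplitude_radius = amplitude_radius,
                 amplitude_noise = amplitude_noise,
                 geometry = geometry, disease_effect = disease_effect),
            class = "hb_sim_config")
}

#' Default jump matrix favouring angularly adjacent states
#'
#' Next-state probabilities decay exponentially with the circular
#' distance between sectors on the 10-cycle (`exp(-d/2)`), normalized per
#' current state with zero self-probability.
#'
#' @return A 10 x 10 column-stochastic matrix, zero diagonal.
#' @export
default_jump_matrix <- function() {
  d <- abs(outer(1:10, 1:10, "-"))
  d <- pmin(d, 10 - d)
  w <- exp(-d / 2)
  diag(w) <- 0
  sweep(w, 2, colSums(w), "/")
}

#' Simulate the state label series
#'
#' Runs the embedded jump chain with geometric dwells independently per
#' voxel; initial states are drawn uniformly. Reproducible under the
#' config seed.
#'
#' @param config An [hb_sim_config()].
#' @return An `hb_states` object.
#' @export
simulate_state_chain <- function(config) {
  stopifnot(inherits(config, "hb_sim_config"))
  set.seed(config$seed)
  cumjump <- apply(config$jump_matrix, 2, cumsum)
  labels <- matrix(0L, config$n_voxels, config$n_frames)
  # initial states from the embedded chain's stationary distribution
  # (power iteration), so unreachable states never seed a voxel
  pi0 <- rep(1 / 10, 10)
  for (it in 1:400)   # lazy-chain damping handles periodic jump structures
    pi0 <- 0.5 * (pi0 + as.vector(config$jump_matrix %*% pi0))
  pi0 <- pmax(pi0, 0); pi0 <- pi0 / sum(pi0)
  starts <- sample.int(10L, config$n_voxels, replace = TRUE, prob = pi0)
  for (v in seq_len(config$n_voxels))
    labels[v, ] <- .simulate_chain_voxel(config$n_frames, cumjump,
                                         config$dwell_means, starts[v])
  structure(list(labels = labels, n_voxels = config$n_voxels,
                 n_frames = config$n_frames,
                 sampling_rate = config$sampling_rate),
            class = "hb_states")
}

#' Realize (dD, dO) amplitudes for a label series
#'
#' Each sample receives a direction drawn uniformly within its state's
#' sector -- inset by a 1% margin of the sector width on either side, so
#' that [assign_state()] recovers the input labels exactly despite
#' floating-point rounding -- and a radius `amplitude_radius + noise`
#' (redrawn while non-positive). Samples labelled 0 get (0, 0).
#'
#' @param states An `hb_states` object or label matrix.
#' @param config An [hb_sim_config()] (supplies amplitudes and geometry).
#' @param reseed Call `set.seed(config$seed + 1)` first (default `TRUE`;
#'   set `FALSE` when embedding inside a longer seeded stream).
#' @return List with matrices `dD`, `dO`.
#' @export
embed_amplitudes <- function(states, config, reseed = TRUE) {
  stopifnot(inherits(config, "hb_sim_config"))
  labels <- if (inherits(states, "hb_states")) states$labels else states
  if (reseed) set.seed(config$seed + 1L)
  geo <- .sector_geometry(config$geometry$s0)
  lower <- geo$bounds
  upper <- c(geo$bounds[-1], 360)
  width <- upper - lower
  # per state label: sector bounds with the interior margin
  ord <- match(1:10, geo$labels)
  lo <- lower[ord] + 0.01 * width[ord]
  hi <- upper[ord] - 0.01 * width[ord]
  dD <- dO <- array(0, dim = dim(labels))
  def <- which(labels > 0L)
  s <- labels[def]
  theta <- stats::runif(length(def), lo[s], hi[s])
  r <- config$amplitude_radius[s] +
    config$amplitude_noise * stats::rnorm(length(def))
  while (any(bad <- r <= 0))
    r[bad] <- config$amplitude_radius[s[bad]] +
      config$amplitude_noise * stats::rnorm(sum(bad))
  dD[def] <- r * cospi(theta / 180)
  dO[def] <- r * sinpi(theta / 180)
  list(dD = dD, dO = dO)
}

#' Simulate one breast's voxel time series
#'
#' Chain plus amplitudes in one call.
#'
#' @param config An [hb_sim_config()].
#' @return List with `dD`, `dO`, `states`.
#' @export
simulate_breast <- function(config) {
  states <- simulate_state_chain(config)
  amp <- embed_amplitudes(states, config)
  list(dD = amp$dD, dO = amp$dO, states = states)
}

# apply the disease multipliers to a config (tumor-bearing breast)
.apply_disease <- function(config) {
  dw <- pmax(config$dwell_means * config$disease_effect$dwell, 1)
  config$dwell_means <- dw
  config$amplitude_radius <- config$amplitude_radius *
    config$disease_effect$amplitude
  config
}

#' Simulate a bilateral cohort to disk
#'
#' Writes per-subject, per-breast `dD`/`dO` matrices as CSV files plus a
#' manifest CSV (`subject_id, group, laterality, path_dD_left,
#' path_dO_left, path_dD_right, path_dO_right`). Cancer subjects have the
#' disease multipliers applied to the tumor side. Each (subject, breast)
#' stream gets its own counter-derived seed, so outputs are identical for
#' a given config seed regardless of generation order.
#'
#' @param config An [hb_sim_config()]; its `seed` governs the whole
#'   cohort.
#' @param n_cancer,n_noncancer Group sizes (defaults follow a cohort of
#'   18 cancer and 45 non-cancer subjects).
#' @param laterality Tumor sides for the cancer subjects: a character
#'   vector of length `n_cancer`, or a named count vector like
#'   `c(left = 12, right = 6)`; `NULL` assigns a 2:1 left:right split
#'   (the study's 12/6 proportion).
#' @param dir Output directory (created if needed).
#' @return The manifest as a data frame (invisibly also written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
simulate_cohort <- function(config, n_cancer = 18L, n_noncancer = 45L,
                            laterality = NULL,
                            dir = tempfile("hb_cohort_")) {
  stopifnot(inherits(config, "hb_sim_config"), n_cancer >= 0, n_noncancer >= 0)
  laterality <- .resolve_laterality(laterality, n_cancer)
  if (n_cancer > 0 && length(laterality) != n_cancer)
    stop("`laterality` must give a tumor side for each cancer subject")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c(rep("cancer", n_cancer), rep("non_cancer", n_noncancer))
  sides <- c(laterality[seq_len(n_cancer)], rep("none", n_noncancer))
  rows <- vector("list", length(groups))
  counter <- 0L
  for (j in seq_along(groups)) {
    id <- sprintf("S%03d", j)
    paths <- character(4)
    names(paths) <- c("dD_left", "dO_left", "dD_right", "dO_right")
    for (side in c("left", "right")) {
      counter <- counter + 1L
      cfg <- config
      cfg$seed <- (config$seed + 7919L * counter) %% 2147483647L
      tumor_here <- (groups[j] == "cancer" && sides[j] == side)
      if (tumor_here) cfg <- .apply_disease(cfg)
      b <- simulate_breast(cfg)
      pD <- file.path(dir, sprintf("%s_%s_dD.csv", id, side))
      pO <- file.path(dir, sprintf("%s_%s_dO.csv", id, side))
      utils::write.table(b$dD, pD, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(b$dO, pO, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      paths[paste0("dD_", side)] <- pD
      paths[paste0("dO_", side)] <- pO
    }
    rows[[j]] <- data.frame(subject_id = id, group = groups[j],
                            laterality = sides[j],
                            path_dD_left = paths["dD_left"],
                            path_dO_left = paths["dO_left"],
                            path_dD_right = paths["dD_right"],
                            path_dO_right = paths["dO_right"],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Build an in-memory cohort of coefficient maps from a simulation
#'
#' Convenience wrapper used by the diagnostic machinery and tests:
#' simulates every subject's two breasts (without touching disk) and
#' computes the full coefficient-map set per breast.
#'
#' @inheritParams simulate_cohort
#' @return An [hb_cohort()].
#' @export
simulate_cohort_maps <- function(config, n_cancer = 18L, n_noncancer = 45L,
                                 laterality = NULL) {
  stopifnot(inherits(config, "hb_sim_config"))
  laterality <- .resolve_laterality(laterality, n_cancer)
  if (n_cancer > 0 && length(laterality) != n_cancer)
    stop("`laterality` must give a tumor side for each cancer subject")
  groups <- c(rep("cancer", n_cancer), rep("non_cancer", n_noncancer))
  sides <- c(laterality[seq_len(n_cancer)], rep("none", n_noncancer))
  counter <- 0L
  subjects <- vector("list", length(groups))
  for (j in seq_along(groups)) {
    maps <- list()
    for (side in c("left", "right")) {
      counter <- counter + 1L
      cfg <- config
      cfg$seed <- (config$seed + 7919L * counter) %% 2147483647L
      if (groups[j] == "cancer" && sides[j] == side)
        cfg <- .apply_disease(cfg)
      b <- simulate_breast(cfg)
      maps[[side]] <- transition_coefficients(b$dD, b$dO, cfg$geometry,
                                              cfg$sampling_rate)
    }
    subjects[[j]] <- list(id = sprintf("S%03d", j), group = groups[j],
                          laterality = sides[j],
                          left = maps$left, right = maps$right)
  }
  hb_cohort(subjects)
}

.resolve_laterality <- function(laterality, n_cancer) {
  if (is.null(laterality)) {
    n_left <- ceiling(2 * n_cancer / 3)
    laterality <- rep(c("left", "right"), c(n_left, n_cancer - n_left))
  }
  if (!is.null(names(laterality)))
    laterality <- rep(names(laterality), times = laterality)
  as.character(laterality)
}
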