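test_that("the scanner reproduces the hand-traced accumulator", {
  lab <- matrix(c(1L, 1L, 2L, 2L, 2L, 7L), 1)
  acc <- accumulate_transitions(lab)
  expect_identical(acc$N, 60L)
  expect_equal(acc$A_TC[2, 1, 2], 1L)
  expect_equal(acc$A_TC[7, 2, 3], 1L)
  expect_equal(acc$n_transitions, 2L)
  expect_true(all(acc$A_TC[cbind(1:10, 1:10, 1)] == 0L))

  # constant sequence: nothing to count
  expect_equal(accumulate_transitions(matrix(3L, 2, 50))$n_transitions, 0L)

  # component increments, Eq-5 style
  accO <- accumulate_transitions(matrix(c(1L, 2L), 1),
                                 components = list(O = matrix(c(-1, 2), 1)))
  expect_equal(sum(accO$A_X$O), 3)
  expect_equal(accO$pre_sum$O[2, 1], -1)
  expect_equal(accO$post_sum$O[2, 1], 2)
})

test_that("undefined labels break runs without contributing transitions", {
  lab <- matrix(c(1L, 1L, 0L, 2L, 2L, 3L), 1)
  acc <- accumulate_transitions(lab)
  expect_equal(acc$n_transitions, 1L)        # only 2 -> 3
  expect_equal(acc$counts[3, 2], 1L)
  # interruption splits a would-be run
  acc2 <- accumulate_transitions(matrix(c(1L, 0L, 1L, 2L), 1))
  expect_equal(acc2$counts[2, 1], 1L)
  expect_equal(sum(acc2$A_TC[2, 1, ]), 1L)
  expect_equal(acc2$A_TC[2, 1, 1], 1L)       # dwell restarts after the gap
})

test_that("dwells longer than the default lag depth are kept", {
  lab <- matrix(c(rep(1L, 100), 2L), 1)
  acc <- accumulate_transitions(lab, n_max = 60L)
  expect_gte(acc$N, 100L)
  expect_equal(acc$A_TC[2, 1, 100], 1L)
})

test_that("scanner agrees with the run-length-encoding oracle", {
  set.seed(21)
  for (rep in 1:25) {
    lab <- random_labels(4, 60)
    acc <- accumulate_transitions(lab, n_max = 60L)
    expect_identical(as.vector(acc$A_TC),
                     as.vector(oracle_accumulate(lab, acc$N)))
  }
})

test_that("transition probabilities normalize to 100", {
  lab <- matrix(c(1L, 1L, 2L, 2L, 2L, 7L), 1)
  P <- transition_probability(accumulate_transitions(lab))
  expect_equal(P[2, 1], 50)
  expect_equal(P[7, 2], 50)
  single <- transition_probability(accumulate_transitions(matrix(c(4L, 9L), 1)))
  expect_equal(single[9, 4], 100)
  set.seed(22)
  Pr <- transition_probability(accumulate_transitions(random_labels(5, 200)))
  expect_equal(sum(off_diagonal(Pr), na.rm = TRUE), 100)
  expect_true(all(off_diagonal(Pr) >= 0, na.rm = TRUE))
  expect_error(transition_probability(accumulate_transitions(matrix(1L, 1, 5))),
               "empty")
})

test_that("mean lag is the count-weighted dwell and scales out of counts", {
  lab <- rbind(c(1L, 1L, 2L, 2L, 2L),    # dwell 2 before 1 -> 2
               c(1L, 1L, 1L, 1L, 2L))    # dwell 4 before 1 -> 2
  tau <- mean_lag(accumulate_transitions(lab))
  expect_equal(tau[2, 1], 3)
  tau1 <- mean_lag(accumulate_transitions(matrix(c(5L, 6L), 1)))
  expect_equal(tau1[6, 5], 1)
  # scaling all counts leaves tau unchanged
  acc <- accumulate_transitions(lab)
  acc2 <- acc; acc2$A_TC <- acc$A_TC * 3L
  expect_equal(unclass(mean_lag(acc2)), unclass(mean_lag(acc)))
  expect_true(all(off_diagonal(tau) >= 1, na.rm = TRUE))
})

test_that("rate constants invert the lag and respect the sampling-rate bound", {
  lab <- matrix(c(1L, 1L, 2L), 1)
  acc <- accumulate_transitions(lab, sampling_rate = 1.8)
  expect_equal(rate_constants(acc)[2, 1], 0.9)           # 1.8 / 2
  expect_equal(rate_constants(acc, in_hz = FALSE)[2, 1], 0.5)
  k1 <- rate_constants(accumulate_transitions(matrix(c(1L, 2L), 1)))
  expect_equal(k1[2, 1], 1.8)                            # tau = 1 bound
  set.seed(23)
  k <- rate_constants(accumulate_transitions(random_labels(5, 300)))
  expect_true(all(off_diagonal(k) <= 1.8 + 1e-12, na.rm = TRUE))
  expect_true(all(off_diagonal(k) > 0, na.rm = TRUE))
  tau <- mean_lag(accumulate_transitions(matrix(c(1L, 1L), 1)))
  expect_true(all(is.na(off_diagonal(tau))))             # missing propagates
})

test_that("intrinsic flux averages the per-transition component change", {
  acc <- accumulate_transitions(matrix(c(1L, 2L), 1),
                                components = list(O = matrix(c(-1, 2), 1)))
  expect_equal(intrinsic_flux(acc, "O")[2, 1], 3)
  acc2 <- accumulate_transitions(matrix(c(1L, 2L, 1L, 2L), 1),
                                 components = list(O = matrix(c(0, 1, 0, 3), 1)))
  # changes +1, -1, +3 across transitions 1->2, 2->1, 1->2
  expect_equal(intrinsic_flux(acc2, "O")[2, 1], 2)
  expect_error(intrinsic_flux(acc, "D"), "not accumulated")
})

test_that("flux signs are forced in the sign-change regions on any input", {
  set.seed(24)
  cfg <- hb_sim_config(n_voxels = 10, n_frames = 400, seed = 24)
  b <- simulate_breast(cfg)
  maps <- transition_coefficients(b$dD, b$dO, cfg$geometry)
  for (X in c("O", "D", "T", "E", "S")) {
    phi <- unclass(maps[[paste0("phi_", X)]])
    fr <- flux_sign_regions(X)
    pos <- !is.na(phi) & !is.na(fr) & fr == 1L
    neg <- !is.na(phi) & !is.na(fr) & fr == -1L
    expect_true(all(phi[pos] > 0))
    expect_true(all(phi[neg] < 0))
  }
})

test_that("transition mass and weighted coefficients obey their algebra", {
  set.seed(25)
  cfg <- hb_sim_config(n_voxels = 8, n_frames = 300, seed = 25)
  b <- simulate_breast(cfg)
  st <- assign_state_series(b$dD, b$dO, cfg$geometry)
  comp <- dependent_components(b$dD, b$dO, cfg$geometry)
  acc <- accumulate_transitions(st, components = list(T = comp$dT))
  P <- transition_probability(acc)
  phi <- intrinsic_flux(acc, "T")
  m <- transition_mass(P, phi)
  expect_equal(unclass(m), unclass(P) * unclass(phi), ignore_attr = TRUE)
  # grand mean change per transition: sum(m)/100
  expect_equal(sum(off_diagonal(m), na.rm = TRUE) / 100,
               sum(acc$A_X$T) / acc$n_transitions)

  k <- rate_constants(acc, in_hz = FALSE)
  w <- weighted_coefficients(k, phi, m)
  # right-hand identity: k*phi = sum A_X / sum n * A_TC, cell-wise
  ax <- matrix(rowSums(matrix(acc$A_X$T, 100)), 10)
  nw <- matrix(matrix(acc$A_TC, 100) %*% seq_len(acc$N), 10)
  off <- row(nw) != col(nw) & nw > 0
  expect_equal(unclass(w$k_phi)[off], (ax / nw)[off])
  # k*m = 100 * k*phi * cell count / total count
  cnt <- acc$counts
  expect_equal(unclass(w$k_m)[off],
               (100 * unclass(w$k_phi) * cnt / acc$n_transitions)[off])
})

test_that("pre/post amplitudes reconstruct the flux exactly", {
  acc <- accumulate_transitions(matrix(c(1L, 2L), 1),
                                components = list(O = matrix(c(-1, 2), 1)))
  amps <- pre_post_amplitudes(acc, "O")
  expect_equal(amps$pre_amp[2, 1], -1)
  expect_equal(amps$post_amp[2, 1], 2)
  set.seed(26)
  cfg <- hb_sim_config(n_voxels = 10, n_frames = 400, seed = 26)
  b <- simulate_breast(cfg)
  maps <- transition_coefficients(b$dD, b$dO, cfg$geometry)
  for (X in c("O", "S")) {
    phi <- off_diagonal(maps[[paste0("phi_", X)]])
    d <- off_diagonal(maps[[paste0("post_amp_", X)]]) -
      off_diagonal(maps[[paste0("pre_amp_", X)]])
    scale <- max(abs(phi), na.rm = TRUE)
    expect_lt(max(abs(phi - d), na.rm = TRUE), 1e-12 * scale)
    # zero-count cells are missing in both
    expect_identical(is.na(phi), is.na(d))
  }
})

test_that("ohmic voltages divide rate by probability", {
  v <- hb_map(matrix(0.5, 10, 10), "k", units = "1/frame")
  P <- hb_map(matrix(50, 10, 10), "P", units = "%")
  V <- ohmic_voltages(v, P)
  expect_equal(V[2, 1], 0.01)
  expect_equal(length(unique(off_diagonal(V))), 1L)   # uniform in, uniform out
  phi <- hb_map(matrix(3, 10, 10), "phi", component = "T")
  VX <- ohmic_voltages(v, P, phi)
  expect_equal(unclass(VX), unclass(V) * unclass(phi), ignore_attr = TRUE)
  P0 <- hb_map(matrix(0, 10, 10), "P")
  expect_true(all(is.na(off_diagonal(ohmic_voltages(v, P0)))))
})

test_that("asymmetry maps are antisymmetric", {
  set.seed(27)
  Y <- hb_map(matrix(runif(100), 10), "P")
  a <- asymmetry_map(Y)
  av <- unclass(a)
  off <- row(av) != col(av)
  expect_equal(av[off] + t(av)[off], rep(0, 90))
  sym <- hb_map(matrix(1, 10, 10), "P")
  expect_true(all(off_diagonal(asymmetry_map(sym)) == 0))
  Y2 <- hb_map(matrix(0, 10, 10), "P")
  Y2[2, 1] <- 50; Y2[1, 2] <- 30
  a2 <- asymmetry_map(Y2)
  expect_equal(a2[2, 1], 20)
  expect_equal(a2[1, 2], -20)
})
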