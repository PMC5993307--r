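# minimal cohort builder: one "k"-like map per breast from given matrices
make_subject <- function(id, group, laterality, left, right) {
  list(id = id, group = group, laterality = laterality,
       left = list(k = hb_map(left, "k")),
       right = list(k = hb_map(right, "k")))
}

test_that("Z metric: left-right relative difference with right-tumor correction", {
  base <- matrix(100, 10, 10)
  nc1 <- make_subject("n1", "non_cancer", "none", base, base)
  nc2 <- make_subject("n2", "non_cancer", "none", base, base)
  lt <- make_subject("c1", "cancer", "left", base * 1.1, base)
  coh <- hb_cohort(list(nc1, nc2, lt))
  Z <- z_metric(coh, "k")
  expect_true(all(off_diagonal(Z$n1) == 0))
  expect_equal(off_diagonal(Z$c1), rep(10, 90))

  # with equal NC reference means, the right-tumor form reduces to
  # 100 * (Yr - Yl) / Yl
  rt <- make_subject("c2", "cancer", "right", base, base * 1.2)
  coh2 <- hb_cohort(list(nc1, nc2, rt))
  Z2 <- z_metric(coh2, "k")
  expect_equal(off_diagonal(Z2$c2), rep(20, 90))

  # right-tumor correction, hand-evaluated with an intrinsic left-right bias:
  # NC means 105 (left) / 100 (right); subject Yl = 105, Yr = 120
  # -> numerator (120 - 100 + 105) - (105 - 105 + 100) = 25, denominator 100
  bias <- matrix(5, 10, 10)
  nc_b1 <- make_subject("n1", "non_cancer", "none", base + bias, base)
  nc_b2 <- make_subject("n2", "non_cancer", "none", base + bias, base)
  rt_b <- make_subject("c3", "cancer", "right", base + bias, base * 1.2)
  Z3 <- z_metric(hb_cohort(list(nc_b1, nc_b2, rt_b)), "k")
  expect_equal(off_diagonal(Z3$c3), rep(25, 90))

  zero <- make_subject("c4", "cancer", "left", base, matrix(0, 10, 10))
  Z4 <- z_metric(hb_cohort(list(nc1, nc2, zero)), "k")
  expect_true(all(is.na(off_diagonal(Z4$c4))))
})

test_that("group t-test maps match the pooled-variance oracle", {
  set.seed(41)
  n_c <- 8L; n_n <- 12L
  subs <- c(
    lapply(seq_len(n_c), function(j)
      make_subject(paste0("c", j), "cancer", "left",
                   matrix(rnorm(100, 1), 10), matrix(rnorm(100), 10))),
    lapply(seq_len(n_n), function(j)
      make_subject(paste0("n", j), "non_cancer", "none",
                   matrix(rnorm(100), 10), matrix(rnorm(100), 10))))
  coh <- hb_cohort(subs)
  p <- group_difference_ttests(coh, "k")
  # oracle at a handful of cells
  dc <- sapply(subs[1:n_c], function(s) s$left$k[3, 1] - s$right$k[3, 1])
  dn <- sapply(subs[n_c + seq_len(n_n)],
               function(s) s$left$k[3, 1] - s$right$k[3, 1])
  expect_equal(p[3, 1], unname(oracle_pooled_t(dc, dn)["p"]))
  expect_true(all(off_diagonal(p) >= 0 & off_diagonal(p) <= 1, na.rm = TRUE))

  # identical groups: p = 1 everywhere defined
  same <- matrix(1:100, 10)
  subs_eq <- c(
    lapply(1:3, function(j) make_subject(paste0("c", j), "cancer", "left",
                                         same + j, same)),
    lapply(1:3, function(j) make_subject(paste0("n", j), "non_cancer", "none",
                                         same + j, same)))
  p_eq <- group_difference_ttests(hb_cohort(subs_eq), "k")
  expect_true(all(off_diagonal(p_eq) == 1, na.rm = TRUE))

  # well-separated groups are detected decisively
  set.seed(42)
  subs_sep <- c(
    lapply(1:15, function(j)
      make_subject(paste0("c", j), "cancer", "left",
                   matrix(5 + rnorm(100, sd = 1), 10), matrix(rnorm(100), 10))),
    lapply(1:15, function(j)
      make_subject(paste0("n", j), "non_cancer", "none",
                   matrix(rnorm(100), 10), matrix(rnorm(100), 10))))
  p_sep <- group_difference_ttests(hb_cohort(subs_sep), "k")
  expect_true(all(off_diagonal(p_sep) < 0.001, na.rm = TRUE))
})

test_that("rank-sum AUC equals brute-force pair counting, with midrank ties", {
  expect_equal(rank_sum_auc(c(5, 6, 7), c(1, 2, 3)), 100)   # full separation
  expect_equal(rank_sum_auc(c(1, 2, 3), c(1, 2, 3)), 50)    # identical -> ties
  set.seed(43)
  for (rep in 1:20) {
    pos <- sample(0:5, 7, replace = TRUE)   # integer values force ties
    neg <- sample(0:5, 9, replace = TRUE)
    expect_equal(rank_sum_auc(pos, neg), oracle_auc(pos, neg))
  }
  # complement property
  x <- rnorm(6); y <- rnorm(8)
  expect_equal(rank_sum_auc(x, y) + rank_sum_auc(y, x), 100)
})

test_that("AUC maps carry per-cell rank-sum values and fold correctly", {
  set.seed(44)
  Zc <- lapply(1:5, function(j) hb_map(matrix(rnorm(100, 1), 10), "Z"))
  Zn <- lapply(1:7, function(j) hb_map(matrix(rnorm(100), 10), "Z"))
  a <- roc_auc_map(Zc, Zn)
  expect_equal(a[2, 1],
               oracle_auc(sapply(Zc, function(z) z[2, 1]),
                          sapply(Zn, function(z) z[2, 1])))
  rev <- roc_auc_map(Zn, Zc)
  expect_equal(off_diagonal(a) + off_diagonal(rev), rep(100, 90))
  folded <- roc_auc_map(Zc, Zn, fold = TRUE)
  expect_true(all(off_diagonal(folded) >= 50))
  expect_equal(unclass(folded), pmax(unclass(a), 100 - unclass(a)),
               ignore_attr = TRUE)
})

test_that("a disease effect on dwell times drives AUC above the null", {
  cfg_null <- hb_sim_config(n_voxels = 15, n_frames = 250, seed = 45,
                            disease_effect = list(dwell = 1, amplitude = 1))
  coh_null <- simulate_cohort_maps(cfg_null, n_cancer = 8, n_noncancer = 10,
                                   laterality = c(left = 5, right = 3))
  grp <- vapply(coh_null$subjects, `[[`, "", "group")
  Z <- z_metric(coh_null, "k")
  a_null <- roc_auc_map(Z[grp == "cancer"], Z[grp == "non_cancer"])
  expect_lt(abs(mean(off_diagonal(a_null), na.rm = TRUE) - 50), 10)

  cfg_eff <- hb_sim_config(n_voxels = 15, n_frames = 250, seed = 45,
                           disease_effect = list(dwell = 0.6, amplitude = 1))
  coh_eff <- simulate_cohort_maps(cfg_eff, n_cancer = 8, n_noncancer = 10,
                                  laterality = c(left = 5, right = 3))
  Ze <- z_metric(coh_eff, "k")
  a_eff <- roc_auc_map(Ze[grp == "cancer"], Ze[grp == "non_cancer"])
  expect_gt(mean(off_diagonal(a_eff), na.rm = TRUE),
            mean(off_diagonal(a_null), na.rm = TRUE) + 5)
})

test_that("cohort construction enforces the group/laterality invariants", {
  base <- matrix(1, 10, 10)
  expect_error(hb_cohort(list(make_subject("x", "cancer", "none", base, base))),
               "laterality")
  expect_error(hb_cohort(list(make_subject("x", "non_cancer", "left",
                                           base, base))),
               "laterality")
  expect_error(hb_cohort(list(make_subject("x", "sick", "left", base, base))),
               "group")
})
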