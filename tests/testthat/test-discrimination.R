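test_that("degrees of separation is a normalised Mahalanobis summary", {
  st <- model_structure("A", 2)
  grid <- c(18, 35, 50, 62.5)

  # identical mean trajectories: exactly zero
  f0 <- fake_fit(st, c(0.5, 0.5), cbind(c(24, 1, 0.2), c(24, 1, 0.2)))
  expect_identical(degrees_of_separation(f0, grid)$dos, 0)

  # pooled covariance I (sigma2 = 1), constant mean difference 1 on 4 times:
  # d = sqrt(4) = 2 and DoS = 2 / sqrt(4) = 1
  f1 <- fake_fit(st, c(0.5, 0.5), cbind(c(0, 0, 0), c(1, 0, 0)), sigma2 = 1)
  r1 <- degrees_of_separation(f1, grid)
  expect_equal(r1$pairwise[1, 2], 2, tolerance = 1e-10)
  expect_equal(r1$dos, 1, tolerance = 1e-10)

  # doubling the separation doubles DoS (linearity in the mean difference)
  f2 <- fake_fit(st, c(0.5, 0.5), cbind(c(0, 0, 0), c(2, 0, 0)), sigma2 = 1)
  expect_equal(degrees_of_separation(f2, grid)$dos, 2 * r1$dos,
               tolerance = 1e-10)

  # invariant under affine outcome rescaling (Mahalanobis property)
  c_ <- 3.7
  f3 <- fake_fit(st, c(0.5, 0.5), cbind(c(0, 0, 0), c(1, 0, 0)) * c_,
                 sigma2 = c_^2)
  expect_equal(degrees_of_separation(f3, grid)$dos, r1$dos, tolerance = 1e-10)

  # symmetry and zero diagonal
  expect_equal(r1$pairwise, t(r1$pairwise))
  expect_equal(diag(r1$pairwise), c(0, 0))
})

test_that("residual envelopes equal brute-force weighted local moments", {
  st <- model_structure("A", 1, fixed_degree = 0, time_transform = c(0, 1))

  # residuals {-1, +1} at one time with equal weights: mean 0, sd 1
  td <- trajectory_data(data.frame(id = c("a", "b"), time = c(10, 10),
                                   y = c(-1, 1)))
  f <- fake_fit(st, 1, matrix(0, 1, 1), posterior = matrix(1, 2, 1))
  rownames(f$posterior) <- c("a", "b"); names(f$assignment) <- c("a", "b")
  env <- envelope_residuals(f, td, weight_floor = 1)
  expect_equal(env$table$mean, 0)
  expect_equal(env$table$sd, 1)
  expect_equal(env$table$lower, -1)
  expect_equal(env$table$upper, 1)

  # noiseless data on the class means with one-hot posteriors: sd 0
  sim <- simulate_trajectories(simulation_config(
    30, model_structure("A", 2), sep_beta2(), pi = c(0.5, 0.5),
    sigma2 = 1e-12, seed = 3))
  fitA <- fake_fit(model_structure("A", 2), c(0.5, 0.5), sep_beta2(),
                   posterior = diag(2)[sim$labels$class, ])
  rownames(fitA$posterior) <- sim$labels$id
  fitA$assignment <- setNames(sim$labels$class, sim$labels$id)
  env0 <- envelope_residuals(fitA, sim$data, weight_floor = 0.5)
  ok <- !is.na(env0$table$sd)
  expect_true(all(env0$table$sd[ok] < 1e-5))
  expect_equal(env0$table$lower[ok], env0$table$upper[ok], tolerance = 1e-4)

  # brute-force oracle for the weighted local moments on a random instance
  set.seed(2)
  n <- 40
  td2 <- trajectory_data(data.frame(id = sprintf("s%02d", 1:n),
                                    time = rep(c(1, 2), n / 2),
                                    y = rnorm(n)))
  w <- runif(n)
  post <- cbind(w, 1 - w)
  f2 <- fake_fit(model_structure("A", 2, fixed_degree = 0,
                                 time_transform = c(0, 1)),
                 c(0.5, 0.5), matrix(c(0.3, -0.2), 1, 2), posterior = post)
  rownames(f2$posterior) <- td2$id; names(f2$assignment) <- td2$id
  env2 <- envelope_residuals(f2, td2, weight_floor = 0)
  for (k in 1:2) {
    for (tm in c(1, 2)) {
      ix <- td2$time == tm
      r <- td2$y[ix] - f2$beta[1, k]
      wi <- post[match(td2$id[ix], td2$id), k]
      m_ref <- sum(wi * r) / sum(wi)
      s_ref <- sqrt(sum(wi * (r - m_ref)^2) / sum(wi))
      row <- env2$table[env2$table$class == k & env2$table$time == tm, ]
      expect_equal(row$mean, m_ref, tolerance = 1e-12)
      expect_equal(row$sd, s_ref, tolerance = 1e-12)
    }
  }
})

test_that("envelope parallelism flags homoscedastic vs time-varying noise", {
  set.seed(5)
  n <- 300
  times <- c(18, 35, 50, 62.5)
  mk_data <- function(noise_sd) {
    df <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(id = sprintf("s%03d", i), time = times,
                 y = 25 + rnorm(4, 0, noise_sd))))
    trajectory_data(df)
  }
  st <- model_structure("A", 1)
  post1 <- matrix(1, n, 1)
  mk_fit <- function(td) {
    f <- fake_fit(st, 1, matrix(c(25, 0, 0), 3, 1), posterior = post1)
    rownames(f$posterior) <- unique(td$id)
    f$assignment <- setNames(rep(1L, n), unique(td$id))
    f
  }
  td_h <- mk_data(rep(1, 4))
  expect_identical(envelope_residuals(mk_fit(td_h), td_h)$parallel, "parallel")
  td_n <- mk_data(c(0.5, 1, 2, 4))
  expect_identical(envelope_residuals(mk_fit(td_n), td_n)$parallel,
                   "non-parallel")
})

test_that("weighted kappa honours its identities", {
  # perfect agreement: 1 for every weighting
  dtab <- diag(c(10, 20, 30, 5))
  for (w in c("unweighted", "linear", "quadratic")) {
    expect_equal(weighted_kappa(dtab, w)$kappa, 1)
  }
  # independence table (outer product of margins): exactly 0
  ind <- outer(c(10, 30, 60), c(20, 30, 50))
  for (w in c("unweighted", "linear", "quadratic")) {
    expect_equal(weighted_kappa(ind, w)$kappa, 0, tolerance = 1e-12)
  }
  # on 2x2 tables quadratic weighting coincides with unweighted kappa
  set.seed(7)
  for (r in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_equal(weighted_kappa(tab, "quadratic")$kappa,
                 weighted_kappa(tab, "unweighted")$kappa, tolerance = 1e-12)
  }
  # assignment optimisation is invariant to row relabelling
  set.seed(8)
  for (r in 1:10) {
    tab <- matrix(rpois(16, 15), 4, 4)
    k1 <- weighted_kappa(tab, "quadratic", optimize_assignment = TRUE)$kappa
    k2 <- weighted_kappa(tab[sample(4), ], "quadratic",
                         optimize_assignment = TRUE)$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("model concordance detects identity, relabelling and mismatch", {
  sim <- simulate_trajectories(sep_config("A", n_subjects = 150, seed = 12))
  fit <- quick_fit(sim, model_structure("A", 2), seed = 2)
  cc <- model_concordance(fit, fit)
  expect_equal(cc$kappa, 1)
  expect_equal(cc$kappa_unweighted, 1)

  # permuted-label copy still gives kappa 1 after assignment optimisation
  fit_p <- fit
  fit_p$assignment <- setNames(3L - fit$assignment, names(fit$assignment))
  fit_p$posterior <- fit$posterior[, 2:1]
  expect_equal(model_concordance(fit, fit_p)$kappa_unweighted, 1)

  # independent labelings give kappa near zero
  set.seed(3)
  fit_r <- fit
  fit_r$assignment <- setNames(sample(1:2, 150, replace = TRUE),
                               names(fit$assignment))
  expect_lt(abs(model_concordance(fit, fit_r)$kappa_unweighted), 0.2)

  # different subject sets are a data error
  sim2 <- simulate_trajectories(sep_config("A", n_subjects = 120, seed = 13))
  fit2 <- quick_fit(sim2, model_structure("A", 2), seed = 2)
  expect_error(model_concordance(fit, fit2), "different subjects")
})
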