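make_design <- function(times, st, y) {
  td <- trajectory_data(data.frame(id = "a", time = times, y = y))
  build_design(td, st)
}

test_that("marginal covariance reflects each structure's assumptions", {
  # structure A: no random effects, sigma2 * identity
  stA <- model_structure("A", 1)
  pA <- lctm_params(stA, 1, matrix(0, 3, 1), sigma2 = 2)
  expect_equal(marginal_covariance(pA, NULL, 1, n_obs = 3), diag(2, 3))

  # structure C: random intercept b gives sigma2*I + b * ones
  stC <- model_structure("C", 1)
  pC <- lctm_params(stC, 1, matrix(0, 3, 1), sigma2 = 1.5,
                    B = matrix(0.7, 1, 1))
  Z <- matrix(1, 3, 1)
  expect_equal(marginal_covariance(pC, Z, 1),
               diag(1.5, 3) + 0.7 * matrix(1, 3, 3))

  # structure F with all scales 1 coincides with structure E
  B <- diag(c(0.5, 0.2, 0.1))
  beta <- cbind(c(20, 1, 0), c(25, -1, 0))
  stE <- model_structure("E", 2)
  stF <- model_structure("F", 2)
  pE <- lctm_params(stE, c(0.5, 0.5), beta, 1, B = B)
  pF <- lctm_params(stF, c(0.5, 0.5), beta, 1, B = B, omega = c(1, 1))
  Z3 <- poly_design(c(-1, 0, 1), 2)
  for (k in 1:2) {
    expect_equal(marginal_covariance(pF, Z3, k),
                 marginal_covariance(pE, Z3, k))
  }
})

test_that("log-likelihood handles point-mass and collapsed-mixture cases", {
  st1 <- model_structure("A", 1, fixed_degree = 0, time_transform = c(0, 1))
  # one subject, one observation at the class mean, unit variance:
  # the standard normal log density at its mode
  d <- make_design(1, st1, y = 5)
  p1 <- lctm_params(st1, 1, matrix(5, 1, 1), sigma2 = 1)
  expect_equal(lctm_loglik(p1, d), -0.5 * log(2 * pi), tolerance = 1e-9)

  # K = 2 with identical components collapses to the K = 1 value for any pi
  st2 <- model_structure("A", 2, fixed_degree = 0, time_transform = c(0, 1))
  for (pi1 in c(0.2, 0.5, 0.9)) {
    p2 <- lctm_params(st2, c(pi1, 1 - pi1), matrix(5, 1, 2), sigma2 = 1)
    expect_equal(lctm_loglik(p2, d), -0.5 * log(2 * pi), tolerance = 1e-9)
  }
})

test_that("posterior probabilities follow Bayes rule", {
  st2 <- model_structure("A", 2, fixed_degree = 0, time_transform = c(0, 1))
  d <- make_design(c(1, 2), st2, y = c(4, 6))

  # identical classes: the data carry no information, rows equal pi
  p_same <- lctm_params(st2, c(0.3, 0.7), matrix(5, 1, 2), sigma2 = 1)
  es <- e_step(p_same, d)
  expect_equal(unname(es$posterior[1, ]), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(rowSums(es$posterior), setNames(1, "a"))

  # K = 1: a column of ones
  st1 <- model_structure("A", 1, fixed_degree = 0, time_transform = c(0, 1))
  es1 <- e_step(lctm_params(st1, 1, matrix(5, 1, 1), 1), make_design(1, st1, 5))
  expect_equal(unname(es1$posterior), matrix(1, 1, 1))

  # scalar case: y = 0, unit-variance classes at means 0 and 2, uniform pi:
  # p_1 = 1 / (1 + exp(-2))
  dd <- make_design(1, st2, y = 0)
  p <- lctm_params(st2, c(0.5, 0.5), matrix(c(0, 2), 1, 2), sigma2 = 1)
  expect_equal(unname(e_step(p, dd)$posterior[1, 1]), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
})

test_that("M step reduces to weighted least squares in closed-form cases", {
  set.seed(9)
  df <- data.frame(id = rep(sprintf("s%02d", 1:20), each = 3),
                   time = rep(c(18, 35, 50), 20),
                   y = rnorm(60, rep(c(20, 30), each = 30), 1))
  td <- trajectory_data(df)
  st <- model_structure("A", 2)
  d <- build_design(td, st)

  # one-hot posterior: per-class OLS fits and pooled residual variance
  post <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
  p0 <- lctm_params(st, c(0.5, 0.5), matrix(c(20, 0, 0, 30, 0, 0), 3, 2), 1)
  up <- m_step(post, d, p0, fit_config())
  for (k in 1:2) {
    ids <- unique(df$id)[post[, k] == 1]
    sub <- df[df$id %in% ids, ]
    ols <- lm(y ~ poly(I((time - 45) / 10), 2, raw = TRUE), data = sub)
    expect_equal(unname(up$beta[, k]), unname(coef(ols)), tolerance = 1e-8)
  }
  res2 <- sapply(1:2, function(k) {
    ids <- unique(df$id)[post[, k] == 1]
    sub <- df[df$id %in% ids, ]
    sum(resid(lm(y ~ poly(I((time - 45) / 10), 2, raw = TRUE), data = sub))^2)
  })
  expect_equal(up$sigma2, sum(res2) / 60, tolerance = 1e-8)

  # uniform posterior: both classes solve the same weighted problem
  post_u <- matrix(0.5, 20, 2)
  up_u <- m_step(post_u, d, p0, fit_config())
  expect_equal(up_u$beta[, 1], up_u$beta[, 2], tolerance = 1e-10)

  # pi update is the posterior column mean
  post_c <- rbind(matrix(rep(c(1, 0), 2), 2, 2, byrow = TRUE),
                  matrix(c(0, 1), 1, 2),
                  matrix(0.5, 17, 2))[1:20, ]
  up_c <- m_step(post_c, d, p0, fit_config())
  expect_equal(up_c$pi, colMeans(post_c))
})
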