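# Shared fixtures: all data are generated in code at test time.

# two well-separated quadratic mean curves (transformed-time scale); the
# curves stay >= 2 residual SDs apart over the 4-visit age grid at sigma2 = 1
sep_beta2 <- function() cbind(c(22, 1, 0.3), c(28, -1, -0.3))

# a simulation config per covariance structure, 2 classes, >= 2-SD separation
sep_config <- function(code, n_subjects = 500, seed = 11) {
  st <- model_structure(code, 2)
  q <- st$random_degree + 1L
  B <- if (st$random_cov_mode %in% c("shared", "proportional"))
    diag(c(0.5, 0.2, 0.05)[seq_len(q)], q)
  simulation_config(
    n_subjects, st, sep_beta2(), pi = c(0.6, 0.4),
    sigma2 = if (code == "B") c(1, 1.5) else 1,
    B = B,
    omega = if (code == "F") c(1.4, 1),
    B_list = if (code == "G") list(diag(c(0.5, 0.2, 0.05)),
                                   diag(c(0.9, 0.1, 0.02))),
    seed = seed)
}

# three-class model-F truth used for class-enumeration experiments
three_class_F_config <- function(n_subjects = 500, seed = 100) {
  simulation_config(
    n_subjects, model_structure("F", 3),
    beta = cbind(c(20, 0.5, 0.1), c(26, 1, 0.2), c(33, -0.5, -0.2)),
    pi = c(0.5, 0.3, 0.2), sigma2 = 1,
    B = diag(c(0.5, 0.2, 0.05)), omega = c(1.3, 0.8, 1), seed = seed)
}

quick_fit <- function(sim, structure, seed = 5, n_starts = 2, ...) {
  fit_lctm(sim$data, structure, fit_config(n_starts = n_starts, seed = seed, ...))
}

# minimal hand-built fitted-model object for metric tests that only need
# parameters and a posterior matrix
fake_fit <- function(structure, pi, beta, sigma2 = 1, B = NULL, omega = NULL,
                     B_list = NULL, posterior = NULL) {
  params <- lctm_params(structure, pi, beta, sigma2, B = B, omega = omega,
                        B_list = B_list)
  if (!is.null(posterior)) {
    rownames(posterior) <- sprintf("s%03d", seq_len(nrow(posterior)))
  }
  structure(c(params[c("structure", "pi", "beta", "sigma2", "B", "omega",
                       "B_list")],
              list(posterior = posterior,
                   assignment = if (!is.null(posterior)) {
                     a <- max.col(posterior, ties.method = "first")
                     names(a) <- rownames(posterior)
                     a
                   },
                   converged = TRUE, status = "converged",
                   loglik = NA_real_,
                   n_subjects = if (!is.null(posterior)) nrow(posterior) else 0L,
                   n_params = count_parameters(structure),
                   small_classes = integer(0))),
            class = "lctm_fit")
}

# Monte-Carlo integration of the marginal likelihood over random effects:
# independent oracle for lctm_loglik on tiny instances (structures C-G).
# Returns the MC log-likelihood and its standard error.
mc_loglik <- function(params, design, n_draws = 1e6, seed = 1) {
  st <- params$structure
  K <- st$n_classes
  q <- st$random_degree + 1L
  set.seed(seed)
  total <- 0; var_total <- 0
  for (pat in design$patterns) {
    n_t <- length(pat$times)
    for (i in seq_len(nrow(pat$Y))) {
      y <- pat$Y[i, ]
      mix_mean <- 0; mix_var <- 0
      for (k in seq_len(K)) {
        Bk <- trajmix:::class_cov(params, k)
        s <- sqrt(trajmix:::class_sigma2(params, k))
        mu0 <- as.vector(pat$X %*% params$beta[, k])
        b <- matrix(rnorm(n_draws * q), n_draws, q) %*%
          chol(Bk + diag(1e-12, q))
        dev <- b %*% t(pat$Z)                     # draws x n_t
        ld <- rep(0, n_draws)
        for (j in seq_len(n_t)) {
          ld <- ld + dnorm(y[j], mu0[j] + dev[, j], s, log = TRUE)
        }
        dens <- exp(ld)
        mix_mean <- mix_mean + params$pi[k] * mean(dens)
        mix_var <- mix_var + params$pi[k]^2 * var(dens) / n_draws
      }
      total <- total + log(mix_mean)
      var_total <- var_total + mix_var / mix_mean^2   # delta method on log
    }
  }
  list(loglik = total, se = sqrt(var_total))
}
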