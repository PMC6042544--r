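#' Configure a generative trajectory simulation
#'
#' Defines the ground truth for a simulated cohort: class mixing proportions,
#' class mean polynomials, random-effect covariance and residual noise, plus
#' the observation design — by default the 4-visit adult age grid
#' `18, 35, 50, 62.5` years, optionally thinned by independent per-visit
#' dropout to mimic subjects with 2-4 observations.
#'
#' @param n_subjects number of subjects to simulate.
#' @param structure a [model_structure] giving the true covariance structure.
#' @param beta true fixed-effect matrix (`(fixed_degree + 1) x K`), on the
#'   transformed time scale of `structure`.
#' @param pi true mixing proportions.
#' @param sigma2 true residual variance(s).
#' @param B,omega,B_list true random-effect covariance parameters, as in
#'   [lctm_params()].
#' @param visit_times scheduled observation times (natural axis).
#' @param time_jitter SD of Gaussian jitter added independently to each
#'   subject's visit times (0 = exact grid).
#' @param retention per-visit retention probability; visits are dropped
#'   independently, but every subject keeps at least one (a uniformly chosen
#'   visit is forced if all were dropped).
#' @param seed integer seed; identical configurations produce identical data.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, structure, beta, pi, sigma2,
                              B = NULL, omega = NULL, B_list = NULL,
                              visit_times = c(18, 35, 50, 62.5),
                              time_jitter = 0, retention = 1, seed = 1) {
  params <- lctm_params(structure, pi, beta, sigma2,
                        B = B, omega = omega, B_list = B_list)
  stopifnot(n_subjects >= 1, length(visit_times) >= 1,
            retention > 0, retention <= 1, time_jitter >= 0)
  structure(list(n_subjects = as.integer(n_subjects), params = params,
                 visit_times = as.numeric(visit_times),
                 time_jitter = time_jitter, retention = retention,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a latent class trajectory cohort
#'
#' Draws, per subject, a class from the mixing proportions, random effects
#' from the class covariance, and observations
#' `y = X beta_k + Z b + noise` at the configured visit times. The true class
#' labels and random effects are returned alongside the dataset, so recovery
#' and selection experiments have full ground truth.
#'
#' @param config a [simulation_config].
#' @return list of class `lctm_sim`: `data` (a [trajectory_data]), `labels`
#'   (data.frame `id`, `class`), `random_effects` (N x q matrix or NULL) and
#'   the `config`.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pr <- config$params
  st <- pr$structure
  K <- st$n_classes
  q <- n_random(st)
  N <- config$n_subjects
  set.seed(config$seed)

  cls <- sample.int(K, N, replace = TRUE, prob = pr$pi)
  chols <- if (q > 0L) {
    lapply(seq_len(K), function(k) {
      Bk <- class_cov(pr, k)
      t(chol(Bk + diag(1e-12, q)))
    })
  }
  b_all <- if (q > 0L) matrix(0, N, q)

  rows <- vector("list", N)
  nv <- length(config$visit_times)
  for (i in seq_len(N)) {
    k <- cls[i]
    keep <- if (config$retention < 1) {
      kp <- stats::runif(nv) < config$retention
      if (!any(kp)) kp[sample.int(nv, 1L)] <- TRUE
      kp
    } else rep(TRUE, nv)
    tms <- config$visit_times[keep]
    if (config$time_jitter > 0)
      tms <- tms + stats::rnorm(length(tms), 0, config$time_jitter)
    tt <- transform_time(tms, st)
    X <- poly_design(tt, st$fixed_degree)
    mu <- as.vector(X %*% pr$beta[, k])
    if (q > 0L) {
      b <- as.vector(chols[[k]] %*% stats::rnorm(q))
      b_all[i, ] <- b
      mu <- mu + as.vector(X[, seq_len(q), drop = FALSE] %*% b)
    }
    y <- mu + stats::rnorm(length(tms), 0, sqrt(class_sigma2(pr, k)))
    rows[[i]] <- data.frame(id = sprintf("s%06d", i), time = tms, y = y)
  }
  df <- do.call(rbind, rows)
  structure(list(
    data = trajectory_data(df),
    labels = data.frame(id = sprintf("s%06d", seq_len(N)), class = cls,
                        stringsAsFactors = FALSE),
    random_effects = b_all,
    config = config
  ), class = "lctm_sim")
}

#' Cohort-like simulation scenario
#'
#' A ready-made 5-class scenario mimicking the structure of a large adult
#' cohort with recalled body-mass-index at ages 18, 35 and 50 plus a baseline
#' determination around age 62.5: strongly imbalanced classes — proportions
#' about 68%, 25%, 4%, 2.7% and 0.4% (normalised) including a sub-1% class —
#' with quadratic mean curves rising from the low 20s into the high-20s/30s
#' kg/m2 range, a proportional random-quadratic covariance (structure F) and
#' unit residual variance. The mean-curve coefficients are obtained by
#' least-squares quadratic fits through class-typical BMI values at the four
#' visit ages, computed at construction time.
#'
#' @param n_subjects cohort size.
#' @param seed simulation seed.
#' @param retention per-visit retention probability (1 = complete 4-visit
#'   data).
#' @return a [simulation_config].
#' @export
scenario_aarp_like <- function(n_subjects = 2000, seed = 1, retention = 1) {
  st <- model_structure("F", 5)
  ages <- c(18, 35, 50, 62.5)
  # class-typical BMI at the four visit ages (stable normal weight; normal to
  # overweight; normal to obese; overweight to obese; rapid early obesity)
  bmi <- rbind(c(20.75, 23.35, 24.66, 25.39),
               c(23.92, 26.72, 29.12, 30.84),
               c(21.69, 30.24, 31.34, 29.07),
               c(27.16, 26.61, 30.95, 35.14),
               c(24.76, 37.69, 35.01, 30.51))
  X <- poly_design(transform_time(ages, st), 2)
  beta <- apply(bmi, 1L, function(v) solve(crossprod(X), crossprod(X, v)))
  pi <- c(0.68, 0.25, 0.04, 0.027, 0.004)
  simulation_config(
    n_subjects = n_subjects, structure = st, beta = beta, pi = pi / sum(pi),
    sigma2 = 1,
    B = diag(c(1.5, 0.5, 0.15)),
    omega = c(1.2, 1.1, 1.4, 1.6, 1),
    seed = seed, retention = retention)
}

## all permutations of 1..n (exact assignment search, n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

## align fitted classes to true labels: permutation maximising agreement
align_to_truth <- function(fitted_class, true_class, K) {
  best <- seq_len(K); best_agree <- -1
  for (p in all_permutations(K)) {
    agree <- mean(p[fitted_class] == true_class)
    if (agree > best_agree) { best_agree <- agree; best <- p }
  }
  list(perm = unlist(best), agreement = best_agree)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates from a known configuration, refits the true structure
#' and class count, aligns fitted classes to the truth by the label
#' permutation maximising assignment agreement, and summarises estimation
#' quality: per-coefficient bias, modal-assignment Cohen's kappa against the
#' true labels, and (optionally) whether a BIC sweep over `sweep_k` selects
#' the true K.
#'
#' @param config a [simulation_config] (the truth).
#' @param fit_cfg a [fit_config] used for each refit.
#' @param n_replicates number of simulate-fit replicates; replicate r uses
#'   simulation seed `config$seed + r - 1`.
#' @param sweep_k optional integer vector of class counts for a per-replicate
#'   BIC sweep (slow; off by default).
#' @return list of class `recovery_report`: `beta_bias` (mean over replicates
#'   of the aligned coefficient error, same shape as `beta`), `beta_rmse`,
#'   `kappa` (per replicate), `k_selected` (per replicate, if swept),
#'   `failures` (count), `n_replicates`.
#' @export
recovery_experiment <- function(config, fit_cfg = fit_config(n_starts = 3),
                                n_replicates = 5, sweep_k = NULL) {
  st <- config$params$structure
  K <- st$n_classes
  errs <- list(); kappas <- numeric(0); ksel <- integer(0); fails <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    sim <- simulate_trajectories(cfg_r)
    fit <- tryCatch(fit_lctm(sim$data, st, fit_cfg), error = function(e) NULL)
    if (is.null(fit)) { fails <- fails + 1L; next }
    al <- align_to_truth(fit$assignment, sim$labels$class, K)
    perm <- al$perm   # perm[fitted] = true label
    inv <- order(perm) # column of fit corresponding to true class k
    errs[[length(errs) + 1L]] <-
      fit$beta[, inv, drop = FALSE] - config$params$beta
    tab <- table(factor(perm[fit$assignment], levels = seq_len(K)),
                 factor(sim$labels$class, levels = seq_len(K)))
    kappas <- c(kappas, cohen_kappa(tab, weighting = "unweighted"))
    if (!is.null(sweep_k)) {
      sw <- sweep_classes(sim$data, st, k_range = sweep_k, config = fit_cfg)
      ksel <- c(ksel, sw$best_k)
    }
  }
  if (!length(errs)) stop("all replicates failed to fit", call. = FALSE)
  arr <- simplify2array(errs)
  structure(list(
    beta_bias = apply(arr, c(1, 2), mean),
    beta_rmse = sqrt(apply(arr^2, c(1, 2), mean)),
    kappa = kappas,
    k_selected = if (!is.null(sweep_k)) ksel,
    failures = fails,
    n_replicates = n_replicates
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates (%d failures)\n",
              x$n_replicates, x$failures))
  cat(sprintf("  mean |beta bias|: %.4f | mean assignment kappa: %.3f\n",
              mean(abs(x$beta_bias)), mean(x$kappa)))
  if (!is.null(x$k_selected))
    cat("  K selected:", paste(x$k_selected, collapse = " "), "\n")
  invisible(x)
}
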