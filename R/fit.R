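#' EM fitting configuration
#'
#' @param n_starts number of EM starts (start 1 is a deterministic k-means
#'   initialisation; the rest are randomised under `seed`).
#' @param max_iter maximum EM iterations per start.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param seed integer seed controlling all randomised starts; refitting with
#'   the same seed reproduces the fit exactly.
#' @param ridge diagonal jitter applied when factorising near-singular
#'   marginal covariances.
#' @param min_class_prop_warn classes whose estimated proportion falls below
#'   this fraction are flagged in the fit (advisory only; they are never
#'   removed).
#' @param mstep_maxit BFGS iterations per covariance M step (structures C-G);
#'   a partial conditional maximisation is sufficient for EM monotonicity.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, max_iter = 500, tol = 1e-6, seed = 1,
                       ridge = 1e-8, min_class_prop_warn = 0.005,
                       mstep_maxit = 10) {
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0, ridge >= 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), ridge = ridge,
                 min_class_prop_warn = min_class_prop_warn,
                 mstep_maxit = as.integer(mstep_maxit)),
            class = "fit_config")
}

## ---- covariance parameter packing (unconstrained scale) --------------------
## B is parameterised by its lower Cholesky factor with log-diagonal, so any
## real vector maps to a PSD matrix; variances and scales enter as logs.

chol_to_vec <- function(B) {
  L <- t(chol(B + diag(1e-10, nrow(B))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

vec_to_cov <- function(v, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

pack_cov <- function(params) {
  st <- params$structure
  q <- n_random(st)
  K <- st$n_classes
  switch(st$random_cov_mode,
         shared = c(chol_to_vec(params$B), log(params$sigma2)),
         proportional = c(chol_to_vec(params$B),
                          if (K > 1L) log(params$omega[-1L]),
                          log(params$sigma2)),
         class = c(unlist(lapply(params$B_list, chol_to_vec)),
                   log(params$sigma2)))
}

unpack_cov <- function(theta, params) {
  st <- params$structure
  q <- n_random(st)
  K <- st$n_classes
  nb <- (q * (q + 1L)) %/% 2L
  out <- params
  if (st$random_cov_mode == "shared") {
    out$B <- vec_to_cov(theta[seq_len(nb)], q)
    out$sigma2 <- exp(theta[nb + 1L])
  } else if (st$random_cov_mode == "proportional") {
    out$B <- vec_to_cov(theta[seq_len(nb)], q)
    out$omega <- c(1, if (K > 1L) exp(theta[nb + seq_len(K - 1L)]))
    out$sigma2 <- exp(theta[nb + K])
  } else {
    for (k in seq_len(K))
      out$B_list[[k]] <- vec_to_cov(theta[(k - 1L) * nb + seq_len(nb)], q)
    out$sigma2 <- exp(theta[K * nb + 1L])
  }
  out
}

## Sufficient statistics for the covariance part of the expected
## complete-data objective: per pattern and class, the total posterior weight
## and the weighted residual scatter matrix M_k = sum_i w_i r_i r_i'. Given
## these, the objective is
##   -0.5 sum [ (n log 2pi + logdet V_k) sw_k + tr(V_k^{-1} M_k) ],
## whose evaluation cost no longer depends on the number of subjects.
cov_suffstats <- function(params, posterior, design) {
  K <- params$structure$n_classes
  lapply(design$patterns, function(pat) {
    mu <- pat$X %*% params$beta           # n_t x K
    lapply(seq_len(K), function(k) {
      w <- posterior[pat$idx, k]
      E <- pat$Y - rep(mu[, k], each = nrow(pat$Y))
      list(sw = sum(w), M = crossprod(E * sqrt(w)))
    })
  })
}

q_cov <- function(theta, params, stats, design, ridge) {
  pr <- unpack_cov(theta, params)
  if (any(!is.finite(pr$sigma2)) || any(pr$sigma2 < 1e-12)) return(1e10)
  K <- pr$structure$n_classes
  total <- 0
  for (p in seq_along(design$patterns)) {
    pat <- design$patterns[[p]]
    n_t <- length(pat$times)
    for (k in seq_len(K)) {
      s <- stats[[p]][[k]]
      if (s$sw < 1e-12) next
      V <- marginal_covariance(pr, pat$Z, k, n_obs = n_t)
      R <- chol_ridge(V, ridge)
      if (is.null(R)) return(1e10)
      Vinv <- chol2inv(R)
      total <- total +
        -0.5 * ((n_t * log(2 * pi) + 2 * sum(log(diag(R)))) * s$sw +
                  sum(Vinv * s$M))
    }
  }
  if (!is.finite(total)) return(1e10)
  -total
}

## posterior-weighted GLS update of beta given the current covariances
update_beta <- function(params, posterior, design) {
  st <- params$structure
  K <- st$n_classes
  p <- st$fixed_degree + 1L
  beta <- params$beta
  for (k in seq_len(K)) {
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (pat in design$patterns) {
      n_t <- length(pat$times)
      w <- posterior[pat$idx, k]
      sw <- sum(w)
      if (sw < 1e-12) next
      V <- marginal_covariance(params, pat$Z, k, n_obs = n_t)
      Vi <- chol2inv(chol_ridge(V, 1e-8))
      XtVi <- crossprod(pat$X, Vi)
      A <- A + sw * (XtVi %*% pat$X)
      b <- b + XtVi %*% crossprod(pat$Y, w)
    }
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(sol)) beta[, k] <- sol
  }
  beta
}

#' M step of the EM algorithm
#'
#' Given posterior membership probabilities, updates the mixing proportions
#' (posterior column means), the class fixed effects (posterior-weighted
#' generalised least squares under the current covariances) and the covariance
#' block. Structures A/B have closed-form residual-variance updates; for C-G
#' the Cholesky-parameterised covariance block is improved by a short BFGS run
#' on the expected complete-data objective, a conditional-maximisation step
#' that preserves EM's monotone likelihood ascent.
#'
#' @param posterior N x K matrix of membership probabilities (rows sum to 1).
#' @param design an [build_design()] object.
#' @param params current [lctm_params]; supplies the GLS covariances and the
#'   optimiser's starting point.
#' @param control a [fit_config] (only `ridge` and `mstep_maxit` are used).
#' @return updated [lctm_params]-style list.
#' @export
m_step <- function(posterior, design, params, control = fit_config()) {
  st <- params$structure
  K <- st$n_classes
  out <- params
  out$pi <- colMeans(posterior)

  if (st$random_cov_mode == "none") {
    # V proportional to I: GLS reduces to posterior-weighted OLS
    p <- st$fixed_degree + 1L
    rss <- numeric(K)
    wn <- numeric(K)
    beta <- out$beta
    for (k in seq_len(K)) {
      A <- matrix(0, p, p)
      b <- numeric(p)
      for (pat in design$patterns) {
        w <- posterior[pat$idx, k]
        A <- A + sum(w) * crossprod(pat$X)
        b <- b + crossprod(pat$X, crossprod(pat$Y, w))
      }
      sol <- tryCatch(solve(A, b), error = function(e) beta[, k])
      beta[, k] <- sol
      for (pat in design$patterns) {
        w <- posterior[pat$idx, k]
        E <- pat$Y - rep(as.vector(pat$X %*% beta[, k]),
                         each = nrow(pat$Y))
        rss[k] <- rss[k] + sum(w * rowSums(E^2))
        wn[k] <- wn[k] + sum(w) * length(pat$times)
      }
    }
    out$beta <- beta
    out$sigma2 <- if (st$residual_mode == "class") {
      pmax(rss / pmax(wn, 1e-12), 1e-12)
    } else {
      max(sum(rss) / sum(wn), 1e-12)
    }
    return(out)
  }

  out$beta <- update_beta(out, posterior, design)
  stats <- cov_suffstats(out, posterior, design)
  theta0 <- pack_cov(out)
  q0 <- q_cov(theta0, out, stats, design, control$ridge)
  opt <- stats::optim(theta0, q_cov, params = out, stats = stats,
                      design = design, ridge = control$ridge,
                      method = "BFGS",
                      control = list(maxit = control$mstep_maxit))
  if (is.finite(opt$value) && opt$value <= q0) {
    out <- unpack_cov(opt$par, out)
  }
  out
}

## ---- initialisation --------------------------------------------------------

# per-subject OLS polynomial coefficients (degree capped by n_i - 1, padded)
subject_coefs <- function(design) {
  st <- design$structure
  p <- st$fixed_degree + 1L
  out <- matrix(0, length(design$subjects), p)
  for (pat in design$patterns) {
    n_t <- length(pat$times)
    d <- min(p, n_t)
    Xd <- pat$X[, seq_len(d), drop = FALSE]
    cf <- t(solve(crossprod(Xd) + diag(1e-10, d), crossprod(Xd, t(pat$Y))))
    out[pat$idx, seq_len(d)] <- cf
  }
  out
}

init_from_assignment <- function(assign, design, structure) {
  K <- structure$n_classes
  N <- length(design$subjects)
  post <- matrix(1e-6, N, K)
  post[cbind(seq_len(N), assign)] <- 1
  post <- post / rowSums(post)

  # closed-form fixed effects / residual variance from hard classes
  p <- structure$fixed_degree + 1L
  beta <- matrix(0, p, K)
  rss <- wn <- numeric(K)
  for (k in seq_len(K)) {
    A <- diag(1e-8, p); b <- numeric(p)
    for (pat in design$patterns) {
      w <- post[pat$idx, k]
      A <- A + sum(w) * crossprod(pat$X)
      b <- b + crossprod(pat$X, crossprod(pat$Y, w))
    }
    beta[, k] <- solve(A, b)
    for (pat in design$patterns) {
      w <- post[pat$idx, k]
      E <- pat$Y - rep(as.vector(pat$X %*% beta[, k]), each = nrow(pat$Y))
      rss[k] <- rss[k] + sum(w * rowSums(E^2))
      wn[k] <- wn[k] + sum(w) * length(pat$times)
    }
  }
  s2 <- pmax(rss / pmax(wn, 1), 1e-6)
  sigma2 <- if (structure$residual_mode == "class") s2 else max(mean(s2), 1e-6)

  q <- n_random(structure)
  B <- omega <- B_list <- NULL
  if (q > 0L) {
    cf <- subject_coefs(design)[, seq_len(q), drop = FALSE]
    v <- pmax(apply(cf, 2L, stats::var), 0.05)
    B <- diag(0.5 * v, q)
    if (structure$random_cov_mode == "proportional") omega <- rep(1, K)
    if (structure$random_cov_mode == "class")
      B_list <- replicate(K, B, simplify = FALSE)
    if (structure$random_cov_mode %in% c("none")) B <- NULL
  }
  pi0 <- pmax(colMeans(post), 1e-4)
  lctm_params(structure, pi0 / sum(pi0), beta, sigma2,
              B = if (structure$random_cov_mode %in% c("shared", "proportional")) B,
              omega = omega, B_list = B_list)
}

start_assignment <- function(start, design, structure, seed) {
  K <- structure$n_classes
  N <- length(design$subjects)
  if (K == 1L) return(rep(1L, N))
  cf <- subject_coefs(design)
  set.seed((seed + 7919L * start) %% .Machine$integer.max)
  if (start == 1L) {
    km <- stats::kmeans(cf, centers = K, nstart = 5L, iter.max = 50L)
    return(km$cluster)
  }
  # randomised start: K distinct subjects as centres, nearest-centre assignment
  ctr <- cf[sample.int(N, K), , drop = FALSE]
  d2 <- sapply(seq_len(K), function(k) rowSums(sweep(cf, 2L, ctr[k, ])^2))
  max.col(-d2, ties.method = "first")
}

## ---- single EM run ---------------------------------------------------------

run_em <- function(params, design, config) {
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  status <- "max_iter"
  post <- NULL
  for (it in seq_len(config$max_iter)) {
    es <- tryCatch(e_step(params, design, config$ridge),
                   error = function(e) NULL)
    if (is.null(es)) { status <- "numerical_failure"; break }
    ll_trace <- c(ll_trace, es$loglik)
    post <- es$posterior
    if (it > 1L &&
        abs(es$loglik - ll_old) <= config$tol * (abs(ll_old) + 1)) {
      converged <- TRUE; status <- "converged"; break
    }
    ll_old <- es$loglik
    new_params <- tryCatch(m_step(post, design, params, config),
                           error = function(e) NULL)
    if (is.null(new_params)) { status <- "numerical_failure"; break }
    params <- new_params
    if (any(params$pi < 1e-10)) { status <- "degenerate"; break }
  }
  list(params = params, posterior = post,
       loglik = if (length(ll_trace)) ll_trace[length(ll_trace)] else -Inf,
       ll_trace = ll_trace, converged = converged, status = status,
       n_iter = length(ll_trace))
}

## canonical class order: descending mixing proportion
reorder_classes <- function(params, posterior) {
  st <- params$structure
  K <- st$n_classes
  ord <- order(params$pi, decreasing = TRUE)
  params$pi <- params$pi[ord]
  params$beta <- params$beta[, ord, drop = FALSE]
  if (st$residual_mode == "class") params$sigma2 <- params$sigma2[ord]
  if (st$random_cov_mode == "proportional") {
    om <- params$omega[ord]
    params$B <- om[K]^2 * params$B      # rescale so the last class has scale 1
    params$omega <- om / om[K]
  }
  if (st$random_cov_mode == "class") params$B_list <- params$B_list[ord]
  posterior <- posterior[, ord, drop = FALSE]
  list(params = params, posterior = posterior)
}

#' Fit a latent class trajectory model by maximum likelihood
#'
#' Multi-start EM estimation of the mixture of polynomial mixed-effects
#' models described in [model_structure()]. Start 1 clusters per-subject OLS
#' polynomial coefficients by k-means; further starts randomise the initial
#' partition under `config$seed`, so a fit is exactly reproducible. The best
#' converged start (highest log-likelihood) is returned with classes in
#' canonical order (descending mixing proportion) and the posterior columns
#' permuted to match. Non-convergence is an explicit, reported state — it is
#' informative, not an error — and per-start diagnostics are retained.
#'
#' @param data a [trajectory_data] object.
#' @param structure a [model_structure].
#' @param config a [fit_config].
#' @return An object of class `lctm_fit` with elements `structure`, `pi`,
#'   `beta`, `B` / `omega` / `B_list`, `sigma2`, `loglik`, `n_params`,
#'   `n_subjects`, `posterior` (rows named by subject), `assignment` (modal
#'   class, ties to the lowest class index), `converged`, `status`,
#'   `ll_trace`, `starts` (per-start diagnostics), `n_starts_used`, `seed`,
#'   and `small_classes` (indices below the advisory size threshold).
#' @examples
#' sim <- simulate_trajectories(simulation_config(
#'   n_subjects = 120, structure = model_structure("A", 2),
#'   beta = cbind(c(22, 1, 0), c(30, 1, 0)), pi = c(0.5, 0.5),
#'   sigma2 = 1, seed = 42))
#' fit <- fit_lctm(sim$data, model_structure("A", 2),
#'                 fit_config(n_starts = 2, seed = 1))
#' fit$pi
#' @export
fit_lctm <- function(data, structure, config = fit_config()) {
  stopifnot(inherits(structure, "model_structure"),
            inherits(config, "fit_config"))
  design <- build_design(data, structure)
  q <- n_random(structure)
  if (q > 0L && !any(design$n_obs > q)) {
    stop("structure ", structure$code, " needs subjects with more than ", q,
         " observations", call. = FALSE)
  }

  runs <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    assign0 <- start_assignment(s, design, structure, config$seed)
    init <- tryCatch(init_from_assignment(assign0, design, structure),
                     error = function(e) NULL)
    runs[[s]] <- if (is.null(init)) {
      list(loglik = -Inf, converged = FALSE, status = "init_failure",
           n_iter = 0L)
    } else {
      run_em(init, design, config)
    }
  }
  diag_tab <- data.frame(
    start = seq_len(config$n_starts),
    loglik = vapply(runs, `[[`, numeric(1), "loglik"),
    converged = vapply(runs, `[[`, logical(1), "converged"),
    iterations = vapply(runs, function(r) as.integer(r$n_iter), integer(1)),
    status = vapply(runs, `[[`, character(1), "status")
  )
  ok <- which(is.finite(diag_tab$loglik))
  if (!length(ok)) {
    stop("all EM starts failed; per-start diagnostics:\n",
         paste(utils::capture.output(print(diag_tab)), collapse = "\n"),
         call. = FALSE)
  }
  conv <- ok[diag_tab$converged[ok]]
  pick <- if (length(conv)) conv[which.max(diag_tab$loglik[conv])]
          else ok[which.max(diag_tab$loglik[ok])]
  best <- runs[[pick]]

  ro <- reorder_classes(best$params, best$posterior)
  post <- ro$posterior
  rownames(post) <- design$subjects
  assignment <- max.col(post, ties.method = "first")
  names(assignment) <- design$subjects

  small <- which(ro$params$pi < config$min_class_prop_warn)
  out <- structure(c(
    ro$params[c("structure", "pi", "beta", "sigma2", "B", "omega", "B_list")],
    list(loglik = best$loglik,
         n_subjects = length(design$subjects),
         n_params = count_parameters(structure),
         posterior = post,
         assignment = assignment,
         converged = best$converged,
         status = best$status,
         ll_trace = best$ll_trace,
         n_iter = best$n_iter,
         starts = diag_tab,
         n_starts_used = config$n_starts,
         seed = config$seed,
         small_classes = small)),
    class = "lctm_fit")
  out
}

#' @export
print.lctm_fit <- function(x, ...) {
  st <- x$structure
  cat(sprintf("Latent class trajectory model %s, K = %d (%s)\n", st$code,
              st$n_classes,
              if (x$converged) "converged" else paste0("NOT converged: ", x$status)))
  cat(sprintf("  logLik %.3f | parameters %d | subjects %d | BIC %s\n",
              x$loglik, x$n_params, x$n_subjects,
              if (x$converged) sprintf("%.3f", BIC(x)) else "undefined"))
  cat("  class proportions:", paste(sprintf("%.3f", x$pi), collapse = "  "), "\n")
  if (length(x$small_classes))
    cat("  advisory: class(es)", paste(x$small_classes, collapse = ", "),
        "below the minimum-size threshold\n")
  invisible(x)
}

#' @export
logLik.lctm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2 loglik + p log(N)` with `N` the number of subjects and `p` the
#' structure's free-parameter count ([count_parameters()]). Undefined for a
#' non-converged fit: attempting it is an error, mirroring the convention of
#' reporting failed fits rather than their criteria.
#'
#' @param object an `lctm_fit`.
#' @param ... unused.
#' @return scalar BIC.
#' @export
BIC.lctm_fit <- function(object, ...) {
  if (!object$converged) {
    stop("BIC undefined: model did not converge (status: ", object$status, ")",
         call. = FALSE)
  }
  -2 * object$loglik + object$n_params * log(object$n_subjects)
}

# parameters of a fitted model as an lctm_params (shared plumbing)
fit_params <- function(fit) {
  lctm_params(fit$structure, fit$pi, fit$beta, fit$sigma2,
              B = fit$B, omega = fit$omega, B_list = fit$B_list)
}

#' Class mean trajectories on a time grid
#'
#' @param fit an `lctm_fit` (or [lctm_params]).
#' @param grid numeric vector of times on the natural axis.
#' @return matrix `length(grid) x K` of class mean outcome values.
#' @export
class_means <- function(fit, grid) {
  st <- fit$structure
  X <- poly_design(transform_time(grid, st), st$fixed_degree)
  M <- X %*% fit$beta
  dimnames(M) <- list(NULL, paste0("class_", seq_len(st$n_classes)))
  M
}
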