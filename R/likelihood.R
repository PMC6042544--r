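#' Assemble a parameter set for a latent class trajectory model
#'
#' Low-level constructor used by the EM fitter, the simulator and the tests.
#' Validates the mixture invariants (proportions on the simplex, symmetric
#' positive semi-definite covariance blocks, positive variances).
#'
#' @param structure a [model_structure].
#' @param pi mixing proportions, length K, summing to 1.
#' @param beta fixed-effect coefficient matrix, `(fixed_degree + 1) x K`
#'   (column k is the class-k polynomial).
#' @param sigma2 residual variance: scalar, or length K for structure B.
#' @param B shared random-effect covariance (`q x q`), structures C-F.
#' @param omega class scale factors, length K with `omega[K] = 1`, structure F
#'   (class-k covariance is `omega[k]^2 * B`).
#' @param B_list list of K class-specific covariance matrices, structure G.
#' @return list of class `lctm_params`.
#' @export
lctm_params <- function(structure, pi, beta, sigma2,
                        B = NULL, omega = NULL, B_list = NULL) {
  stopifnot(inherits(structure, "model_structure"))
  K <- structure$n_classes
  p <- structure$fixed_degree + 1L
  q <- n_random(structure)
  beta <- as.matrix(beta)
  stopifnot(length(pi) == K, all(pi >= 0), abs(sum(pi) - 1) < 1e-8,
            nrow(beta) == p, ncol(beta) == K)
  if (structure$residual_mode == "class") {
    stopifnot(length(sigma2) == K, all(sigma2 > 0))
  } else {
    stopifnot(length(sigma2) == 1L, sigma2 > 0)
  }
  check_psd <- function(M, lab) {
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
      stop(lab, " is not symmetric", call. = FALSE)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop(lab, " is not positive semi-definite", call. = FALSE)
  }
  if (structure$random_cov_mode %in% c("shared", "proportional")) {
    stopifnot(is.matrix(B), nrow(B) == q, ncol(B) == q)
    check_psd(B, "B")
  }
  if (structure$random_cov_mode == "proportional") {
    if (is.null(omega)) omega <- rep(1, K)
    stopifnot(length(omega) == K, all(omega > 0))
    if (abs(omega[K] - 1) > 1e-8)
      stop("omega[K] must be 1 (identifiability convention)", call. = FALSE)
  }
  if (structure$random_cov_mode == "class") {
    stopifnot(is.list(B_list), length(B_list) == K)
    for (k in seq_len(K)) check_psd(B_list[[k]], paste0("B_", k))
  }
  structure(list(structure = structure, pi = as.numeric(pi), beta = beta,
                 sigma2 = as.numeric(sigma2), B = B, omega = omega,
                 B_list = B_list),
            class = "lctm_params")
}

# class-k random-effect covariance matrix (NULL for A/B)
class_cov <- function(params, k) {
  st <- params$structure
  switch(st$random_cov_mode,
         none = NULL,
         shared = params$B,
         proportional = params$omega[k]^2 * params$B,
         class = params$B_list[[k]])
}

class_sigma2 <- function(params, k) {
  if (params$structure$residual_mode == "class") params$sigma2[k]
  else params$sigma2
}

#' Marginal covariance of one subject's observations under one class
#'
#' With random effects integrated out, the class-k marginal covariance of a
#' subject with random design `Z_i` is
#' \eqn{V_{ik} = Z_i B_k Z_i' + \sigma_k^2 I}, where \eqn{B_k} is absent
#' (structures A/B), shared (C-E), proportionally scaled (F:
#' \eqn{\omega_k^2 B}) or class-specific (G), and \eqn{\sigma_k^2} is common
#' except under structure B.
#'
#' @param params an [lctm_params] (or fitted model) parameter set.
#' @param Z random-effect design matrix of the subject (`n_i x q`); ignored
#'   for structures without random effects, where only `n_obs` matters.
#' @param k class index.
#' @param n_obs number of observations (defaults to `nrow(Z)`).
#' @return `n_obs x n_obs` covariance matrix.
#' @export
marginal_covariance <- function(params, Z, k, n_obs = if (is.null(Z)) NULL else nrow(Z)) {
  s2 <- class_sigma2(params, k)
  Bk <- class_cov(params, k)
  if (is.null(Bk)) {
    if (is.null(n_obs)) stop("n_obs required for structures without random effects")
    return(diag(s2, n_obs))
  }
  V <- Z %*% Bk %*% t(Z)
  diag(V) <- diag(V) + s2
  (V + t(V)) / 2
}

# Cholesky, with an escalating diagonal ridge as fallback; NULL when hopeless
chol_ridge <- function(V, ridge) {
  n <- nrow(V)
  for (r in c(0, ridge, ridge * 1e2, ridge * 1e4)) {
    R <- tryCatch(chol(V + diag(r, n)), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

# N x K matrix of class-conditional log densities log phi(y_i; X_i beta_k, V_ik)
log_density_matrix <- function(params, design, ridge = 1e-8) {
  st <- params$structure
  K <- st$n_classes
  N <- length(design$subjects)
  out <- matrix(NA_real_, N, K)
  for (pat in design$patterns) {
    n_t <- length(pat$times)
    Yt <- t(pat$Y)                       # n_t x m
    for (k in seq_len(K)) {
      V <- marginal_covariance(params, pat$Z, k, n_obs = n_t)
      R <- chol_ridge(V, ridge)
      if (is.null(R)) stop("singular marginal covariance in class ", k,
                           call. = FALSE)
      mu <- as.vector(pat$X %*% params$beta[, k])
      C <- backsolve(R, Yt - mu, transpose = TRUE)
      quad <- colSums(C^2)
      out[pat$idx, k] <- -0.5 * (n_t * log(2 * pi) +
                                   2 * sum(log(diag(R))) + quad)
    }
  }
  out
}

row_log_sum_exp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Marginal mixture log-likelihood
#'
#' \eqn{\ell = \sum_i \log \sum_k \pi_k \phi(y_i; X_i\beta_k, V_{ik})},
#' evaluated with per-class Cholesky factorisations and a log-sum-exp over
#' classes so small densities do not underflow.
#'
#' @param params an [lctm_params] parameter set.
#' @param design an [build_design()] object for the same structure.
#' @param ridge diagonal jitter used when factorising near-singular
#'   covariances.
#' @return scalar log-likelihood.
#' @export
lctm_loglik <- function(params, design, ridge = 1e-8) {
  ld <- log_density_matrix(params, design, ridge)
  lw <- sweep(ld, 2L, log(params$pi), `+`)
  sum(row_log_sum_exp(lw))
}

#' E step: posterior class membership probabilities
#'
#' \eqn{p_{ik} = \pi_k \phi_{ik} / \sum_l \pi_l \phi_{il}}, computed in log
#' space and renormalised row-wise, so every row sums to 1 even when all
#' class densities are tiny.
#'
#' @inheritParams lctm_loglik
#' @return list with `posterior` (N x K matrix, rows summing to 1) and
#'   `loglik`.
#' @export
e_step <- function(params, design, ridge = 1e-8) {
  ld <- log_density_matrix(params, design, ridge)
  lw <- sweep(ld, 2L, log(params$pi), `+`)
  lse <- row_log_sum_exp(lw)
  post <- exp(lw - lse)
  post <- post / rowSums(post)   # exact renormalisation
  rownames(post) <- design$subjects
  list(posterior = post, loglik = sum(lse))
}
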