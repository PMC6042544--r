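#' Specify a latent class trajectory model structure
#'
#' The model family is a finite mixture of polynomial mixed-effects models:
#' subject i in latent class k has
#' \deqn{y_{ij} = x_{ij}' \beta_k + z_{ij}' b_i + \epsilon_{ij},}
#' with polynomial design rows in a transformed time, class-specific fixed
#' effects \eqn{\beta_k}, subject random effects \eqn{b_i} and Gaussian
#' residual noise. Seven covariance structures, labelled A-G, form a ladder of
#' increasingly flexible within-class covariance assumptions:
#'
#' \describe{
#'   \item{A}{Homoscedastic fixed effects: no random effects, common residual
#'     variance \eqn{\sigma^2}.}
#'   \item{B}{Heteroscedastic fixed effects: no random effects, class-specific
#'     residual variances \eqn{\sigma_k^2}.}
#'   \item{C}{Random intercept, shared covariance, common \eqn{\sigma^2}.}
#'   \item{D}{Random slope (intercept + linear), shared covariance.}
#'   \item{E}{Random quadratic, equal: shared covariance matrix B across
#'     classes.}
#'   \item{F}{Random quadratic, proportional: class covariance
#'     \eqn{\omega_k^2 B} with shared B and class scale factors
#'     (\eqn{\omega_K = 1} for identifiability).}
#'   \item{G}{Random quadratic, unrestricted: class-specific covariance
#'     matrices \eqn{B_k}.}
#' }
#'
#' The structure code uniquely determines the random-effect order, the
#' residual mode and the covariance mode; only the class count and fixed
#' polynomial degree are free.
#'
#' @param code one of `"A"`..`"G"`.
#' @param n_classes number of latent classes K (>= 1).
#' @param fixed_degree degree of the class mean polynomial (default 2,
#'   quadratic). The random-effect order implied by `code` must not exceed it.
#' @param time_transform numeric `c(center, scale)`: times enter the design as
#'   `(t - center) / scale`. The default `c(45, 10)` centres mid-adulthood age
#'   and rescales to roughly decade units so the quadratic design is well
#'   conditioned; fitted trajectories are always reported back on the natural
#'   time axis.
#' @return An object of class `model_structure`.
#' @examples
#' model_structure("F", n_classes = 5)
#' count_parameters(model_structure("F", 5))  # 30
#' @export
model_structure <- function(code, n_classes, fixed_degree = 2,
                            time_transform = c(45, 10)) {
  code <- match.arg(toupper(code), LETTERS[1:7])
  n_classes <- as.integer(n_classes)
  fixed_degree <- as.integer(fixed_degree)
  stopifnot(n_classes >= 1L, fixed_degree >= 0L,
            is.numeric(time_transform), length(time_transform) == 2L,
            time_transform[2] != 0)
  random_degree <- switch(code,
                          A = -1L, B = -1L, C = 0L, D = 1L,
                          E = 2L, F = 2L, G = 2L)
  if (random_degree > fixed_degree) {
    stop("structure ", code, " needs random-effect order ", random_degree,
         " <= fixed_degree (", fixed_degree, ")", call. = FALSE)
  }
  structure(list(
    code = code,
    n_classes = n_classes,
    fixed_degree = fixed_degree,
    random_degree = random_degree,
    residual_mode = if (code == "B") "class" else "common",
    random_cov_mode = switch(code, A = "none", B = "none",
                             C = "shared", D = "shared", E = "shared",
                             F = "proportional", G = "class"),
    time_transform = as.numeric(time_transform)
  ), class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  desc <- switch(x$code,
                 A = "Homoscedastic (fixed effects)",
                 B = "Heteroscedastic (fixed effects)",
                 C = "Random intercept",
                 D = "Random slope",
                 E = "Random quadratic, Equal",
                 F = "Random quadratic, Proportional",
                 G = "Random quadratic, Unrestricted")
  cat(sprintf("Model %s: %s | K = %d, fixed degree %d\n",
              x$code, desc, x$n_classes, x$fixed_degree))
  cat(sprintf("  time transform: (t - %g) / %g | free parameters: %d\n",
              x$time_transform[1], x$time_transform[2], count_parameters(x)))
  invisible(x)
}

# number of random-effect terms (columns of Z); 0 for A/B
n_random <- function(structure) max(structure$random_degree + 1L, 0L)

#' Count free parameters of a model structure
#'
#' The count that enters the BIC penalty: per-class fixed-effect polynomial
#' coefficients, K - 1 free mixing proportions, the random-effect covariance
#' block (none for A/B; one shared q x q symmetric matrix for C-F, plus K - 1
#' proportional scale factors for F; K class-specific matrices for G, with
#' q = random order + 1), and the residual variance (one, or K for model B).
#'
#' For quadratic model F this is 5K + 5: 10, 15, 20, ... parameters at
#' K = 1, 2, 3, ...
#'
#' @param structure a [model_structure].
#' @return integer parameter count.
#' @export
count_parameters <- function(structure) {
  stopifnot(inherits(structure, "model_structure"))
  K <- structure$n_classes
  q <- n_random(structure)
  p_fixed <- (structure$fixed_degree + 1L) * K
  p_mix <- K - 1L
  p_cov <- switch(structure$random_cov_mode,
                  none = 0L,
                  shared = (q * (q + 1L)) %/% 2L,
                  proportional = (q * (q + 1L)) %/% 2L + (K - 1L),
                  class = K * ((q * (q + 1L)) %/% 2L))
  p_resid <- if (structure$residual_mode == "class") K else 1L
  p_fixed + p_mix + p_cov + p_resid
}

transform_time <- function(times, structure) {
  (times - structure$time_transform[1]) / structure$time_transform[2]
}

poly_design <- function(tt, degree) {
  outer(tt, 0:degree, `^`)
}

#' Build per-subject design matrices
#'
#' Converts a trajectory dataset into the sufficient per-subject pieces the
#' likelihood needs: outcome vector `y_i`, fixed design `X_i` (polynomial in
#' transformed time, `fixed_degree + 1` columns) and random design `Z_i` (the
#' first `random_degree + 1` columns of `X_i`; absent for structures A/B).
#' Subjects sharing the same observation-time pattern are grouped so the
#' per-pattern covariance factorisations are computed once, which is what
#' makes near-balanced designs (e.g. a common 4-visit grid) fast.
#'
#' @param data a [trajectory_data] object.
#' @param structure a [model_structure].
#' @return An object of class `lctm_design`: list with elements
#'   `subjects` (ids in canonical order), `n_obs` (per subject) and
#'   `patterns`, a list of groups each holding `times`, `X`, `Z`, the stacked
#'   outcome matrix `Y` (subjects x occasions) and the subject indices `idx`.
#' @export
build_design <- function(data, structure) {
  stopifnot(inherits(data, "trajectory_data"),
            inherits(structure, "model_structure"))
  subj <- subjects(data)
  tt <- transform_time(data$time, structure)
  if (!all(is.finite(tt))) stop("non-finite transformed time", call. = FALSE)
  q <- n_random(structure)

  split_idx <- split(seq_len(nrow(data)), match(data$id, subj))
  keys <- vapply(split_idx, function(ix) paste(signif(tt[ix], 12), collapse = ";"),
                 character(1))
  groups <- split(seq_along(subj), keys)
  # deterministic pattern order: by first subject appearing in the pattern
  groups <- groups[order(vapply(groups, min, integer(1)))]

  patterns <- lapply(groups, function(g) {
    ix1 <- split_idx[[g[1]]]
    times <- data$time[ix1]
    X <- poly_design(tt[ix1], structure$fixed_degree)
    Y <- do.call(rbind, lapply(g, function(i) data$y[split_idx[[i]]]))
    list(times = times, tt = tt[ix1], X = X,
         Z = if (q > 0L) X[, seq_len(q), drop = FALSE] else NULL,
         Y = Y, idx = g)
  })
  structure(list(subjects = subj,
                 n_obs = lengths(split_idx),
                 n_total = nrow(data),
                 patterns = patterns,
                 structure = structure),
            class = "lctm_design")
}
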