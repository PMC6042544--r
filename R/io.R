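#' Serialise a fitted model to JSON
#'
#' Writes the estimated parameters, fit metadata and per-start diagnostics as
#' a documented JSON structure; the (potentially large) posterior matrix is
#' written separately with [write_posterior()]. [read_lctm()] restores an
#' `lctm_fit` (without the posterior) good enough for trajectory evaluation,
#' parameter inspection and BIC.
#'
#' @param fit an `lctm_fit`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_lctm <- function(fit, path) {
  st <- fit$structure
  obj <- list(
    structure = list(code = st$code, n_classes = st$n_classes,
                     fixed_degree = st$fixed_degree,
                     time_transform = st$time_transform),
    pi = fit$pi,
    beta = unname(as.data.frame(fit$beta)),
    sigma2 = fit$sigma2,
    B = if (!is.null(fit$B)) unname(as.data.frame(fit$B)),
    omega = fit$omega,
    B_list = if (!is.null(fit$B_list))
      lapply(fit$B_list, function(m) unname(as.data.frame(m))),
    loglik = fit$loglik, n_params = fit$n_params,
    n_subjects = fit$n_subjects, converged = fit$converged,
    status = fit$status, n_iter = fit$n_iter,
    n_starts_used = fit$n_starts_used, seed = fit$seed,
    starts = fit$starts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_lctm
#' @param path path to a JSON file written by [write_lctm()].
#' @export
read_lctm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- model_structure(obj$structure$code, obj$structure$n_classes,
                        obj$structure$fixed_degree,
                        obj$structure$time_transform)
  structure(list(
    structure = st, pi = obj$pi, beta = as.matrix(obj$beta),
    sigma2 = obj$sigma2,
    B = if (!is.null(obj$B)) as.matrix(obj$B),
    omega = obj$omega,
    B_list = if (!is.null(obj$B_list)) lapply(obj$B_list, as.matrix),
    loglik = obj$loglik, n_params = obj$n_params,
    n_subjects = obj$n_subjects, converged = obj$converged,
    status = obj$status, n_iter = obj$n_iter,
    n_starts_used = obj$n_starts_used, seed = obj$seed,
    starts = obj$starts, posterior = NULL, assignment = NULL,
    small_classes = integer(0)), class = "lctm_fit")
}
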