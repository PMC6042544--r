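#' Degrees of separation between class mean trajectories
#'
#' Summarises how far apart the fitted class mean trajectories are, on a time
#' grid, using a multivariate Mahalanobis distance: with `mu_k` the class-k
#' mean trajectory evaluated at the T grid times and `Vbar` the
#' mixing-proportion-weighted average of the class marginal covariances on
#' the grid,
#' \deqn{d_{kl} = \sqrt{(\mu_k - \mu_l)' \bar V^{-1} (\mu_k - \mu_l)},}
#' and the degrees-of-separation statistic is the smallest pairwise distance
#' normalised per grid point, `DoS = min_{k<l} d_kl / sqrt(T)`. It is zero
#' exactly when all mean trajectories coincide on the grid; larger values
#' mean better-separated classes, and a small value suggests a model with
#' fewer classes. The raw pairwise matrix is returned so other summaries can
#' be formed.
#'
#' @param fit a converged `lctm_fit` with K >= 2.
#' @param grid numeric vector of T >= 2 evaluation times (natural axis).
#' @return list of class `discrimination_report`: `dos`, `pairwise` (K x K
#'   symmetric distance matrix), `grid`.
#' @export
degrees_of_separation <- function(fit, grid) {
  stopifnot(inherits(fit, "lctm_fit"), length(grid) >= 2L)
  st <- fit$structure
  K <- st$n_classes
  if (K < 2L) stop("degrees of separation needs K >= 2", call. = FALSE)
  Tn <- length(grid)
  params <- fit_params(fit)
  Xg <- poly_design(transform_time(grid, st), st$fixed_degree)
  Zg <- if (n_random(st) > 0L) Xg[, seq_len(n_random(st)), drop = FALSE]
  M <- Xg %*% fit$beta
  Vbar <- matrix(0, Tn, Tn)
  for (k in seq_len(K)) {
    Vbar <- Vbar + fit$pi[k] * marginal_covariance(params, Zg, k, n_obs = Tn)
  }
  R <- chol_ridge(Vbar, 1e-10)
  if (is.null(R)) stop("singular pooled covariance on the grid", call. = FALSE)
  D <- matrix(0, K, K)
  for (k in seq_len(K - 1L)) {
    for (l in (k + 1L):K) {
      d <- backsolve(R, M[, k] - M[, l], transpose = TRUE)
      D[k, l] <- D[l, k] <- sqrt(sum(d^2))
    }
  }
  structure(list(dos = min(D[upper.tri(D)]) / sqrt(Tn),
                 pairwise = D, grid = grid),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("Degrees of separation DoS = %.4f (grid of %d times)\n",
              x$dos, length(x$grid)))
  cat("pairwise Mahalanobis distances:\n")
  print(round(x$pairwise, 3))
  invisible(x)
}

#' Posterior-weighted residual envelopes
#'
#' A check on the covariance-structure assumptions: for each class, residuals
#' from the class mean curve are pooled within time bins, and the local
#' posterior-weighted mean and SD are computed, giving an envelope
#' `mean +/- SD` per class over time. Approximately parallel envelope
#' boundaries support homoscedastic residuals; non-parallel boundaries
#' indicate heteroscedasticity, and differing envelope widths across classes
#' suggest unaccounted between-class variability.
#'
#' Residuals are grouped by exact observation time when the design is
#' near-balanced (at most `max_exact_times` distinct times); otherwise by
#' fixed-width time bins. Bins whose total posterior weight falls below
#' `weight_floor` are reported missing rather than zero.
#'
#' @param fit an `lctm_fit`.
#' @param data the [trajectory_data] the model was fitted to.
#' @param bin_width bin width in time units when binning is needed
#'   (default 5).
#' @param max_exact_times largest number of distinct observation times still
#'   treated as a balanced design (default 12).
#' @param weight_floor minimum effective (posterior) weight for a bin to be
#'   reported (default 1).
#' @param parallel_ratio boundary SDs whose max/min ratio across bins is at
#'   most this are flagged `"parallel"` (default 1.5).
#' @return list of class `envelope_report`: `table` (data.frame with class,
#'   time, n_eff, mean, sd, lower, upper) and `parallel` (per-class flag,
#'   `"parallel"` or `"non-parallel"`).
#' @export
envelope_residuals <- function(fit, data, bin_width = 5, max_exact_times = 12,
                               weight_floor = 1, parallel_ratio = 1.5) {
  stopifnot(inherits(fit, "lctm_fit"), inherits(data, "trajectory_data"))
  st <- fit$structure
  K <- st$n_classes
  tt <- transform_time(data$time, st)
  X <- poly_design(tt, st$fixed_degree)
  subj_idx <- match(data$id, rownames(fit$posterior))
  if (anyNA(subj_idx)) stop("dataset subjects not matching the fit", call. = FALSE)

  times <- sort(unique(data$time))
  if (length(times) <= max_exact_times) {
    bin_of <- match(data$time, times)
    bin_time <- times
  } else {
    brks <- seq(floor(min(data$time)), ceiling(max(data$time)) + bin_width,
                by = bin_width)
    bin_of <- findInterval(data$time, brks, rightmost.closed = TRUE)
    bin_time <- brks[-length(brks)] + bin_width / 2
  }
  nb <- length(bin_time)

  rows <- list()
  flags <- character(K)
  for (k in seq_len(K)) {
    r <- data$y - as.vector(X %*% fit$beta[, k])
    w <- fit$posterior[subj_idx, k]
    m <- s <- neff <- rep(NA_real_, nb)
    for (b in seq_len(nb)) {
      ix <- bin_of == b
      sw <- sum(w[ix])
      neff[b] <- sw
      if (sw >= weight_floor) {
        mb <- sum(w[ix] * r[ix]) / sw
        vb <- sum(w[ix] * (r[ix] - mb)^2) / sw
        m[b] <- mb
        s[b] <- sqrt(max(vb, 0))
      }
    }
    ok <- !is.na(s) & s > 0
    flags[k] <- if (sum(ok) >= 2L && max(s[ok]) / min(s[ok]) <= parallel_ratio)
      "parallel" else if (sum(ok) >= 2L) "non-parallel" else "parallel"
    rows[[k]] <- data.frame(class = k, time = bin_time, n_eff = neff,
                            mean = m, sd = s, lower = m - s, upper = m + s)
  }
  structure(list(table = do.call(rbind, rows), parallel = flags),
            class = "envelope_report")
}

## scalar Cohen kappa on a fixed (square) count table
cohen_kappa <- function(tab, weighting = c("quadratic", "linear", "unweighted")) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  K <- nrow(tab)
  if (ncol(tab) != K) stop("kappa requires a square table", call. = FALSE)
  n <- sum(tab)
  p <- tab / n
  e <- outer(rowSums(p), colSums(p))
  W <- switch(weighting,
              unweighted = 1 - diag(K),
              linear = abs(outer(seq_len(K), seq_len(K), `-`)) / (K - 1),
              quadratic = (outer(seq_len(K), seq_len(K), `-`) / (K - 1))^2)
  denom <- sum(W * e)
  if (denom <= 0) return(NA_real_)   # degenerate marginals: undefined
  1 - sum(W * p) / denom
}

#' Cohen's kappa with disagreement weights and label-assignment search
#'
#' Chance-corrected agreement for a K x K cross-classification:
#' `kappa = 1 - sum(w * p) / sum(w * e)` with observed cell proportions `p`,
#' chance proportions `e` (outer product of the margins) and disagreement
#' weights `w` — 0/1 (unweighted), `|i-j|/(K-1)` (linear) or its square
#' (quadratic, the default, which is the scheme that reproduces the weighted
#' kappa convention for ordinal categories). Because latent classes carry no
#' intrinsic labels, `optimize_assignment = TRUE` searches all row-label
#' permutations exhaustively (exact for K <= 8) and returns the best
#' assignment with its kappa.
#'
#' @param tab K x K count table (rows: latent classes, columns: reference
#'   categories).
#' @param weighting `"quadratic"` (default), `"linear"` or `"unweighted"`.
#' @param optimize_assignment search row permutations for the maximal kappa.
#' @return list: `kappa`, `weighting`, `assignment` (row permutation used;
#'   identity when not optimised), `table` (the permuted table).
#' @examples
#' tab <- diag(c(10, 20, 30))
#' weighted_kappa(tab)$kappa  # 1: perfect agreement
#' @export
weighted_kappa <- function(tab, weighting = c("quadratic", "linear", "unweighted"),
                           optimize_assignment = FALSE) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  K <- nrow(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!optimize_assignment) {
    return(list(kappa = cohen_kappa(tab, weighting), weighting = weighting,
                assignment = seq_len(K), table = tab))
  }
  if (K > 8L) stop("exhaustive assignment search limited to K <= 8",
                   call. = FALSE)
  best <- list(kappa = -Inf, assignment = seq_len(K))
  for (p in all_permutations(K)) {
    p <- unlist(p)
    kp <- cohen_kappa(tab[order(p), , drop = FALSE], weighting)
    if (!is.na(kp) && kp > best$kappa) best <- list(kappa = kp, assignment = p)
  }
  list(kappa = best$kappa, weighting = weighting,
       assignment = best$assignment,
       table = tab[order(best$assignment), , drop = FALSE])
}

#' Concordance between two fitted models
#'
#' Cross-tabulates the modal class assignments of two models fitted to the
#' same subjects and reports optimal-assignment Cohen's kappa, unweighted and
#' weighted. Used to compare the partitions produced by different covariance
#' structures.
#'
#' @param model_a,model_b `lctm_fit` objects fitted to identical subject
#'   sets with equal class counts.
#' @param weighting weighting scheme for the weighted kappa.
#' @return list of class `concordance_table`: `table` (cross-tabulation with
#'   model A rows permuted to the optimal assignment), `kappa`,
#'   `kappa_unweighted`, `weighting`, `assignment`.
#' @export
model_concordance <- function(model_a, model_b,
                              weighting = c("quadratic", "linear", "unweighted")) {
  weighting <- match.arg(weighting)
  ids_a <- names(model_a$assignment)
  ids_b <- names(model_b$assignment)
  if (!setequal(ids_a, ids_b)) {
    stop("models fitted to different subjects (",
         length(setdiff(ids_a, ids_b)) + length(setdiff(ids_b, ids_a)),
         " not shared)", call. = FALSE)
  }
  Ka <- model_a$structure$n_classes
  Kb <- model_b$structure$n_classes
  if (Ka != Kb) stop("models have different class counts", call. = FALSE)
  b <- model_b$assignment[ids_a]
  tab <- table(factor(model_a$assignment, levels = seq_len(Ka)),
               factor(b, levels = seq_len(Kb)))
  wk <- weighted_kappa(tab, weighting, optimize_assignment = TRUE)
  uw <- weighted_kappa(tab, "unweighted", optimize_assignment = TRUE)
  structure(list(table = wk$table, kappa = wk$kappa,
                 kappa_unweighted = uw$kappa, weighting = weighting,
                 assignment = wk$assignment),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Concordance: kappa (%s) = %.3f, unweighted = %.3f\n",
              x$weighting, x$kappa, x$kappa_unweighted))
  print(x$table)
  invisible(x)
}
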