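#' Average posterior probability of assignment (APPA)
#'
#' For each class k, the mean of the class-k posterior probability over the
#' subjects assigned to k. Values above 0.70 in every class are conventionally
#' regarded as adequate. A class with no assigned members has no APPA: it is
#' reported as `NA` (with a warning), which deliberately distinguishes class
#' collapse from poor separation.
#'
#' @param posterior N x K posterior matrix (rows sum to 1).
#' @param assignment modal class per subject; defaults to the row-wise
#'   arg-max with ties broken to the lowest class index.
#' @return numeric length K; `NA` for empty classes.
#' @export
appa <- function(posterior, assignment = max.col(posterior, ties.method = "first")) {
  K <- ncol(posterior)
  out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    members <- assignment == k
    if (any(members)) out[k] <- mean(posterior[members, k])
  }
  if (anyNA(out)) {
    warning("empty class(es): ", paste(which(is.na(out)), collapse = ", "),
            "; APPA reported as missing", call. = FALSE)
  }
  out
}

#' Odds of correct classification (OCC)
#'
#' Ratio of the posterior classification odds to the chance odds implied by
#' the mixing proportion:
#' `OCC_k = [APPA_k / (1 - APPA_k)] / [pi_k / (1 - pi_k)]`.
#' Values above 5.0 indicate adequate assignment. Perfect assignment
#' (`APPA_k = 1`) yields `Inf`.
#'
#' @param appa_k per-class APPA value(s) in (0, 1].
#' @param pi_k per-class mixing proportion(s), strictly inside (0, 1).
#' @return OCC value(s); `Inf` where `appa_k == 1`, `NA` where `appa_k` is
#'   missing.
#' @export
occ <- function(appa_k, pi_k) {
  if (any(pi_k <= 0 | pi_k >= 1)) {
    stop("OCC undefined for mixing proportions of 0 or 1", call. = FALSE)
  }
  ifelse(is.na(appa_k), NA_real_,
         ifelse(appa_k >= 1, Inf,
                (appa_k / (1 - appa_k)) / (pi_k / (1 - pi_k))))
}

#' Mismatch between estimated proportions and assignment shares
#'
#' `delta_k = pi_hat_k - N_k / N`, the difference between each class's
#' estimated mixing proportion and its modal-assignment share. The components
#' sum to zero exactly.
#'
#' @param pi_hat estimated mixing proportions (sum to 1).
#' @param assignment modal class per subject (integers in 1..K).
#' @return numeric length K summing to 0.
#' @export
mismatch <- function(pi_hat, assignment) {
  K <- length(pi_hat)
  shares <- tabulate(assignment, nbins = K) / length(assignment)
  pi_hat - shares
}

#' Relative entropy of a posterior classification
#'
#' `E_K = 1 - sum_i sum_k (-p_ik log p_ik) / (N log K)`, with `0 log 0 = 0`.
#' Equals 1 when every posterior row is one-hot (perfect separation) and 0
#' when every row is uniform (no information); values above 0.5 are the
#' conventional adequacy threshold. Any logarithm base gives the same value;
#' natural log is used with `log K` normalisation.
#'
#' @param posterior N x K posterior matrix, K >= 2.
#' @return scalar in [0, 1].
#' @export
relative_entropy <- function(posterior) {
  K <- ncol(posterior)
  if (K < 2L) stop("relative entropy undefined for K = 1", call. = FALSE)
  p <- pmax(pmin(posterior, 1), 0)
  h <- -p * log(p)
  h[p == 0] <- 0
  e <- 1 - sum(h) / (nrow(posterior) * log(K))
  min(max(e, 0), 1)
}

#' Model adequacy report
#'
#' Assembles the posterior-classification diagnostics of a fitted model:
#' per-class APPA and OCC, the mismatch between estimated proportions and
#' assignment shares, the relative entropy, and booleans for the conventional
#' thresholds (APPA > 0.70 in every class, OCC > 5.0 in every class,
#' relative entropy > 0.5). Empty classes are flagged explicitly.
#'
#' @param fit a converged `lctm_fit`.
#' @return list of class `adequacy_report` with elements `appa`, `occ`,
#'   `mismatch`, `relative_entropy`, `empty_classes` and `thresholds_met`
#'   (named logical vector `appa`, `occ`, `entropy`).
#' @export
adequacy_report <- function(fit) {
  stopifnot(inherits(fit, "lctm_fit"))
  if (!fit$converged) {
    stop("adequacy report requires a converged model", call. = FALSE)
  }
  K <- fit$structure$n_classes
  a <- suppressWarnings(appa(fit$posterior, fit$assignment))
  o <- if (K > 1L) occ(a, fit$pi) else rep(NA_real_, K)
  mm <- mismatch(fit$pi, fit$assignment)
  ent <- if (K > 1L) relative_entropy(fit$posterior) else NA_real_
  empty <- which(is.na(a))
  thr <- c(appa = !anyNA(a) && all(a > 0.70),
           occ = K > 1L && !anyNA(o) && all(o > 5.0),
           entropy = K > 1L && !is.na(ent) && ent > 0.5)
  structure(list(appa = a, occ = o, mismatch = mm, relative_entropy = ent,
                 empty_classes = empty, thresholds_met = thr),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  K <- length(x$appa)
  tab <- data.frame(class = seq_len(K),
                    APPA = round(x$appa, 3),
                    OCC = round(x$occ, 2),
                    mismatch = round(x$mismatch, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("relative entropy E_K = %s\n",
              ifelse(is.na(x$relative_entropy), "NA",
                     sprintf("%.3f", x$relative_entropy))))
  if (length(x$empty_classes))
    cat("empty class(es):", paste(x$empty_classes, collapse = ", "), "\n")
  cat("thresholds met: APPA>0.70:", x$thresholds_met["appa"],
      "| OCC>5.0:", x$thresholds_met["occ"],
      "| E_K>0.5:", x$thresholds_met["entropy"], "\n")
  invisible(x)
}

#' Write a posterior matrix as CSV
#'
#' Columns `id, class_1..class_K, assigned`.
#'
#' @param fit an `lctm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  df <- data.frame(id = rownames(fit$posterior), fit$posterior,
                   assigned = fit$assignment, check.names = FALSE,
                   row.names = NULL)
  names(df) <- c("id", paste0("class_", seq_len(ncol(fit$posterior))),
                 "assigned")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
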