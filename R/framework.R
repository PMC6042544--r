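#' Framework configuration for the eight-step workflow
#'
#' Bundles the tunables of the model-construction workflow: the provisional
#' class count for the scoping step, the class-count range for enumeration,
#' the structure ladder, the EM settings, the plotting grid and the
#' sensitivity thresholds.
#'
#' @param scoping_k provisional number of classes for the scoping model
#'   (step 1).
#' @param k_range class counts swept in step 2 (default 1:7).
#' @param structures structure codes swept in step 3 (default A-G).
#' @param fit a [fit_config] used for every fit.
#' @param grid evaluation/plotting times; `NULL` = derived from the data
#'   (distinct observation times when few, else 4 equally spaced times).
#' @param spaghetti_sample number of subjects sampled for spaghetti plot data.
#' @param sensitivity_min_obs minimum observation counts for the step-8
#'   refits (default `c(2, 3)`).
#' @param category_cuts outcome cut-points defining the conventional
#'   categories used in the step-7 concordance (default the adult BMI bands
#'   18.5 / 25 / 30 / 35 kg/m2); fully configurable.
#' @return list of class `framework_config`.
#' @export
framework_config <- function(scoping_k = 5, k_range = 1:7,
                             structures = LETTERS[1:7],
                             fit = fit_config(), grid = NULL,
                             spaghetti_sample = 50,
                             sensitivity_min_obs = c(2, 3),
                             category_cuts = c(18.5, 25, 30, 35)) {
  stopifnot(length(k_range) >= 1, scoping_k >= 1, scoping_k <= 10,
            all(structures %in% LETTERS[1:7]))
  structure(list(scoping_k = as.integer(scoping_k),
                 k_range = as.integer(k_range),
                 structures = structures, fit = fit, grid = grid,
                 spaghetti_sample = as.integer(spaghetti_sample),
                 sensitivity_min_obs = as.integer(sensitivity_min_obs),
                 category_cuts = category_cuts),
            class = "framework_config")
}

default_grid <- function(data, max_exact_times = 12) {
  times <- sort(unique(data$time))
  if (length(times) <= max_exact_times) times
  else seq(min(times), max(times), length.out = 4)
}

#' Step 1: scoping — suggest the random-effect order
#'
#' Fits a fixed-effects-only model (structure A) at a provisional class count
#' and examines the per-subject residual profiles around the class mean
#' curves. Each subject's residuals are fitted by a polynomial in transformed
#' time; under a pure fixed-effects truth the across-subject variance of the
#' order-c coefficient is the one implied by within-subject noise alone
#' (`sigma2 * diag((X_i'X_i)^{-1})`). The within-subject noise variance is
#' estimated from the per-subject residual mean square beyond the subject
#' polynomial — which is free of any smooth subject-level random effect — so
#' a variance-inflation ratio above `threshold` at order 0, 1 or 2 signals a
#' random intercept, slope or quadratic term respectively. The suggestion is
#' the highest inflated order in any class; flat profiles (no inflation
#' anywhere) suggest no random effects. The numeric rule makes the usual
#' by-eye judgement of residual-profile shape reproducible and overridable.
#'
#' @param data a [trajectory_data]; subjects need more observations than the
#'   polynomial order + 1 to contribute to the noise estimate.
#' @param scoping_k provisional class count.
#' @param config a [fit_config].
#' @param threshold variance-inflation ratio above which an order counts as
#'   present (default 1.5).
#' @return list of class `scoping_report`: `suggestion` (0, 1, 2 or `NA` for
#'   "none/flat"), `label`, `inflation` (max-over-classes ratio per order),
#'   `by_class` (matrix of ratios), `sigma2_noise`, and the scoping `fit`.
#' @export
step1_scoping <- function(data, scoping_k = 5, config = fit_config(),
                          threshold = 1.5) {
  st <- model_structure("A", scoping_k)
  fit <- tryCatch(fit_lctm(data, st, config), error = function(e) {
    stop("scoping model failed (", conditionMessage(e),
         "); consider fewer classes", call. = FALSE)
  })
  if (!fit$converged) {
    stop("scoping model did not converge; consider fewer classes",
         call. = FALSE)
  }
  tt <- transform_time(data$time, st)
  X <- poly_design(tt, st$fixed_degree)
  sidx <- match(data$id, rownames(fit$posterior))
  resid <- data$y - rowSums(X * t(fit$beta[, fit$assignment[sidx],
                                           drop = FALSE]))

  p <- st$fixed_degree + 1L
  by_subj <- split(seq_len(nrow(data)), sidx)
  usable <- which(lengths(by_subj) >= p)
  if (!length(usable)) {
    stop("no subject has enough observations to profile residuals",
         call. = FALSE)
  }
  coefs <- noise_var <- matrix(NA_real_, length(usable), p)
  noise_ss <- noise_df <- 0
  for (j in seq_along(usable)) {
    ix <- by_subj[[usable[j]]]
    Xi <- X[ix, , drop = FALSE]
    XtXi <- tryCatch(solve(crossprod(Xi)), error = function(e) NULL)
    if (is.null(XtXi)) next
    ci <- XtXi %*% crossprod(Xi, resid[ix])
    coefs[j, ] <- ci
    noise_var[j, ] <- diag(XtXi)
    if (length(ix) > p) {
      noise_ss <- noise_ss + sum((resid[ix] - Xi %*% ci)^2)
      noise_df <- noise_df + length(ix) - p
    }
  }
  # within-subject noise, free of smooth subject effects; falls back to the
  # scoping model's residual variance when no subject has spare df
  sigma2_noise <- if (noise_df > 0) noise_ss / noise_df else fit$sigma2
  keep <- stats::complete.cases(coefs)
  coefs <- coefs[keep, , drop = FALSE]
  noise_var <- noise_var[keep, , drop = FALSE]
  cls <- fit$assignment[usable[keep]]

  by_class <- matrix(NA_real_, scoping_k, p,
                     dimnames = list(paste0("class_", seq_len(scoping_k)),
                                     paste0("order_", 0:(p - 1L))))
  for (k in seq_len(scoping_k)) {
    ix <- cls == k
    if (sum(ix) >= 5L) {
      by_class[k, ] <- apply(coefs[ix, , drop = FALSE], 2L, stats::var) /
        (sigma2_noise * colMeans(noise_var[ix, , drop = FALSE]))
    }
  }
  infl <- apply(by_class, 2L, max, na.rm = TRUE)
  present <- which(infl > threshold) - 1L
  suggestion <- if (length(present)) max(present) else NA_integer_
  structure(list(
    suggestion = suggestion,
    label = if (is.na(suggestion)) "none/flat"
            else c("random intercept", "random slope",
                   "random quadratic")[suggestion + 1L],
    inflation = infl, by_class = by_class, threshold = threshold,
    sigma2_noise = sigma2_noise, fit = fit), class = "scoping_report")
}

#' @export
print.scoping_report <- function(x, ...) {
  cat("Scoping suggestion:", x$label,
      sprintf("(variance-inflation ratios: %s; threshold %.2f)\n",
              paste(sprintf("%.2f", x$inflation), collapse = ", "),
              x$threshold))
  invisible(x)
}

sweep_row <- function(fit_or_null, label, grid) {
  if (is.null(fit_or_null) || !fit_or_null$converged) {
    status <- if (is.null(fit_or_null)) "failed" else fit_or_null$status
    return(data.frame(candidate = label, converged = FALSE, status = status,
                      n_params = NA_integer_, loglik = NA_real_,
                      bic = NA_real_, proportions = NA_character_,
                      appa = NA_character_, entropy = NA_real_,
                      dos = NA_real_, stringsAsFactors = FALSE))
  }
  fit <- fit_or_null
  K <- fit$structure$n_classes
  ad <- adequacy_report(fit)
  dos <- if (K >= 2L) degrees_of_separation(fit, grid)$dos else NA_real_
  data.frame(
    candidate = label, converged = TRUE, status = "converged",
    n_params = fit$n_params, loglik = fit$loglik, bic = BIC(fit),
    proportions = paste(sprintf("%.1f", 100 * fit$pi), collapse = ": "),
    appa = paste(ifelse(is.na(ad$appa), "-", sprintf("%.0f", 100 * ad$appa)),
                 collapse = ": "),
    entropy = if (K >= 2L) ad$relative_entropy else NA_real_,
    dos = dos, stringsAsFactors = FALSE)
}

#' Step 2: sweep the number of classes
#'
#' Fits the given structure at each candidate class count and tabulates BIC,
#' class proportions and adequacy statistics, marking the lowest-BIC
#' converged candidate. Failures to converge are carried as explicit rows,
#' never dropped.
#'
#' @param data a [trajectory_data].
#' @param structure a [model_structure] (its class count is overridden by
#'   each candidate K).
#' @param k_range integer vector of class counts.
#' @param config a [fit_config].
#' @param grid evaluation grid for the separation statistic (`NULL` =
#'   data-derived).
#' @return list of class `lctm_sweep`: `table` (one row per K), `fits`
#'   (named list, `NULL` entries for hard failures), `best_k` (lowest BIC
#'   among converged; `NA` if none).
#' @export
sweep_classes <- function(data, structure, k_range = 1:7,
                          config = fit_config(), grid = NULL) {
  if (is.null(grid)) grid <- default_grid(data)
  fits <- list(); rows <- list()
  for (K in k_range) {
    stK <- model_structure(structure$code, K, structure$fixed_degree,
                           structure$time_transform)
    f <- tryCatch(fit_lctm(data, stK, config), error = function(e) NULL)
    fits[[as.character(K)]] <- f
    rows[[as.character(K)]] <- cbind(K = K, sweep_row(f, as.character(K), grid))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  conv <- tab$converged
  best_k <- if (any(conv)) tab$K[conv][which.min(tab$bic[conv])] else NA_integer_
  structure(list(table = tab, fits = fits, best_k = best_k,
                 kind = "classes"), class = "lctm_sweep")
}

#' Step 3: sweep the covariance structures
#'
#' Fits each candidate structure at a fixed class count and tabulates BIC,
#' proportions, APPA, relative entropy and degrees of separation — the
#' structure-comparison table of the workflow. Rows are always reported in
#' ladder order A-G regardless of fitting order.
#'
#' @param data a [trajectory_data].
#' @param n_classes the class count (typically the step-2 selection).
#' @param structures subset of `"A"`..`"G"`.
#' @param config a [fit_config].
#' @param grid evaluation grid for the separation statistic.
#' @param fixed_degree,time_transform passed to [model_structure()].
#' @return list of class `lctm_sweep` with `best_structure` instead of
#'   `best_k`.
#' @export
sweep_structures <- function(data, n_classes, structures = LETTERS[1:7],
                             config = fit_config(), grid = NULL,
                             fixed_degree = 2, time_transform = c(45, 10)) {
  structures <- sort(match.arg(structures, LETTERS[1:7], several.ok = TRUE))
  if (is.null(grid)) grid <- default_grid(data)
  fits <- list(); rows <- list()
  for (code in structures) {
    st <- model_structure(code, n_classes, fixed_degree, time_transform)
    f <- tryCatch(fit_lctm(data, st, config), error = function(e) NULL)
    fits[[code]] <- f
    rows[[code]] <- cbind(structure = code, sweep_row(f, code, grid))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  conv <- tab$converged
  best <- if (any(conv)) tab$structure[conv][which.min(tab$bic[conv])]
          else NA_character_
  structure(list(table = tab, fits = fits, best_structure = best,
                 kind = "structures"), class = "lctm_sweep")
}

#' @export
print.lctm_sweep <- function(x, ...) {
  cat("Model sweep (", x$kind, ")\n", sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 1)
  tab$bic <- round(tab$bic, 1)
  tab$entropy <- round(tab$entropy, 2)
  tab$dos <- round(tab$dos, 3)
  print(tab, row.names = FALSE)
  if (x$kind == "classes") cat("lowest BIC at K =", x$best_k, "\n")
  else cat("lowest BIC: structure", x$best_structure, "\n")
  invisible(x)
}

#' Step 4: select the favoured model
#'
#' Among the converged candidates of a sweep, selects the lowest-BIC
#' candidate whose adequacy criteria all pass (APPA > 0.70, OCC > 5.0,
#' relative entropy > 0.5). When the lowest-BIC candidate fails adequacy but
#' a higher-BIC one passes, the passing one is selected and the override is
#' recorded — surfacing, not automating away, the analyst's trade-off
#' between fit and adequacy. When no candidate passes, the lowest-BIC
#' candidate is returned flagged `adequacy_violated`.
#'
#' @param sweep an `lctm_sweep`.
#' @return list of class `lctm_selection`: `candidate`, `fit`, `adequacy`,
#'   `adequacy_ok`, `overridden` (TRUE when a lower-BIC candidate was passed
#'   over for adequacy), `violations` (criterion names failing for the
#'   selected candidate).
#' @export
select_favoured <- function(sweep) {
  stopifnot(inherits(sweep, "lctm_sweep"))
  tab <- sweep$table
  conv <- which(tab$converged)
  if (!length(conv)) stop("no converged candidates to select from", call. = FALSE)
  ord <- conv[order(tab$bic[conv])]
  labels <- tab$candidate
  reports <- lapply(ord, function(i) adequacy_report(sweep$fits[[labels[i]]]))
  pass <- vapply(reports, function(r) all(r$thresholds_met), logical(1))
  pick <- if (any(pass)) which(pass)[1L] else 1L
  i <- ord[pick]
  rep_i <- reports[[pick]]
  structure(list(
    candidate = labels[i],
    fit = sweep$fits[[labels[i]]],
    adequacy = rep_i,
    adequacy_ok = all(rep_i$thresholds_met),
    overridden = any(pass) && pick > 1L,
    violations = names(rep_i$thresholds_met)[!rep_i$thresholds_met]
  ), class = "lctm_selection")
}

#' @export
print.lctm_selection <- function(x, ...) {
  cat("Selected candidate:", x$candidate,
      if (x$adequacy_ok) "(adequacy criteria met)"
      else paste0("(adequacy violated: ", paste(x$violations, collapse = ", "),
                  ")"),
      if (x$overridden) "[lower-BIC candidate passed over for adequacy]", "\n")
  invisible(x)
}

#' Step 5: plot-ready tabular exports
#'
#' Emits the three graphical summaries as plain tables: (1) class mean
#' trajectories on the grid; (2) mean trajectories with 95% predictive bands,
#' `mean +/- 1.96 * sqrt(marginal variance)` where the marginal variance at
#' time t is `z' B_k z + sigma_k^2` (constant for fixed-effects structures);
#' (3) a seeded random sample of subjects with their observed points and
#' modal class, for spaghetti plots.
#'
#' @param fit a converged `lctm_fit`.
#' @param data the fitted [trajectory_data].
#' @param grid evaluation times (`NULL` = data-derived).
#' @param spaghetti_sample number of subjects to sample.
#' @param seed sampling seed (same seed, same sample).
#' @return list of class `lctm_plot_data`: data.frames `means`
#'   (time, class, mean), `bands` (time, class, mean, lower, upper) and
#'   `spaghetti` (id, time, y, class).
#' @export
plot_data <- function(fit, data, grid = NULL, spaghetti_sample = 50,
                      seed = 1) {
  stopifnot(inherits(fit, "lctm_fit"))
  if (is.null(grid)) grid <- default_grid(data)
  st <- fit$structure
  K <- st$n_classes
  params <- fit_params(fit)
  M <- class_means(fit, grid)
  q <- n_random(st)
  Xg <- poly_design(transform_time(grid, st), st$fixed_degree)
  bands <- do.call(rbind, lapply(seq_len(K), function(k) {
    v <- rep(class_sigma2(params, k), length(grid))
    if (q > 0L) {
      Zg <- Xg[, seq_len(q), drop = FALSE]
      Bk <- class_cov(params, k)
      v <- v + rowSums((Zg %*% Bk) * Zg)
    }
    half <- 1.96 * sqrt(v)
    data.frame(time = grid, class = k, mean = M[, k],
               lower = M[, k] - half, upper = M[, k] + half)
  }))
  means <- do.call(rbind, lapply(seq_len(K), function(k)
    data.frame(time = grid, class = k, mean = M[, k])))

  ids <- rownames(fit$posterior)
  set.seed(seed)
  pick <- sort(sample.int(length(ids), min(spaghetti_sample, length(ids))))
  sel <- data$id %in% ids[pick]
  spaghetti <- data.frame(id = data$id[sel], time = data$time[sel],
                          y = data$y[sel],
                          class = fit$assignment[data$id[sel]],
                          row.names = NULL)
  structure(list(means = means, bands = bands, spaghetti = spaghetti),
            class = "lctm_plot_data")
}

#' Categorise subjects by an outcome cut-point scheme
#'
#' Assigns each subject an ordinal category from the outcome observed at a
#' reference time — by default each subject's last observation (e.g. the
#' baseline determination in a recall design). Default cut-points are the
#' conventional adult BMI bands (<18.5, 18.5-24.9, 25-29.9, 30-34.9, >=35).
#'
#' @param data a [trajectory_data].
#' @param cuts increasing interior cut-points.
#' @param at `"last"` (default) or `"first"` observation per subject, or a
#'   numeric time whose nearest observation is used.
#' @return named integer vector (1 = lowest band), one entry per subject.
#' @export
outcome_categories <- function(data, cuts = c(18.5, 25, 30, 35),
                               at = "last") {
  stopifnot(all(diff(cuts) > 0))
  by_subj <- split(seq_len(nrow(data)), match(data$id, subjects(data)))
  val <- vapply(by_subj, function(ix) {
    if (identical(at, "last")) data$y[ix[which.max(data$time[ix])]]
    else if (identical(at, "first")) data$y[ix[which.min(data$time[ix])]]
    else data$y[ix[which.min(abs(data$time[ix] - at))]]
  }, numeric(1))
  out <- findInterval(val, cuts) + 1L
  names(out) <- subjects(data)
  out
}

#' Step 7: concordance with conventional categories
#'
#' Cross-tabulates the modal latent-class assignment against a conventional
#' per-subject categorisation and computes the optimal-assignment weighted
#' kappa (latent classes carry no labels, so all row permutations are
#' searched). Quantifies how much the trajectory classes differ from a
#' one-off categorisation.
#'
#' @param fit an `lctm_fit`.
#' @param categories named integer vector of ordinal categories covering
#'   every fitted subject (see [outcome_categories()]).
#' @param weighting kappa weighting scheme.
#' @return list of class `concordance_table` (as [model_concordance()]).
#' @export
concordance_vs_categories <- function(fit, categories,
                                      weighting = c("quadratic", "linear",
                                                    "unweighted")) {
  weighting <- match.arg(weighting)
  ids <- names(fit$assignment)
  if (is.null(names(categories)) || !all(ids %in% names(categories))) {
    stop("categories must be named and cover every fitted subject",
         call. = FALSE)
  }
  cat_v <- categories[ids]
  if (anyNA(cat_v)) stop("missing categories for some subjects", call. = FALSE)
  K <- fit$structure$n_classes
  C <- max(K, max(cat_v))
  tab <- table(factor(fit$assignment, levels = seq_len(C)),
               factor(cat_v, levels = seq_len(C)))
  wk <- weighted_kappa(tab, weighting, optimize_assignment = TRUE)
  uw <- weighted_kappa(tab, "unweighted", optimize_assignment = TRUE)
  structure(list(table = wk$table, kappa = wk$kappa,
                 kappa_unweighted = uw$kappa, weighting = weighting,
                 assignment = wk$assignment),
            class = "concordance_table")
}

#' Step 8: sensitivity refits on observation-count subsets
#'
#' Refits the favoured structure on the subjects contributing at least `m`
#' observations, for each `m` in `min_obs`, and compares each refit with the
#' main fit: class proportions, the maximum absolute deviation between
#' aligned class mean trajectories on the grid, and optimal-assignment kappa
#' on the shared subjects. Classes are aligned by the kappa-optimal
#' permutation.
#'
#' @param data a [trajectory_data].
#' @param structure the favoured [model_structure].
#' @param config a [fit_config].
#' @param min_obs integer vector of minimum observation counts.
#' @param grid comparison grid (`NULL` = data-derived).
#' @param main_fit optionally, the already-fitted main model.
#' @return list of class `sensitivity_report`: `table` (per m: n_subjects,
#'   converged, kappa, max_mean_deviation, proportions) and `fits`.
#' @export
sensitivity_refit <- function(data, structure, config = fit_config(),
                              min_obs = c(2, 3), grid = NULL,
                              main_fit = NULL) {
  min_obs <- as.integer(min_obs)
  if (is.null(grid)) grid <- default_grid(data)
  if (is.null(main_fit)) main_fit <- fit_lctm(data, structure, config)
  K <- structure$n_classes
  n_obs <- table(data$id)[subjects(data)]
  rows <- list(); fits <- list()
  for (m in min_obs) {
    keep_ids <- names(n_obs)[n_obs >= m]
    key <- as.character(m)
    if (length(keep_ids) < 2L * K) {
      rows[[key]] <- data.frame(min_obs = m, n_subjects = length(keep_ids),
                                converged = FALSE, kappa = NA_real_,
                                max_mean_deviation = NA_real_,
                                proportions = NA_character_)
      next
    }
    sub <- trajectory_data(as.data.frame(data)[data$id %in% keep_ids, ])
    f <- tryCatch(fit_lctm(sub, structure, config), error = function(e) NULL)
    fits[[key]] <- f
    if (is.null(f) || !f$converged) {
      rows[[key]] <- data.frame(min_obs = m, n_subjects = length(keep_ids),
                                converged = FALSE, kappa = NA_real_,
                                max_mean_deviation = NA_real_,
                                proportions = NA_character_)
      next
    }
    shared <- intersect(names(main_fit$assignment), names(f$assignment))
    tab <- table(factor(f$assignment[shared], levels = seq_len(K)),
                 factor(main_fit$assignment[shared], levels = seq_len(K)))
    wk <- weighted_kappa(tab, "unweighted", optimize_assignment = TRUE)
    perm <- wk$assignment   # perm[refit class] = matching main-fit class
    M_main <- class_means(main_fit, grid)
    M_sub <- class_means(f, grid)
    dev <- max(abs(M_sub - M_main[, perm, drop = FALSE]))
    rows[[key]] <- data.frame(min_obs = m, n_subjects = length(keep_ids),
                              converged = TRUE, kappa = wk$kappa,
                              max_mean_deviation = dev,
                              proportions = paste(
                                sprintf("%.1f", 100 * f$pi[order(perm)]),
                                collapse = ": "))
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 main_fit = main_fit, grid = grid),
            class = "sensitivity_report")
}

#' Run the eight-step workflow end to end
#'
#' Orchestrates: (1) scoping, (2) class-count sweep, (3) structure sweep at
#' the selected K, (4) adequacy-based selection, (5) plot-data exports,
#' (6) discrimination statistics, (7) concordance with a conventional
#' categorisation, (8) sensitivity refits — and writes every report as a
#' machine-readable CSV/JSON file in `outdir`. Identical data, configuration
#' and seed produce byte-identical outputs.
#'
#' @param data a [trajectory_data].
#' @param config a [framework_config].
#' @param outdir output directory (created if needed); `NULL` writes nothing.
#' @return list of class `lctm_run` holding every step's object.
#' @export
run_lctm <- function(data, config = framework_config(), outdir = NULL) {
  grid <- if (is.null(config$grid)) default_grid(data) else config$grid
  scoping <- step1_scoping(data, config$scoping_k, config$fit)
  rd <- if (is.na(scoping$suggestion)) -1L else scoping$suggestion
  scoping_code <- c("A", "C", "D", "F")[rd + 2L]  # none->A, 0->C, 1->D, 2->F
  st0 <- model_structure(scoping_code, config$scoping_k)

  classes <- sweep_classes(data, st0, config$k_range, config$fit, grid)
  K <- if (is.na(classes$best_k)) config$scoping_k else classes$best_k
  structures <- sweep_structures(data, K, config$structures, config$fit, grid)
  selection <- select_favoured(structures)
  fit <- selection$fit
  adequacy <- selection$adequacy
  discrimination <- if (K >= 2L) degrees_of_separation(fit, grid)
  envelopes <- envelope_residuals(fit, data)
  pd <- plot_data(fit, data, grid, config$spaghetti_sample,
                  seed = config$fit$seed)
  categories <- outcome_categories(data, config$category_cuts)
  concordance <- concordance_vs_categories(fit, categories)
  sensitivity <- sensitivity_refit(data, fit$structure, config$fit,
                                   config$sensitivity_min_obs, grid,
                                   main_fit = fit)

  out <- structure(list(scoping = scoping, classes = classes,
                        structures = structures, selection = selection,
                        fit = fit, adequacy = adequacy,
                        discrimination = discrimination,
                        envelopes = envelopes, plot_data = pd,
                        concordance = concordance,
                        sensitivity = sensitivity, grid = grid),
                   class = "lctm_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(outdir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  wc <- function(x, f) utils::write.csv(x, file.path(outdir, f),
                                        row.names = FALSE, quote = FALSE)
  wj(list(suggestion = run$scoping$label,
          inflation = run$scoping$inflation), "scoping.json")
  wc(run$classes$table, "class_sweep.csv")
  wc(run$structures$table, "structure_sweep.csv")
  wj(list(candidate = run$selection$candidate,
          adequacy_ok = run$selection$adequacy_ok,
          violations = run$selection$violations,
          appa = run$adequacy$appa, occ = run$adequacy$occ,
          mismatch = run$adequacy$mismatch,
          relative_entropy = run$adequacy$relative_entropy), "adequacy.json")
  if (!is.null(run$discrimination))
    wj(list(dos = run$discrimination$dos,
            pairwise = run$discrimination$pairwise), "discrimination.json")
  wc(run$envelopes$table, "envelopes.csv")
  wc(run$plot_data$means, "trajectory_means.csv")
  wc(run$plot_data$bands, "trajectory_bands.csv")
  wc(run$plot_data$spaghetti, "spaghetti_sample.csv")
  wj(list(kappa = run$concordance$kappa,
          kappa_unweighted = run$concordance$kappa_unweighted,
          table = as.data.frame.matrix(run$concordance$table)),
     "category_concordance.json")
  wc(run$sensitivity$table, "sensitivity.csv")
  write_posterior(run$fit, file.path(outdir, "posterior.csv"))
  wj(list(structure = run$fit$structure$code,
          n_classes = run$fit$structure$n_classes,
          seed = run$fit$seed, loglik = run$fit$loglik,
          bic = BIC(run$fit), converged = run$fit$converged,
          starts = run$fit$starts), "fit_log.json")
  invisible(outdir)
}
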