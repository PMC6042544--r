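test_that("scoping suggests the generating random-effect order", {
  base <- function(code, B) simulate_trajectories(
    simulation_config(500, model_structure(code, 2), sep_beta2(),
                      pi = c(0.6, 0.4), sigma2 = 1, B = B, seed = 7))
  cfg <- fit_config(n_starts = 2, seed = 3)

  # pure fixed effects: flat profiles, no random term suggested
  s_a <- step1_scoping(base("A", NULL)$data, scoping_k = 2, cfg)
  expect_true(is.na(s_a$suggestion))
  expect_identical(s_a$label, "none/flat")

  # random intercepts only
  s_c <- step1_scoping(base("C", diag(0.6, 1))$data, scoping_k = 2, cfg)
  expect_identical(s_c$suggestion, 0L)

  # random quadratic effects
  s_e <- step1_scoping(base("E", diag(c(0.6, 0.25, 0.1)))$data,
                       scoping_k = 2, cfg)
  expect_identical(s_e$suggestion, 2L)
})

test_that("class sweeps anchor at K = 1 and report failures explicitly", {
  sim <- simulate_trajectories(three_class_F_config(250, seed = 42))
  sw <- sweep_classes(sim$data, model_structure("F", 1), k_range = 1:3,
                      config = fit_config(n_starts = 2, seed = 1))
  expect_identical(sw$table$K, 1:3)
  expect_true(sw$table$converged[1])              # K = 1 always converges
  expect_true(all(c("status", "bic", "proportions") %in% names(sw$table)))
  # a hard failure becomes an explicit row, never a dropped one
  row <- trajmix:::sweep_row(NULL, "9", c(18, 35))
  expect_false(row$converged)
  expect_identical(row$status, "failed")
})

test_that("structure sweeps order rows A-G and favour the generating model", {
  sim <- simulate_trajectories(sep_config("F", n_subjects = 300, seed = 2))
  sw <- sweep_structures(sim$data, 2, structures = c("F", "A"),
                         config = fit_config(n_starts = 2, seed = 1))
  expect_identical(sw$table$structure, c("A", "F"))  # presentation order
  expect_true(all(sw$table$converged))
  # data generated under F: its BIC beats the fixed-effects model's
  expect_lt(sw$table$bic[sw$table$structure == "F"],
            sw$table$bic[sw$table$structure == "A"])
  expect_identical(sw$best_structure, "F")
})

test_that("favoured-model selection balances BIC against adequacy", {
  sim <- simulate_trajectories(sep_config("A", n_subjects = 200, seed = 33))
  sw <- sweep_classes(sim$data, model_structure("A", 1), k_range = 1:2,
                      config = fit_config(n_starts = 2, seed = 1))
  sel <- select_favoured(sw)
  expect_s3_class(sel, "lctm_selection")
  expect_true(sel$fit$converged)
  expect_identical(sel$candidate, as.character(sw$best_k))

  # when every candidate fails adequacy the lowest-BIC one returns, flagged
  sw_bad <- sw
  for (k in names(sw_bad$fits)) {
    if (!is.null(sw_bad$fits[[k]]) && sw_bad$fits[[k]]$converged) {
      n <- sw_bad$fits[[k]]$n_subjects
      K <- sw_bad$fits[[k]]$structure$n_classes
      sw_bad$fits[[k]]$posterior <- matrix(1 / K, n, K,
        dimnames = list(rownames(sw_bad$fits[[k]]$posterior), NULL))
      sw_bad$fits[[k]]$assignment <- setNames(rep(1L, n),
        rownames(sw_bad$fits[[k]]$posterior))
    }
  }
  sel_bad <- suppressWarnings(select_favoured(sw_bad))
  expect_false(sel_bad$adequacy_ok)
  expect_true(length(sel_bad$violations) > 0)
})

test_that("plot data reflects the marginal variance structure", {
  grid <- c(18, 35, 50, 62.5)
  sim <- simulate_trajectories(sep_config("A", n_subjects = 150, seed = 3))
  fitA <- quick_fit(sim, model_structure("A", 2), seed = 1)
  pd <- plot_data(fitA, sim$data, grid, spaghetti_sample = 10, seed = 5)
  # homoscedastic model: bands have constant width 2 * 1.96 * sigma
  w <- pd$bands$upper - pd$bands$lower
  expect_equal(w, rep(2 * 1.96 * sqrt(fitA$sigma2), length(w)),
               tolerance = 1e-10)

  # random-quadratic model: width grows with |transformed time|
  simF <- simulate_trajectories(sep_config("F", n_subjects = 150, seed = 4))
  fitF <- quick_fit(simF, model_structure("F", 2), seed = 1)
  pdF <- plot_data(fitF, simF$data, grid, spaghetti_sample = 10, seed = 5)
  b1 <- pdF$bands[pdF$bands$class == 1, ]
  wd <- b1$upper - b1$lower
  expect_gt(wd[1], wd[3])   # |t'| = 2.7 at age 18 vs 0.5 at age 50

  # seeded spaghetti sample reproduces exactly
  pd2 <- plot_data(fitA, sim$data, grid, spaghetti_sample = 10, seed = 5)
  expect_identical(pd$spaghetti, pd2$spaghetti)
  expect_lte(length(unique(pd$spaghetti$id)), 10L)
})

test_that("category concordance is perfect when classes mirror categories", {
  set.seed(21)
  n <- 120
  cls <- sample(1:3, n, replace = TRUE)
  level <- c(20, 27, 33)[cls]
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = sprintf("s%03d", i), time = c(18, 50),
               y = level[i])))
  td <- trajectory_data(df)
  cats <- outcome_categories(td, cuts = c(25, 30))
  post <- diag(3)[cls, ]
  f <- fake_fit(model_structure("A", 3), prop.table(tabulate(cls, 3)),
                matrix(0, 3, 3), posterior = post)
  rownames(f$posterior) <- sprintf("s%03d", 1:n)
  f$assignment <- setNames(cls, sprintf("s%03d", 1:n))
  cc <- concordance_vs_categories(f, cats)
  expect_equal(cc$kappa, 1)
  expect_error(concordance_vs_categories(f, cats[-1]), "cover")
})

test_that("sensitivity refits reproduce the main model on complete data", {
  sim <- simulate_trajectories(sep_config("A", n_subjects = 150, seed = 10))
  st <- model_structure("A", 2)
  cfg <- fit_config(n_starts = 2, seed = 6)
  main <- fit_lctm(sim$data, st, cfg)
  # balanced data: the >= 4 subset IS the full data, so the refit matches
  sr <- sensitivity_refit(sim$data, st, cfg, min_obs = c(2, 4),
                          main_fit = main)
  expect_identical(sr$table$min_obs, c(2L, 4L))
  expect_true(all(sr$table$converged))
  expect_equal(sr$table$kappa, c(1, 1))
  expect_lt(max(sr$table$max_mean_deviation), 1e-6)

  # random thinning: trajectories deviate little relative to the noise SD
  sim_t <- simulate_trajectories(sep_config("A", n_subjects = 400, seed = 11))
  cfg_t <- sep_config("A", n_subjects = 400, seed = 11)
  cfg_t$retention <- 0.7
  sim_thin <- simulate_trajectories(cfg_t)
  main_t <- fit_lctm(sim_thin$data, st, cfg)
  sr_t <- sensitivity_refit(sim_thin$data, st, cfg, min_obs = 3,
                            main_fit = main_t)
  expect_true(sr_t$table$converged)
  expect_lt(sr_t$table$max_mean_deviation, 0.5)   # residual SD is 1
  expect_gt(sr_t$table$kappa, 0.9)
})

test_that("the eight-step pipeline runs end to end, deterministically", {
  sim <- simulate_trajectories(sep_config("C", n_subjects = 150, seed = 9))
  fw <- framework_config(scoping_k = 2, k_range = 1:2,
                         structures = c("A", "C"),
                         fit = fit_config(n_starts = 1, seed = 2),
                         spaghetti_sample = 8, sensitivity_min_obs = 4,
                         category_cuts = c(24, 28))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_lctm(sim$data, fw, outdir = out1)
  r2 <- run_lctm(sim$data, fw, outdir = out2)
  files <- c("scoping.json", "class_sweep.csv", "structure_sweep.csv",
             "adequacy.json", "discrimination.json", "envelopes.csv",
             "trajectory_means.csv", "trajectory_bands.csv",
             "spaghetti_sample.csv", "category_concordance.json",
             "sensitivity.csv", "posterior.csv", "fit_log.json")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("determinism of", f))
  }
  expect_true(r1$selection$fit$converged)
  expect_s3_class(r1$concordance, "concordance_table")
})
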