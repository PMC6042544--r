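test_that("APPA averages maximum posteriors within assigned classes", {
  expect_equal(appa(rbind(c(1, 0), c(0, 1))), c(1, 1))
  # hand average for class 1; class 2 empty is missing, never zero
  post <- rbind(c(0.6, 0.4), c(0.8, 0.2))
  expect_warning(a <- appa(post), "empty")
  expect_equal(a, c(0.7, NA_real_))
  # uniform rows tie-break to class 1
  expect_warning(a_u <- appa(matrix(0.5, 3, 2)), "empty")
  expect_equal(a_u, c(0.5, NA_real_))
})

test_that("OCC compares classification odds with chance odds", {
  expect_equal(occ(5 / 6, 0.5), 5)           # the usual adequacy benchmark
  expect_equal(occ(0.3, 0.3), 1)             # no better than chance
  expect_identical(occ(1, 0.5), Inf)         # perfect assignment
  expect_error(occ(0.8, 1), "undefined")
  expect_error(occ(0.8, 0), "undefined")
  # monotone in APPA (fixed pi) and antitone in pi (fixed APPA)
  a <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(occ(a, 0.3)) > 0))
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(occ(0.8, p)) < 0))
})

test_that("mismatch components always cancel", {
  expect_equal(mismatch(c(0.5, 0.5), c(1, 2)), c(0, 0))
  expect_equal(mismatch(c(0.6, 0.4), c(1, 2)), c(0.1, -0.1))
  set.seed(4)
  for (r in 1:20) {
    K <- sample(2:6, 1)
    pi_hat <- prop.table(runif(K))
    assign <- sample.int(K, 50, replace = TRUE)
    expect_lt(abs(sum(mismatch(pi_hat, assign))), 1e-12)
  }
})

test_that("relative entropy spans [0, 1] with the right extremes", {
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(relative_entropy(one_hot), 1)
  expect_equal(relative_entropy(matrix(1 / 4, 6, 4)), 0)
  # frozen hand evaluation: two rows of (0.8, 0.2)
  expect_equal(relative_entropy(rbind(c(0.8, 0.2), c(0.8, 0.2))),
               0.2780719051, tolerance = 1e-9)
  expect_error(relative_entropy(matrix(1, 3, 1)), "K = 1")
  # invariant to relabelling, bounded
  set.seed(11)
  for (r in 1:20) {
    K <- sample(2:5, 1)
    p <- matrix(rgamma(30 * K, 1), 30, K)
    p <- p / rowSums(p)
    e <- relative_entropy(p)
    expect_gte(e, 0); expect_lte(e, 1)
    expect_equal(relative_entropy(p[, sample(K)]), e, tolerance = 1e-12)
  }
})

test_that("adequacy report aggregates statistics and threshold flags", {
  sim <- simulate_trajectories(sep_config("A", n_subjects = 300, seed = 6))
  fit <- quick_fit(sim, model_structure("A", 2), seed = 2)
  rep <- adequacy_report(fit)
  expect_true(all(rep$thresholds_met))      # well-separated classes
  expect_lt(abs(sum(rep$mismatch)), 1e-12)
  expect_true(all(rep$occ > 5))

  # indistinguishable classes: entropy near zero, thresholds fail
  st <- model_structure("A", 2, fixed_degree = 0, time_transform = c(0, 1))
  N <- 40
  post <- matrix(0.5, N, 2)
  f_id <- fake_fit(st, c(0.5, 0.5), matrix(5, 1, 2), posterior = post)
  rep_id <- suppressWarnings(adequacy_report(f_id))
  expect_lt(rep_id$relative_entropy, 0.05)
  expect_false(rep_id$thresholds_met["entropy"])

  # a collapsed (empty) class is flagged, not hidden
  post_c <- cbind(rep(1, N), rep(0, N), rep(0, N))
  post_c[1:5, ] <- rep(c(0, 1, 0), each = 5)
  f_c <- fake_fit(model_structure("A", 3), prop.table(c(2, 1, 0.01)),
                  matrix(0, 3, 3), posterior = post_c)
  rep_c <- suppressWarnings(adequacy_report(f_c))
  expect_identical(rep_c$empty_classes, 3L)
  expect_true(is.na(rep_c$appa[3]))

  # non-converged models are refused
  f_nc <- fake_fit(st, c(0.5, 0.5), matrix(5, 1, 2), posterior = post)
  f_nc$converged <- FALSE
  expect_error(adequacy_report(f_nc), "converged")
})

test_that("posterior matrices export with the documented header", {
  sim <- simulate_trajectories(sep_config("A", n_subjects = 20, seed = 9))
  fit <- quick_fit(sim, model_structure("A", 2), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_posterior(fit, f)
  got <- read.csv(f)
  expect_identical(names(got), c("id", "class_1", "class_2", "assigned"))
  expect_equal(nrow(got), 20L)
  expect_equal(got$assigned, unname(fit$assignment[got$id]))
})
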