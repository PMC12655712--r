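test_that("indicator preparation transforms skewed columns and standardises", {
  set.seed(8)
  d <- tibble::tibble(
    dyad_id = sprintf("x%03d", 1:200),
    mp_24h = rnorm(200, 700, 150),
    total_intake_24h = rnorm(200, 750, 120),
    formula_intake_24h = ifelse(runif(200) < 0.6, 0, rlnorm(200, 5.5, 0.6)),
    waz_current = rnorm(200),
    delta_waz = rnorm(200, -0.5, 0.7)
  )
  prep <- prepare_indicators(d)
  tr <- prep$transform
  expect_true(tr$sqrt[tr$indicator == "formula_intake_24h"])
  expect_false(tr$sqrt[tr$indicator == "mp_24h"])
  expect_true(all(abs(colMeans(prep$x)) < 1e-9))
  expect_true(all(abs(apply(prep$x, 2, sd) - 1) < 1e-9))
  d$mp_24h <- 700
  expect_error(prepare_indicators(d), "zero variance")
})

test_that("the one-class model matches the closed-form Gaussian fit", {
  set.seed(3)
  x <- matrix(rnorm(400), 200, 2)
  x <- scale(x)
  f <- fit_lpa(x, 1, var_floor = 1e-9)
  expect_equal(as.numeric(f$mean), c(0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(f$sigma2), apply(x, 2, function(v) mean(v^2)),
               tolerance = 1e-9)
  # oracle: column-wise Gaussian log-likelihood at the MLE
  ll_oracle <- sum(vapply(1:2, function(j) {
    sum(dnorm(x[, j], 0, sqrt(mean(x[, j]^2)), log = TRUE))
  }, numeric(1)))
  expect_equal(f$loglik, ll_oracle, tolerance = 1e-8)
  expect_equal(f$entropy, 1)
  expect_equal(f$bic, -2 * f$loglik + f$n_par * log(200))
})

test_that("well-separated clusters are recovered with stable likelihood", {
  dat <- two_cluster_data(n = 300, d = 2, delta = 6, seed = 10)
  f <- fit_lpa(dat$x, 2, seed = 1)
  # recovered means match the empirical cluster means (either label order)
  mu <- f$mean[order(f$mean[, 1]), ]
  emp <- rbind(colMeans(dat$x[dat$z == 1, ]), colMeans(dat$x[dat$z == 2, ]))
  expect_lt(max(abs(mu - emp)), 0.05)
  expect_lt(max(abs(mu - rbind(rep(0, 2), rep(6, 2)))), 0.25)
  # near-perfect agreement with the generating labels
  agree <- max(mean(f$assignment == dat$z), mean(f$assignment == 3 - dat$z))
  expect_gt(agree, 0.99)
  f2 <- fit_lpa(dat$x, 2, seed = 1)
  expect_identical(f$loglik, f2$loglik)
  # posterior rows sum to one
  expect_true(all(abs(rowSums(f$posterior) - 1) < 1e-9))
})

test_that("our mixture likelihood matches mclust on the same model", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  dat <- two_cluster_data(n = 250, d = 3, delta = 5, seed = 4)
  f <- fit_lpa(dat$x, 2, variance = "equal", var_floor = 1e-9, seed = 2)
  mc <- mclust::Mclust(dat$x, G = 2, modelNames = "EEI", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
  fv <- fit_lpa(dat$x, 2, variance = "varying", var_floor = 1e-9, seed = 2)
  mcv <- mclust::Mclust(dat$x, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(fv$loglik, mcv$loglik, tolerance = 1e-4)
})

test_that("classification entropy matches its definition", {
  expect_equal(classification_entropy(matrix(c(1, 0, 0, 1), 2, 2)), 1)
  expect_equal(classification_entropy(matrix(0.5, 2, 2)), 0)
  p <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(classification_entropy(p), 0.2655, tolerance = 5e-4)
  expect_equal(classification_entropy(matrix(1, 5, 1)), 1)
})

test_that("class-proportion recovery improves with separation and n", {
  cl <- default_class_spec()
  co <- generate_cohort(cohort_spec(n_dyads = 2000, seed = 13),
                        diaries = FALSE)
  prep <- prepare_indicators(co$ground_truth)
  f <- fit_lpa(prep, 4, seed = 5)
  asg <- assign_profiles(f, prep)
  rec <- as.numeric(table(factor(asg$class, 1:4))) / 2000
  expect_lt(mean(abs(rec - cl$proportion)), 0.03)
})

test_that("bootstrap likelihood ratio test separates real from null splits", {
  # power: a genuine two-cluster structure is detected
  dat <- two_cluster_data(n = 200, d = 2, delta = 6, seed = 6)
  b <- blrt(dat$x, 2, n_boot = 99, seed = 7)
  expect_lte(b$p_value, 0.01)
  # null: one-cluster data gives a non-significant test
  set.seed(8)
  x0 <- scale(matrix(rnorm(300), 150, 2))
  b0 <- blrt(x0, 2, n_boot = 49, seed = 9)
  expect_gt(b0$p_value, 0.05)
  # +1 convention: a zero observed statistic gives p = 1
  m0 <- fit_lpa(x0, 1)
  m1_fake <- fit_lpa(x0, 2, n_restarts = 3, seed = 1)
  m1_fake$loglik <- m0$loglik  # force LRT = 0
  b1 <- blrt(x0, 2, n_boot = 19, seed = 10, model0 = m0, model1 = m1_fake)
  expect_equal(b1$p_value, 1)
})

test_that("model selection applies all five criteria", {
  # single-class data: K = 1 selected (BLRT for K = 2 non-significant)
  set.seed(12)
  x0 <- scale(matrix(rnorm(400), 200, 2))
  sel0 <- select_model(x0, k_range = 1:2, n_boot = 49, seed = 13)
  expect_identical(sel0$selected_k, 1L)
  # an impossible entropy bar selects no model at all
  sel_imp <- select_model(x0, k_range = 1:2, n_boot = 9, seed = 14,
                          criteria = list(entropy = 1.01, avg_posterior = 0.5,
                                          min_share = 0.05, alpha = 0.05))
  expect_true(is.na(sel_imp$selected_k))
  # two genuine clusters: K = 2 selected over K = 1
  dat <- two_cluster_data(n = 240, d = 2, delta = 6, seed = 15)
  sel2 <- select_model(dat$x, k_range = 1:2, n_boot = 49, seed = 16)
  expect_identical(sel2$selected_k, 2L)
  expect_true(all(c("bic", "entropy", "blrt_p", "passes") %in%
                    names(sel2$report)))
})

test_that("canonical labelling maps profiles to stable clinical classes", {
  co <- generate_cohort(cohort_spec(seed = 17))
  m <- derive_dyad_measures(co$diaries, co$cohort)
  prep <- prepare_indicators(m)
  f <- fit_lpa(prep, 4, seed = 18)
  asg <- assign_profiles(f, prep)
  cls <- attr(asg, "classes")
  expect_setequal(cls$label, c("adequate", "oversupply", "severe_lms",
                               "slow_growth"))
  expect_equal(cls$canonical, 1:4)
  # oversupply produces more than the infant takes
  over <- cls[cls$label == "oversupply", ]
  expect_gt(over$mp_24h, over$total_intake_24h)
  # severe class has the lowest production and dominant formula use
  sev <- cls[cls$label == "severe_lms", ]
  expect_equal(sev$mp_24h, min(cls$mp_24h))
  expect_equal(sev$formula_intake_24h, max(cls$formula_intake_24h))
  # grouping: adequate+oversupply = NMS, the rest LMS
  expect_setequal(cls$group[cls$label %in% c("adequate", "oversupply")], "NMS")
  expect_setequal(cls$group[cls$label %in% c("severe_lms", "slow_growth")],
                  "LMS")
  # modal assignment with posterior ties resolved to the lower index
  expect_true(all(asg$posterior >= 1 / 4 - 1e-9))
  expect_equal(nrow(asg), nrow(prep$x))
})

test_that("tidiers and plots expose the fitted structure", {
  dat <- two_cluster_data(n = 120, d = 2, delta = 5, seed = 19)
  f <- fit_lpa(dat$x, 2, seed = 20)
  td <- tidy(f)
  expect_equal(nrow(td), 4)  # 2 classes x 2 indicators
  gl <- glance(f)
  expect_equal(gl$k, 2)
  expect_s3_class(autoplot(f), "ggplot")
})
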