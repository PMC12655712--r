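test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_spec(n_dyads = 60, seed = 5))
  b <- generate_cohort(cohort_spec(n_dyads = 60, seed = 5))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$diaries, b$diaries)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_cohort(cohort_spec(n_dyads = 60, seed = 6))
  expect_false(identical(a$ground_truth$mp_24h, c$ground_truth$mp_24h))
})

test_that("default cohort composition matches the target class sizes", {
  co <- generate_cohort(cohort_spec(seed = 1), diaries = FALSE)
  counts <- table(co$ground_truth$true_class)
  expect_equal(as.integer(counts), c(254, 30, 56, 120))
  # multinomial sampling stays inside the binomial 99% envelope
  co2 <- generate_cohort(cohort_spec(seed = 1,
                                     class_sampling = "multinomial"),
                         diaries = FALSE)
  counts2 <- as.integer(table(factor(co2$ground_truth$true_class, 1:4)))
  p <- c(254, 30, 56, 120) / 460
  lo <- stats::qbinom(0.005, 460, p)
  hi <- stats::qbinom(0.995, 460, p)
  expect_true(all(counts2 >= lo & counts2 <= hi))
})

test_that("a single-class spec yields identical labels", {
  cl <- default_class_spec()[1, ]
  cl$proportion <- 1
  co <- generate_cohort(cohort_spec(n_dyads = 40, classes = cl, seed = 2),
                        diaries = FALSE)
  expect_true(all(co$ground_truth$true_class == 1))
})

test_that("infeasible class specs are rejected", {
  cl <- default_class_spec()
  cl$formula_user_mean[3] <- 5000  # formula would exceed total intake
  expect_error(cohort_spec(classes = cl), "infeasible")
  cl2 <- default_class_spec()
  cl2$proportion[1] <- 0.9
  expect_error(cohort_spec(classes = cl2), "sum to 1")
})

test_that("generated diaries hit their production and intake targets", {
  for (i in 1:25) {
    tmp <- 150 + 900 * (i / 25)
    tf <- if (i %% 3 == 0) 40 * (i / 5) else 0
    d <- generate_diary(target_mp = tmp, target_formula = tf,
                        target_bm_intake = tmp * 0.9 + 20, n_feeds = 8,
                        seed = 100 + i)
    expect_equal(milk_production_24h(d), tmp, tolerance = 0.01)
    it <- diary_intakes(d)
    expect_equal(it$formula_intake_24h, tf, tolerance = 0.01)
    expect_equal(it$breastmilk_intake_24h, tmp * 0.9 + 20, tolerance = 0.01)
  }
})

test_that("diary edge cases behave as specified", {
  d <- generate_diary(789, n_feeds = 8, seed = 3)
  mp <- milk_production_24h(d)
  expect_true(mp >= 781 && mp <= 797)
  expect_false(any(d$kind == "formula_bottle"))
  # two feeds: exactly one volume enters the production sum
  d2 <- generate_diary(400, n_feeds = 2, span_h = 24, seed = 4)
  vols <- event_volumes(d2)
  rem <- vols[vols$kind %in% c("breastfeed", "expression"), ]
  expect_equal(sum(rem$volume_ml[-1]), 400, tolerance = 0.01 * 400)
  expect_error(generate_diary(500, n_feeds = 1), "at least 2")
  expect_error(generate_diary(-10, n_feeds = 5), "non-negative")
})

test_that("missingness injection is MCAR at the requested rates", {
  co <- generate_cohort(cohort_spec(n_dyads = 40, seed = 9), diaries = FALSE)
  full <- co$ground_truth
  # rate 0: identity
  r0 <- inject_missingness(full, list(mp_24h = 0), seed = 1)
  expect_identical(r0$mp_24h, full$mp_24h)
  # rate ~1: whole column missing
  r1 <- inject_missingness(full, list(mp_24h = 0.999999), seed = 1)
  expect_true(all(is.na(r1$mp_24h)))
  expect_error(inject_missingness(full, list(nope = 0.5)), "unknown column")
  # default rates: masked counts inside the binomial 99% envelope
  co460 <- generate_cohort(cohort_spec(seed = 11), diaries = FALSE)
  n_bv <- sum(is.na(co460$cohort$bv_post))
  n_bmi <- sum(is.na(co460$cohort$bmi))
  expect_true(n_bv >= stats::qbinom(0.005, 460, 74 / 460) &&
                n_bv <= stats::qbinom(0.995, 460, 74 / 460))
  expect_true(n_bmi >= stats::qbinom(0.005, 460, 51 / 460) &&
                n_bmi <= stats::qbinom(0.995, 460, 51 / 460))
})

test_that("derived measures reproduce the generator's ground truth", {
  co <- generate_cohort(cohort_spec(n_dyads = 80, seed = 21))
  m <- derive_dyad_measures(co$diaries, co$cohort)
  gt <- co$ground_truth
  m <- m[match(gt$dyad_id, m$dyad_id), ]
  expect_lt(max(abs(m$mp_24h - gt$mp_24h) / gt$mp_24h), 0.01)
  expect_lt(max(abs(m$total_intake_24h - gt$total_intake_24h) /
                  gt$total_intake_24h), 0.01)
  expect_lt(max(abs(m$formula_intake_24h - gt$formula_intake_24h)), 5)
  expect_lt(max(abs(m$waz_current - gt$waz_current)), 0.01)
  expect_lt(max(abs(m$delta_waz - gt$delta_waz)), 0.01)
})

test_that("marginal risk prevalence converges to the mixed class rates", {
  co <- generate_cohort(cohort_spec(n_dyads = 50000, seed = 31),
                        diaries = FALSE)
  cl <- default_class_spec()
  gt <- co$ground_truth
  for (f in c("ow", "gdm", "minimal_breast_growth", "hdp")) {
    implied <- sum(cl$proportion * cl[[paste0("prev_", f)]])
    observed <- mean(gt[[paste0("true_", f)]])
    expect_lt(abs(observed - implied), 0.01)
  }
})
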