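test_that("gram-to-millilitre conversion applies the 1.03 density and clamps", {
  expect_equal(grams_to_ml(103), 100)
  expect_equal(grams_to_ml(0), 0)
  expect_equal(grams_to_ml(82.4), 80)
  expect_equal(grams_to_ml(c(103, 206)), c(100, 200))
  # within scale tolerance: silent clamp to zero
  expect_silent(expect_equal(grams_to_ml(-1), 0))
  # beyond tolerance: clamped with a data-quality warning
  expect_warning(out <- grams_to_ml(-5), "clamped")
  expect_equal(out, 0)
  expect_error(grams_to_ml(Inf), "finite")
})

test_that("event volumes come from pre/post weight differences", {
  d <- tibble::tibble(start_min = 0, end_min = 10, kind = "breastfeed",
                      pre_weight_g = 5000, post_weight_g = 5082.4,
                      breast_side = "left")
  expect_equal(event_volumes(d)$volume_ml, 80)
  d$post_weight_g <- 5000
  expect_equal(event_volumes(d)$volume_ml, 0)
  d$post_weight_g <- 4999  # within the 2 g scale tolerance
  expect_equal(event_volumes(d)$volume_ml, 0)
  d$kind <- "unheard_of"
  expect_error(event_volumes(d), "unknown event kind")
})

test_that("24 h milk production follows the windowed sum formula", {
  d <- make_bf_diary(c(0, 4, 9, 15, 20, 24.5), c(60, 80, 70, 90, 60, 85))
  expect_equal(milk_production_24h(d), (80 + 70 + 90 + 60 + 85) * 24 / 24.5,
               tolerance = 1e-12)
  # T = 24 h makes the scaling the identity
  d2 <- make_bf_diary(c(0, 8, 16, 24), c(60, 120, 140, 125))
  expect_equal(milk_production_24h(d2), 385)
  # single feed: no elapsed interval
  expect_error(milk_production_24h(make_bf_diary(24, 300)), "fewer than 2")
  # formula feeds are excluded from production and from the clock
  d3 <- dplyr::bind_rows(d2, make_bf_diary(12, 100, kind = "formula_bottle"))
  d3 <- d3[order(d3$end_min), ]
  expect_equal(milk_production_24h(d3), 385)
})

test_that("diary validity window is enforced", {
  too_short <- make_bf_diary(c(0, 10), c(60, 300))
  expect_error(milk_production_24h(too_short), "validity window")
  expect_error(validate_diary(make_bf_diary(c(0, 25, 24), c(1, 2, 3))),
               "sorted")
})

test_that("time-scaling a diary scales production by the inverse factor", {
  base_hours <- c(0, 5, 11, 17, 22)
  vols <- c(70, 90, 100, 80, 95)
  for (c_fac in c(0.95, 1.1, 1.25)) {
    d0 <- make_bf_diary(base_hours + 2, vols)          # span 22 h
    d1 <- make_bf_diary((base_hours + 2) * c_fac, vols)
    skip_span <- (max(base_hours) * c_fac) < 20 || (max(base_hours) * c_fac) > 30
    if (!skip_span) {
      expect_equal(milk_production_24h(d1),
                   milk_production_24h(d0) / c_fac, tolerance = 1e-9)
    }
  }
})

test_that("intakes conserve breastmilk + formula = total and exclude pumping", {
  d <- dplyr::bind_rows(
    make_bf_diary(c(0, 6, 12, 18, 24), c(100, 120, 130, 125, 125)),
    make_bf_diary(c(10, 21), c(50, 50), kind = "formula_bottle"),
    make_bf_diary(15, 80, kind = "expression", pre = 600)
  )
  d <- d[order(d$end_min), ]
  it <- diary_intakes(d)
  expect_equal(it$total_intake_24h,
               it$breastmilk_intake_24h + it$formula_intake_24h)
  expect_equal(it$formula_intake_24h, 100)
  expect_equal(it$breastmilk_intake_24h, 500)  # first feed outside window
  # expression counts toward production, not intake
  expect_equal(milk_production_24h(d), 580)
})

test_that("naked weight falls back to the clothed weight minus 200 g", {
  expect_equal(infer_naked_weight(5400, 6000), 5400)
  expect_equal(infer_naked_weight(NA_real_, 5600), 5400)
  expect_true(is.na(infer_naked_weight(NA_real_, NA_real_)))
})

test_that("average daily gain subtracts the 8-day regain period", {
  expect_equal(avg_daily_weight_gain(5400, 3400, 58), 40)
  expect_equal(avg_daily_weight_gain(3400, 3400, 58), 0)
  expect_equal(avg_daily_weight_gain(3430, 3400, 9), 30)
  expect_error(avg_daily_weight_gain(3500, 3400, 8), "undefined")
})

test_that("formula-to-growth ratio handles zero formula and failing growth", {
  expect_equal(formula_to_growth(200, 40), 5)
  expect_equal(formula_to_growth(0, 25), 0)
  expect_equal(formula_to_growth(122, 30.5), 4)
  expect_identical(formula_to_growth(100, 0), Inf)
  expect_identical(formula_to_growth(100, -3), Inf)
  expect_equal(formula_to_growth(0, -3), 0)
})

test_that("breast volume lookup maps sizes and flags growth", {
  lk <- read_bra_lookup()
  expect_equal(breast_volume(12, "B", lk), 450)
  expect_equal(breast_volume(12, "D", lk), 600)
  change <- breast_volume(12, "D", lk) - breast_volume(12, "B", lk)
  expect_equal(change, 150)
  expect_false(change < 100)
  expect_true((-230) < 100)  # most negative reported change flags growth
  expect_warning(v <- breast_volume(99, "B", lk), "not in the volume lookup")
  expect_true(is.na(v))
})

test_that("derived risk flags agree with direct threshold comparison", {
  co <- generate_cohort(cohort_spec(n_dyads = 1000, seed = 77),
                        diaries = FALSE)
  ch <- co$cohort
  m <- ch |>
    dplyr::mutate(
      ow = .data$bmi >= 25,
      advanced_age = .data$maternal_age >= 35,
      minimal_breast_growth = (.data$bv_post - .data$bv_pre) < 100
    )
  # missing inputs propagate to missing flags
  expect_identical(is.na(m$ow), is.na(ch$bmi))
  expect_identical(is.na(m$advanced_age), is.na(ch$maternal_age))
  # where observed, the flag equals the ground-truth draw (covariates were
  # generated conditionally on the flag)
  gt <- co$ground_truth
  ok <- !is.na(m$ow)
  expect_identical(m$ow[ok], gt$true_ow[ok])
  ok <- !is.na(m$advanced_age)
  expect_identical(m$advanced_age[ok], gt$true_advanced_age[ok])
  ok <- !is.na(m$minimal_breast_growth)
  expect_identical(m$minimal_breast_growth[ok],
                   gt$true_minimal_breast_growth[ok])
})
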