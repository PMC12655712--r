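test_that("the intercept-only fit reproduces sample class proportions", {
  y <- factor(rep(1:4, c(254, 30, 56, 120)))
  d <- tibble::tibble(class = y)
  f <- fit_multinomial(d, "class", character(0))
  probs <- colMeans(f$fitted)
  expect_equal(unname(probs), c(254, 30, 56, 120) / 460, tolerance = 1e-7)
})

test_that("a two-level outcome reduces to binary logistic regression", {
  set.seed(31)
  n <- 400
  d <- tibble::tibble(
    x1 = rnorm(n), x2 = rbinom(n, 1, 0.4)
  )
  eta <- -0.3 + 0.8 * d$x1 - 0.5 * d$x2
  d$y <- factor(rbinom(n, 1, stats::plogis(eta)))
  ours <- fit_multinomial(d, "y", c("x1", "x2"))
  glm_fit <- stats::glm(y ~ x1 + x2, data = d, family = stats::binomial())
  expect_equal(unname(ours$coefficients[1, ]), unname(coef(glm_fit)),
               tolerance = 1e-6)
  expect_equal(unname(ours$se[1, ]),
               unname(sqrt(diag(stats::vcov(glm_fit)))), tolerance = 1e-4)
  expect_equal(ours$loglik, as.numeric(stats::logLik(glm_fit)),
               tolerance = 1e-8)
})

test_that("a 2x2 table recovers the closed-form odds ratio", {
  d <- tibble::tibble(
    exposed = rep(c(TRUE, FALSE, TRUE, FALSE), c(31, 16, 101, 86)),
    cls = rep(c("case", "case", "control", "control"),
              c(31, 16, 101, 86))
  )
  f <- fit_multinomial(d, "cls", "exposed", reference = "control")
  or <- exp(f$coefficients["case", "exposedTRUE"])
  expect_equal(or, (31 * 86) / (16 * 101), tolerance = 1e-6)
})

test_that("our Newton fit agrees with the neural-net reference fitter", {
  skip_if_not_installed("nnet")
  set.seed(32)
  n <- 600
  d <- tibble::tibble(x1 = rnorm(n), x2 = runif(n))
  lin2 <- 0.5 + 1.2 * d$x1 - 1 * d$x2
  lin3 <- -0.4 - 0.8 * d$x1 + 0.6 * d$x2
  den <- 1 + exp(lin2) + exp(lin3)
  u <- runif(n)
  p2 <- exp(lin2) / den; p3 <- exp(lin3) / den
  d$y <- factor(ifelse(u < p2, "b", ifelse(u < p2 + p3, "c", "a")))
  ours <- fit_multinomial(d, "y", c("x1", "x2"))
  ref <- nnet::multinom(y ~ x1 + x2, data = d, trace = FALSE,
                        reltol = 1e-14, maxit = 500)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
  expect_lt(ours$grad_norm, 1e-6)
})

test_that("changing the reference level shifts coefficients consistently", {
  set.seed(33)
  n <- 500
  d <- tibble::tibble(x = rnorm(n))
  d$y <- factor(sample(c("a", "b", "c"), n, TRUE, prob = c(0.5, 0.3, 0.2)))
  f_a <- fit_multinomial(d, "y", "x", reference = "a")
  f_b <- fit_multinomial(d, "y", "x", reference = "b")
  # log-odds of c vs b is invariant to the chosen reference
  cvb_from_a <- f_a$coefficients["c", ] - f_a$coefficients["b", ]
  cvb_from_b <- f_b$coefficients["c", ]
  expect_equal(unname(cvb_from_a), unname(cvb_from_b), tolerance = 1e-5)
})

test_that("coefficients are recovered from simulated multinomial data", {
  set.seed(34)
  n <- 5000
  d <- tibble::tibble(x = rnorm(n))
  lin2 <- 0.3 + 0.9 * d$x
  lin3 <- -0.5 + 0.4 * d$x
  den <- 1 + exp(lin2) + exp(lin3)
  u <- runif(n)
  p2 <- exp(lin2) / den; p3 <- exp(lin3) / den
  d$y <- factor(ifelse(u < p2, "2", ifelse(u < p2 + p3, "3", "1")))
  f <- fit_multinomial(d, "y", "x", reference = "1")
  truth <- rbind(c(0.3, 0.9), c(-0.5, 0.4))
  expect_lt(max(abs(unname(f$coefficients) - truth)), 0.12)
})

test_that("tidy output carries odds ratios with bracketing intervals", {
  set.seed(35)
  d <- tibble::tibble(x = rnorm(300),
                      y = factor(sample(1:3, 300, TRUE)))
  td <- tidy(fit_multinomial(d, "y", "x", reference = "1"))
  expect_true(all(td$ci_low <= td$or & td$or <= td$ci_high))
  expect_equal(td$or, exp(td$estimate))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("composites code co-occurrence into four exclusive levels", {
  a <- c(FALSE, TRUE, FALSE, TRUE, NA)
  b <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  cp <- make_composite(a, b)
  expect_equal(as.character(cp),
               c("neither", "a_only", "b_only", "both", NA))
  expect_equal(levels(cp), c("neither", "a_only", "b_only", "both"))
  # full cross-tabulation is reproduced by the level counts
  set.seed(36)
  aa <- rbinom(400, 1, 0.3) == 1
  bb <- rbinom(400, 1, 0.4) == 1
  expect_equal(as.integer(table(make_composite(aa, bb))),
               as.integer(c(sum(!aa & !bb), sum(aa & !bb),
                            sum(!aa & bb), sum(aa & bb))))
})

test_that("a degenerate composite nests the single-factor model", {
  set.seed(37)
  n <- 800
  d <- tibble::tibble(
    a = rbinom(n, 1, 0.4) == 1,
    b = rep(FALSE, n),
    x = rnorm(n)
  )
  lin <- -0.2 + 1.1 * d$a
  d$y <- factor(rbinom(n, 1, stats::plogis(lin)))
  single <- fit_multinomial(d, "y", c("a", "x"))
  expect_warning(
    comp <- fit_composite_model(d, "y", "a", "b", confounders = "x"),
    "empty composite level"
  )
  or_single <- exp(single$coefficients[1, "aTRUE"])
  or_comp <- exp(comp$model$coefficients[1, "a_x_ba_only"])
  expect_equal(or_comp, or_single, tolerance = 1e-6)
  expect_true(any(comp$counts == 0))
})

test_that("backward elimination drops noise and keeps signal", {
  set.seed(38)
  n <- 1500
  d <- tibble::tibble(
    strong = rbinom(n, 1, 0.4) == 1,
    noise1 = rbinom(n, 1, 0.3) == 1,
    noise2 = rbinom(n, 1, 0.2) == 1,
    conf = rnorm(n)
  )
  lin2 <- -1 + 1.6 * d$strong + 0.3 * d$conf
  lin3 <- -1.4 + 0.2 * d$conf
  den <- 1 + exp(lin2) + exp(lin3)
  u <- runif(n)
  p2 <- exp(lin2) / den; p3 <- exp(lin3) / den
  d$y <- factor(ifelse(u < p2, "2", ifelse(u < p2 + p3, "3", "1")))
  kept <- backward_aic(d, "y", c("strong", "noise1", "noise2"), "conf",
                       reference = "1")
  expect_true("strong" %in% kept)
})

test_that("stability selection counts factors across resamples", {
  set.seed(39)
  n <- 900
  d <- tibble::tibble(
    strong = rbinom(n, 1, 0.4) == 1,
    noise = rbinom(n, 1, 0.3) == 1,
    conf = rnorm(n)
  )
  lin2 <- -0.8 + 1.5 * d$strong
  den <- 1 + exp(lin2)
  d$y <- factor(ifelse(runif(n) < exp(lin2) / den, "2", "1"))
  st <- bootstrap_stability(d, "y", c("strong", "noise"), "conf",
                            B = 20, seed = 40)
  expect_true(all(st$frequencies$frequency >= 0 &
                    st$frequencies$frequency <= 1))
  expect_true(st$frequencies$retained[st$frequencies$factor == "strong"])
  expect_gt(st$frequencies$frequency[st$frequencies$factor == "strong"], 0.9)
  # confounders are locked, never candidates
  expect_false("conf" %in% st$frequencies$factor)
  expect_s3_class(st$final_model, "multinom_fit")
  # B = 1 with everything kept retains everything
  st1 <- bootstrap_stability(d, "y", "strong", "conf", B = 1, seed = 41)
  expect_true(all(st1$frequencies$frequency %in% c(0, 1)))
})
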