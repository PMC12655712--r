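# Shared fixtures built in code.

# Diary of breastfeeds ending at the given hours with the given volumes
# (mL); weights are back-computed through the 1.03 g/mL density so the
# package re-derives exactly these volumes.
make_bf_diary <- function(end_hours, volumes_ml, kind = "breastfeed",
                          pre = 5000) {
  tibble::tibble(
    start_min = end_hours * 60 - 10,
    end_min = end_hours * 60,
    kind = kind,
    pre_weight_g = pre,
    post_weight_g = pre + volumes_ml * 1.03,
    breast_side = "left"
  )
}

# Tiny LMS growth reference with constant parameters, handy for closed
# forms: z = ((W/M)^L - 1)/(L*S).
flat_reference <- function(L = 1, M = 5, S = 0.1) {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 2),
    age_days = rep(c(0, 200), 2),
    L = L, M = M, S = S
  )
}

# Two well-separated Gaussian clusters in d dimensions.
two_cluster_data <- function(n = 300, d = 2, delta = 6, seed = 1) {
  set.seed(seed)
  z <- rep(1:2, length.out = n)
  mu <- rbind(rep(0, d), rep(delta, d))
  list(x = mu[z, ] + matrix(rnorm(n * d), n, d), z = z)
}

# Independent enumeration oracle for the two-sided Fisher test:
# hypergeometric point-probability method.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small measures tibble with everything the ROC panel needs.
panel_measures <- function(n = 80, seed = 2) {
  set.seed(seed)
  lms <- rep(c(FALSE, TRUE), each = n / 2)
  tibble::tibble(
    dyad_id = sprintf("P%03d", seq_len(n)),
    mp_24h = ifelse(lms, rnorm(n, 550, 80), rnorm(n, 800, 80)),
    breastmilk_intake_24h = ifelse(lms, rnorm(n, 560, 80), rnorm(n, 780, 80)),
    avg_daily_gain = ifelse(lms, rnorm(n, 24, 5), rnorm(n, 33, 5)),
    formula_intake_24h = ifelse(lms & runif(n) < 0.5, rlnorm(n, 5, 0.4), 0),
    group = ifelse(lms, "LMS", "NMS")
  ) |>
    dplyr::mutate(formula_to_growth = formula_to_growth(
      .data$formula_intake_24h, .data$avg_daily_gain))
}
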