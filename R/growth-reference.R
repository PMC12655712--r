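#' Read a growth reference table of LMS parameters
#'
#' A weight-for-age standard in lambda-mu-sigma (LMS) form: one row per
#' (sex, age_days) with the Box-Cox power `L`, median `M` (kg) and
#' coefficient of variation `S`. The bundled default,
#' `growth_reference_synthetic.csv`, is a *synthetic* WHO-like table
#' (smooth curves through realistic 0-6 month weight medians) intended
#' for simulation and testing; swap in a real standard for analyses of
#' real cohorts.
#'
#' @param path CSV path with columns sex, age_days, L, M, S.
#' @return tibble, validated (M > 0, S > 0, strictly increasing age grid
#'   per sex).
#' @export
read_growth_reference <- function(path = system.file(
                                    "extdata", "growth_reference_synthetic.csv",
                                    package = "milksupply")) {
  ref <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sex = "c", age_days = "d",
                                                 L = "d", M = "d", S = "d"))
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort("growth reference must have M > 0 and S > 0")
  }
  split_ok <- vapply(split(ref$age_days, ref$sex),
                     function(a) all(diff(a) > 0), logical(1))
  if (!all(split_ok)) abort("age grid must be strictly increasing per sex")
  ref
}

interp_lms <- function(age_days, sex, reference) {
  out <- matrix(NA_real_, length(age_days), 3,
                dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex[!is.na(sex)])) {
    rs <- reference[reference$sex == s, ]
    if (!nrow(rs)) abort(sprintf("sex '%s' not present in growth reference", s))
    idx <- which(sex == s & !is.na(age_days))
    if (!length(idx)) next
    a <- age_days[idx]
    if (any(a < min(rs$age_days) - 1e-9 | a > max(rs$age_days) + 1e-9)) {
      abort("age_days outside the growth-reference grid")
    }
    for (p in c("L", "M", "S")) {
      out[idx, p] <- approx(rs$age_days, rs[[p]], xout = a, rule = 1)$y
    }
  }
  out
}

#' Weight-for-age z-score by the LMS method
#'
#' `z = ((W/M)^L - 1) / (L * S)` with L, M, S linearly interpolated at
#' the infant's age for its sex; the `L -> 0` limit uses `log(W/M)/S`.
#'
#' @param weight_g infant weight in grams (the reference `M` is in kg).
#' @param age_days age in days; must lie inside the reference grid.
#' @param sex `"male"` or `"female"` (must match the reference's coding).
#' @param reference tibble from [read_growth_reference()].
#' @return numeric z-score vector (NA where inputs are missing).
#' @export
waz <- function(weight_g, age_days, sex, reference = read_growth_reference()) {
  n <- max(length(weight_g), length(age_days), length(sex))
  weight_g <- rep_len(weight_g, n)
  age_days <- rep_len(age_days, n)
  sex <- rep_len(sex, n)
  if (any(weight_g <= 0, na.rm = TRUE)) abort("weight_g must be positive")
  lms <- interp_lms(age_days, sex, reference)
  w_kg <- weight_g / 1000
  r <- w_kg / lms[, "M"]
  z <- ifelse(abs(lms[, "L"]) < 1e-7,
              log(r) / lms[, "S"],
              (r^lms[, "L"] - 1) / (lms[, "L"] * lms[, "S"]))
  as.numeric(z)
}

#' Invert a weight-for-age z-score to a weight
#'
#' Algebraic inverse of [waz()]: `W = M * (1 + L*S*z)^(1/L)` (or
#' `M * exp(S*z)` at L = 0). Used by the synthetic generator to place
#' infant weights at target z-scores, and by tests as a round-trip
#' oracle.
#'
#' @param z z-score vector.
#' @inheritParams waz
#' @return weight in grams.
#' @export
waz_to_weight <- function(z, age_days, sex, reference = read_growth_reference()) {
  n <- max(length(z), length(age_days), length(sex))
  z <- rep_len(z, n)
  age_days <- rep_len(age_days, n)
  sex <- rep_len(sex, n)
  lms <- interp_lms(age_days, sex, reference)
  w_kg <- ifelse(abs(lms[, "L"]) < 1e-7,
                 lms[, "M"] * exp(lms[, "S"] * z),
                 lms[, "M"] * (1 + lms[, "L"] * lms[, "S"] * z)^(1 / lms[, "L"]))
  as.numeric(w_kg * 1000)
}
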