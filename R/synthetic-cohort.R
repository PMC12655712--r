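#' Default latent-class specification for the synthetic cohort
#'
#' Four milk-supply classes with indicator centres at the reported class
#' medians (MP 789/1171/427/604 mL/24 h), class proportions
#' 254/30/56/120 of 460, class-conditional risk-factor prevalences at
#' the reported per-class rates, and zero-inflated formula intake
#' concentrated in the severe low-supply class. Spreads are free
#' parameters of the generator, fixed once so that the pooled cohort
#' reproduces the reported marginal calibration targets (MP
#' 734 +- 228 mL/24 h, 82.4% fully breastfeeding, mean formula
#' 51 mL/24 h, ~81 partially breastfeeding dyads).
#'
#' @return tibble with one row per class: proportions, indicator centres
#'   and spreads, formula-use mixture parameters, and `prev_*` columns
#'   giving class-conditional risk-factor prevalences.
#' @export
default_class_spec <- function() {
  tibble::tibble(
    class = 1:4,
    label = c("adequate", "oversupply", "severe_lms", "slow_growth"),
    proportion = c(254, 30, 56, 120) / 460,
    mp_centre = c(789, 1171, 427, 604),
    mp_sd = c(135, 150, 120, 125),
    intake_centre = c(801, 1032, 760, 615),
    intake_sd = c(100, 110, 120, 95),
    formula_user_rate = c(0.05, 0, 1.00, 0.05),
    formula_user_mean = c(25, 25, 370, 25),
    formula_user_sdlog = c(0.6, 0.6, 0.6, 0.6),
    waz_centre = c(-0.05, 0.26, -0.30, -1.11),
    waz_sd = c(0.70, 0.70, 0.70, 0.55),
    dwaz_centre = c(-0.40, -0.20, -0.60, -1.40),
    dwaz_sd = c(0.60, 0.60, 0.60, 0.50),
    prev_ow = c(0.540, 0.182, 0.660, 0.487),
    prev_advanced_age = c(0.321, 0.273, 0.511, 0.250),
    prev_gdm = c(0.198, 0.182, 0.298, 0.329),
    prev_minimal_breast_growth = c(0.193, 0.273, 0.511, 0.171),
    prev_fertility_issues = c(0.107, 0.136, 0.149, 0.145),
    prev_thyroid = c(0.091, 0.136, 0.085, 0.079),
    prev_pcos = c(0.091, 0.136, 0.085, 0.092),
    prev_nipple_piercing_or_surgery = c(0.080, 0.000, 0.043, 0.066),
    prev_pph = c(0.086, 0.091, 0.106, 0.053),
    prev_hdp = c(0.086, 0.000, 0.021, 0.026)
  )
}

RISK_FACTORS <- c("ow", "advanced_age", "gdm", "minimal_breast_growth",
                  "fertility_issues", "thyroid", "pcos",
                  "nipple_piercing_or_surgery", "pph", "hdp")

#' Default per-variable missingness rates
#'
#' Missing-completely-at-random rates matching the reported missing-data
#' column: change in breast volume 16.1%, BMI 11.1%, maternal age 0.9%,
#' birth mode 3.7%, education and marital status 0.2% each.
#'
#' @export
default_missingness <- function() {
  list(bmi = 51 / 460, bv = 74 / 460, maternal_age = 4 / 460,
       birth_mode = 17 / 460, education_bachelor = 1 / 460,
       marital_married = 1 / 460)
}

#' Build a cohort-simulation specification
#'
#' @param n_dyads number of mother-infant pairs (default 460).
#' @param classes class specification tibble, see [default_class_spec()].
#' @param missingness named list of MCAR rates (`bv` masks the pre/post
#'   breast volumes jointly).
#' @param class_sampling `"fixed"` draws the exact cohort composition
#'   (largest-remainder counts, randomly permuted over dyads);
#'   `"multinomial"` draws class sizes multinomially.
#' @param naked_weight_rate share of infants with a measured naked weight
#'   (the remainder rely on the clothed first pre-feed weight).
#' @param seed integer seed; mandatory for reproducibility.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dyads = 460, classes = default_class_spec(),
                        missingness = default_missingness(),
                        class_sampling = c("fixed", "multinomial"),
                        naked_weight_rate = 259 / 460, seed = 1L) {
  class_sampling <- match.arg(class_sampling)
  if (n_dyads <= 0) abort("n_dyads must be positive")
  if (abs(sum(classes$proportion) - 1) > 1e-8) {
    abort("class proportions must sum to 1")
  }
  sds <- unlist(classes[grepl("_sd$|_sdlog$", names(classes))])
  if (any(sds <= 0)) abort("all class spreads must be positive")
  prev <- unlist(classes[grepl("^prev_", names(classes))])
  if (any(prev < 0 | prev > 1)) abort("prevalences must lie in [0, 1]")
  bad_rates <- unlist(missingness) < 0 | unlist(missingness) >= 1
  if (any(bad_rates)) abort("missingness rates must lie in [0, 1)")
  # feasibility of the intake ledger: breast-milk intake centre must stay
  # positive after subtracting typical formula volumes
  bm_centre <- classes$intake_centre -
    classes$formula_user_rate * classes$formula_user_mean
  if (any(bm_centre <= 0)) {
    abort("infeasible class spec: formula centres exceed total intake centres")
  }
  structure(list(n_dyads = as.integer(n_dyads), classes = classes,
                 missingness = missingness, class_sampling = class_sampling,
                 naked_weight_rate = naked_weight_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 200L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

draw_classes <- function(n, proportions, sampling) {
  k <- length(proportions)
  if (sampling == "multinomial") {
    return(sample(seq_len(k), n, replace = TRUE, prob = proportions))
  }
  # largest-remainder apportionment, then a random permutation over dyads
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    counts[order(raw - counts, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(raw - counts, decreasing = TRUE)[seq_len(short)]] + 1
  }
  sample(rep(seq_len(k), counts))
}

#' Generate a synthetic mother-infant cohort
#'
#' Draws latent class membership, the five feeding/growth indicators from
#' class-conditional distributions (formula intake zero-inflated
#' log-normal, the others truncated normal), class-conditional Bernoulli
#' risk flags, covariates consistent with those flags (maternal age, BMI
#' and breast-volume change are drawn conditionally on their flag so that
#' recomputing a flag from its covariate reproduces the ground truth),
#' infant weights placed at the target z-scores by inverting the LMS
#' growth reference, and per-dyad test-weighing diaries that reproduce
#' the target production/intake values. MCAR missingness is applied last;
#' the pre-masking truth is kept in a ground-truth ledger.
#'
#' @param spec a [cohort_spec()].
#' @param diaries logical; also simulate per-event feed diaries.
#' @param reference growth reference used to place infant weights.
#' @return object of class `milk_cohort`: list with `cohort` (per-dyad
#'   covariates, post-missingness), `diaries` (event-level tibble or
#'   NULL), `ground_truth` (true class, true indicator values, true
#'   flags), and the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), diaries = TRUE,
                            reference = read_growth_reference()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_dyads
  cl <- spec$classes
  z <- draw_classes(n, cl$proportion, spec$class_sampling)
  g <- cl[z, ]

  mp <- rtrunc_norm(n, g$mp_centre, g$mp_sd, lo = 60)
  total <- rtrunc_norm(n, g$intake_centre, g$intake_sd, lo = 280)
  uses_formula <- rbinom(n, 1, g$formula_user_rate) == 1
  formula_ml <- ifelse(
    uses_formula,
    rlnorm(n, log(g$formula_user_mean) - g$formula_user_sdlog^2 / 2,
           g$formula_user_sdlog),
    0
  )
  formula_ml <- pmin(formula_ml, 0.85 * total)
  bm_intake <- total - formula_ml
  waz_now <- rtrunc_norm(n, g$waz_centre, g$waz_sd, lo = -3.8, hi = 2.6)
  dwaz <- rtrunc_norm(n, g$dwaz_centre, g$dwaz_sd, lo = -3.6, hi = 1.8)
  waz_birth <- pmin(pmax(waz_now - dwaz, -3.0), 3.5)
  dwaz <- waz_now - waz_birth

  # risk flags by class-conditional Bernoulli draws
  flags <- vapply(RISK_FACTORS, function(f) {
    rbinom(n, 1, g[[paste0("prev_", f)]]) == 1
  }, logical(n))
  flags <- tibble::as_tibble(flags)

  # covariates consistent with the derived flags
  maternal_age <- ifelse(flags$advanced_age,
                         rtrunc_norm(n, 36.6, 2.6, 35, 45.9),
                         rtrunc_norm(n, 31.3, 2.9, 22.7, 34.9))
  bmi <- ifelse(flags$ow,
                pmin(25 + stats::rgamma(n, shape = 1.6, scale = 2.8), 62.5),
                rtrunc_norm(n, 22.0, 1.9, 17.2, 24.9))
  bv_change <- ifelse(flags$minimal_breast_growth,
                      rtrunc_norm(n, 30, 65, -230, 99),
                      rtrunc_norm(n, 235, 110, 100, 660))
  bv_pre <- rtrunc_norm(n, 500, 140, 250, 900)
  bv_post <- bv_pre + bv_change
  height_m <- rtrunc_norm(n, 1.65, 0.07, 1.45, 1.90)

  infant_sex <- ifelse(runif(n) < 0.45, "male", "female")
  age_days <- round(rtrunc_norm(n, 12.8, 5.1, 4.2, 26) * 7)
  gestation <- rtrunc_norm(n, 39.3, 1.1, 37, 42.4)
  birth_weight <- round(waz_to_weight(waz_birth, 0, infant_sex, reference))
  naked_weight <- round(waz_to_weight(waz_now, age_days, infant_sex, reference))
  has_naked <- runif(n) < spec$naked_weight_rate

  cohort <- tibble::tibble(
    dyad_id = sprintf("D%04d", seq_len(n)),
    maternal_age = maternal_age,
    height_m = height_m,
    prepreg_weight_kg = bmi * height_m^2,
    bmi = bmi,
    bv_pre = bv_pre,
    bv_post = bv_post,
    parity_primiparous = runif(n) < 0.593,
    birth_mode = ifelse(runif(n) < 0.603, "vaginal", "caesarean"),
    education_bachelor = runif(n) < 0.721,
    marital_married = runif(n) < 0.954,
    infant_sex = infant_sex,
    birth_gestation_weeks = gestation,
    birth_weight_g = birth_weight,
    current_weight_naked_g = ifelse(has_naked, naked_weight, NA_real_),
    first_prefeed_weight_g = naked_weight + 200,
    age_at_measurement_days = age_days,
    gdm = flags$gdm,
    fertility_issues = flags$fertility_issues,
    thyroid = flags$thyroid,
    pcos = flags$pcos,
    nipple_piercing_or_surgery = flags$nipple_piercing_or_surgery,
    pph = flags$pph,
    hdp = flags$hdp
  )

  ground_truth <- dplyr::bind_cols(
    tibble::tibble(
      dyad_id = cohort$dyad_id, true_class = z,
      true_label = cl$label[z],
      mp_24h = mp, breastmilk_intake_24h = bm_intake,
      formula_intake_24h = formula_ml, total_intake_24h = total,
      waz_birth = waz_birth, waz_current = waz_now, delta_waz = dwaz,
      naked_weight_g = naked_weight
    ),
    stats::setNames(flags, paste0("true_", names(flags)))
  )

  diary_tbl <- NULL
  if (diaries) {
    n_feeds <- pmax(5L, round(rtrunc_norm(n, 11, 3.5, 4, 24)))
    diary_tbl <- purrr::map_dfr(seq_len(n), function(i) {
      d <- generate_diary(
        target_mp = mp[i], target_formula = formula_ml[i],
        target_bm_intake = bm_intake[i], n_feeds = n_feeds[i],
        infant_weight_g = naked_weight[i] + 200,
        seed = derive_seed(spec$seed, i)
      )
      d$dyad_id <- cohort$dyad_id[i]
      d
    })
    diary_tbl <- dplyr::relocate(diary_tbl, "dyad_id")
  }

  cohort <- inject_missingness(
    cohort, spec$missingness, seed = derive_seed(spec$seed, 999983L),
    groups = list(bv = c("bv_pre", "bv_post"))
  )

  structure(list(cohort = cohort, diaries = diary_tbl,
                 ground_truth = ground_truth, spec = spec),
            class = "milk_cohort")
}

#' @export
print.milk_cohort <- function(x, ...) {
  cat(sprintf("<milk_cohort> %d dyads, %d latent classes%s\n",
              x$spec$n_dyads, nrow(x$spec$classes),
              if (is.null(x$diaries)) "" else
                sprintf(", %d diary events", nrow(x$diaries))))
  invisible(x)
}

#' Simulate one test-weighing feed diary hitting target volumes
#'
#' Builds a "24 h plus one feed" event log whose recomputed milk
#' production, breast-milk intake and formula intake match the targets
#' within 1%. Feed volumes are drawn log-normally and rescaled; the
#' ledger split rule keeps production and intake consistent: when intake
#' is below production the surplus is pump-expressed (counted in MP
#' only), when intake exceeds production the excess is bottle-fed
#' previously expressed milk (counted in intake only).
#'
#' @param target_mp target 24 h milk production (mL), >= 0.
#' @param target_formula target 24 h formula intake (mL).
#' @param target_bm_intake target 24 h breast-milk intake (mL); defaults
#'   to `target_mp` (no expression surplus, no stored milk).
#' @param n_feeds number of breastfeeds (>= 2).
#' @param span_h diary span (end of first to end of last removal), hours.
#' @param infant_weight_g clothed infant weight used for pre-feed scale
#'   readings.
#' @param seed integer seed.
#' @return tibble of feed events, ordered by end time.
#' @export
generate_diary <- function(target_mp, target_formula = 0,
                           target_bm_intake = NULL, n_feeds = 10,
                           span_h = NULL, infant_weight_g = 5500,
                           seed = NULL) {
  assert_scalar_number(target_mp, "target_mp")
  if (target_mp < 0) abort("target_mp must be non-negative")
  if (n_feeds < 2) abort("n_feeds must be at least 2 (elapsed interval)")
  if (!is.null(seed)) set.seed(seed)
  target_bm_intake <- target_bm_intake %||% target_mp
  span_h <- span_h %||% runif(1, 23.6, 25.6)
  w <- span_h / 24

  R <- target_mp * w            # removal volume entering the Eq-1 sum
  I <- target_bm_intake * w     # breast-milk intake inside the window
  f_tot <- target_formula * w
  D <- min(R, I)                # direct breastfeed volume (non-first feeds)
  E <- R - D                    # pump-expressed surplus
  X <- I - D                    # bottle-fed stored milk
  if (n_feeds < 2 || (D <= 0 && R > 0 && E <= 0)) {
    abort("targets unreachable with the requested number of feeds")
  }

  raw <- rlnorm(n_feeds, log(70), 0.4)
  sc <- if (sum(raw[-1]) > 0) D / sum(raw[-1]) else 0
  bf_vol <- raw * sc
  bf_vol[1] <- raw[1] * sc      # first feed sized like the others; not summed

  n_expr <- if (E > 1e-9) max(1L, ceiling(E / 130)) else 0L
  expr_vol <- if (n_expr) as.vector(E * prop.table(runif(n_expr, 0.7, 1.3))) else numeric(0)
  n_x <- if (X > 1e-9) max(1L, ceiling(X / 110)) else 0L
  x_vol <- if (n_x) as.vector(X * prop.table(runif(n_x, 0.7, 1.3))) else numeric(0)
  n_f <- if (f_tot > 1e-9) max(1L, ceiling(f_tot / 100)) else 0L
  f_vol <- if (n_f) as.vector(f_tot * prop.table(runif(n_f, 0.7, 1.3))) else numeric(0)

  span_min <- span_h * 60
  n_rem <- n_feeds + n_expr
  rem_ends <- c(0, sort(runif(n_rem - 2L, 30, span_min - 30)), span_min)
  rem_kind <- c("breastfeed",
                sample(rep(c("breastfeed", "expression"),
                           c(n_feeds - 1L, n_expr))))
  rem_vol <- numeric(n_rem)
  rem_vol[rem_kind == "breastfeed"] <- bf_vol
  rem_vol[rem_kind == "expression"] <- expr_vol

  bottle_kind <- rep(c("expressed_bottle", "formula_bottle"), c(n_x, n_f))
  bottle_vol <- c(x_vol, f_vol)
  bottle_ends <- runif(length(bottle_vol), 20, span_min - 5)

  ends <- c(rem_ends, bottle_ends)
  kinds <- c(rem_kind, bottle_kind)
  vols <- c(rem_vol, bottle_vol)
  dur <- ifelse(kinds == "breastfeed", pmax(4, rnorm(length(ends), 13, 5)),
                ifelse(kinds == "expression", 15, 10))

  pre <- ifelse(kinds == "expression",
                round(600 + rnorm(length(ends), 0, 5), 1),
                round(infant_weight_g + rnorm(length(ends), 0, 25), 1))
  post <- round(pre + vols * MILK_DENSITY_G_PER_ML, 1)

  d <- tibble::tibble(
    start_min = ends - dur, end_min = ends, kind = kinds,
    pre_weight_g = pre, post_weight_g = post,
    breast_side = ifelse(kinds %in% c("breastfeed", "expression"),
                         sample(c("left", "right"), length(ends),
                                replace = TRUE), "n/a")
  )
  d <- d[order(d$end_min), ]
  # break exact end-time ties so the ordering invariant holds
  while (any(duplicated(d$end_min))) {
    i <- which(duplicated(d$end_min))
    d$end_min[i] <- d$end_min[i] + 0.01
    d <- d[order(d$end_min), ]
  }
  d
}

#' Mask values completely at random
#'
#' Applies per-variable MCAR masking at the given rates and records the
#' mask as an attribute. Column groups (e.g. pre/post breast volume) can
#' be masked jointly with a single draw per row.
#'
#' @param records tibble.
#' @param rates named list of rates in `[0, 1)`; names must be column
#'   names or names of entries in `groups`.
#' @param seed integer seed.
#' @param groups named list mapping a rate name to several columns masked
#'   together.
#' @return `records` with masked cells set to `NA`; the logical mask is
#'   attached as attribute `"missing_mask"`.
#' @export
inject_missingness <- function(records, rates, seed = NULL, groups = list()) {
  if (!is.null(seed)) set.seed(seed)
  mask <- list()
  for (nm in names(rates)) {
    cols <- if (nm %in% names(groups)) groups[[nm]] else nm
    missing_cols <- setdiff(cols, names(records))
    if (length(missing_cols)) {
      abort(paste0("unknown column(s) in missingness rates: ",
                   paste(missing_cols, collapse = ", ")))
    }
    hit <- runif(nrow(records)) < rates[[nm]]
    for (cc in cols) {
      records[[cc]][hit] <- NA
      mask[[cc]] <- hit
    }
  }
  attr(records, "missing_mask") <- mask
  records
}
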