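#' Milk density used to convert test-weighing grams to millilitres
#'
#' Human milk has a density close to 1.03 g/mL, so a weight difference of
#' 103 g on the baby scale corresponds to 100 mL of milk transferred.
#'
#' @export
MILK_DENSITY_G_PER_ML <- 1.03

#' Event kinds recognised in a feed diary
#'
#' `breastfeed` and `expression` are maternal milk *removal* events and
#' enter the 24 h milk-production sum; `breastfeed`, `expressed_bottle`
#' and `formula_bottle` are infant *intake* events. Bottle-fed expressed
#' milk is counted as intake but not as production (it was produced and
#' weighed at an earlier removal), keeping the two ledgers consistent.
#'
#' @export
FEED_KINDS <- c("breastfeed", "expressed_bottle", "formula_bottle", "expression")

REMOVAL_KINDS <- c("breastfeed", "expression")
INTAKE_KINDS <- c("breastfeed", "expressed_bottle", "formula_bottle")

#' Convert a milk mass in grams to a volume in millilitres
#'
#' Divides by the 1.03 g/mL density of human milk. Negative masses (scale
#' jitter) are clamped to 0 mL; values more negative than `tolerance_g`
#' (the +-2 g instrument accuracy) additionally raise a data-quality
#' warning, but are still clamped, never propagated as negative intake.
#'
#' @param mass_g numeric vector of milk masses in grams.
#' @param tolerance_g scale tolerance in grams (default 2).
#' @return numeric vector of volumes in mL.
#' @examples
#' grams_to_ml(103)   # 100 mL
#' grams_to_ml(82.4)  # 80 mL
#' @export
grams_to_ml <- function(mass_g, tolerance_g = 2) {
  if (!is.numeric(mass_g) || any(!is.finite(mass_g) & !is.na(mass_g))) {
    abort("`mass_g` must be numeric and finite (NA allowed for missing).")
  }
  if (any(mass_g < -tolerance_g, na.rm = TRUE)) {
    warn(sprintf(
      "%d mass difference(s) more negative than the %g g scale tolerance; clamped to 0 mL.",
      sum(mass_g < -tolerance_g, na.rm = TRUE), tolerance_g
    ))
  }
  pmax(mass_g, 0) / MILK_DENSITY_G_PER_ML
}

#' Per-event milk volumes of a feed diary
#'
#' Adds a `volume_ml` column: the pre/post weight difference converted to
#' millilitres. For breastfeeds and bottle feeds the weights are the
#' infant's; for pump expressions they are the pump set's. Events with a
#' missing weight get `NA` volume and are excluded downstream.
#'
#' @param diary tibble of feed events (see [read_diary_csv()] for columns).
#' @inheritParams grams_to_ml
#' @return the diary with a `volume_ml` column appended.
#' @export
event_volumes <- function(diary, tolerance_g = 2) {
  check_diary_frame(diary)
  diary$volume_ml <- grams_to_ml(diary$post_weight_g - diary$pre_weight_g,
                                 tolerance_g = tolerance_g)
  diary
}

check_diary_frame <- function(diary) {
  needed <- c("start_min", "end_min", "kind", "pre_weight_g", "post_weight_g")
  missing_cols <- setdiff(needed, names(diary))
  if (length(missing_cols)) {
    abort(paste0("diary is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- diary$kind[!diary$kind %in% FEED_KINDS]
  if (length(bad)) {
    abort(paste0("unknown event kind(s): ", paste(unique(bad), collapse = ", ")))
  }
  invisible(diary)
}

#' Validate a "24 h plus one feed" diary
#'
#' Checks event ordering, that at least two maternal milk-removal events
#' are present (the production formula needs an elapsed interval), and
#' that the span from the end of the first removal to the end of the last
#' removal falls inside the validity window (20-30 h by default).
#'
#' @param diary tibble of feed events.
#' @param window_h length-2 numeric, allowed diary span in hours.
#' @return invisibly, a list with `t_hours`, `n_removals` and the window
#'   origin (minutes); aborts with a descriptive error otherwise.
#' @export
validate_diary <- function(diary, window_h = c(20, 30)) {
  check_diary_frame(diary)
  if (any(diary$end_min <= diary$start_min, na.rm = TRUE)) {
    abort("every event must have end_time > start_time")
  }
  if (is.unsorted(diary$end_min)) {
    abort("diary events must be sorted by end time")
  }
  rem <- diary[diary$kind %in% REMOVAL_KINDS, ]
  if (nrow(rem) < 2L) {
    abort("diary has fewer than 2 milk-removal events; elapsed interval undefined")
  }
  t_hours <- (max(rem$end_min) - min(rem$end_min)) / 60
  if (t_hours < window_h[1] || t_hours > window_h[2]) {
    abort(sprintf(
      "diary span %.2f h outside the [%g, %g] h validity window", t_hours,
      window_h[1], window_h[2]
    ))
  }
  invisible(list(t_hours = t_hours, n_removals = nrow(rem),
                 origin_min = min(rem$end_min)))
}

#' 24 h milk production from a test-weighing diary
#'
#' Sums the volumes of all maternal milk-removal events (breastfeeds and
#' pump expressions) *after* the first one and normalises to a 24 h day:
#' `MP = sum(v_i, i = 2..N) * 24 / T`, where `T` (hours) is the elapsed
#' time from the end of the first removal to the end of the last. The
#' first feed's volume is excluded because the milk it delivered was
#' synthesised before the measurement window opened. Formula feeds and
#' bottle-fed expressed milk never enter the sum.
#'
#' @inheritParams validate_diary
#' @inheritParams grams_to_ml
#' @return milk production in mL per 24 h (scalar).
#' @examples
#' d <- tibble::tibble(
#'   start_min = c(0, 240, 540, 900, 1200, 1470) - 10,
#'   end_min = c(0, 240, 540, 900, 1200, 1470),
#'   kind = "breastfeed",
#'   pre_weight_g = 5000,
#'   post_weight_g = 5000 + 1.03 * c(60, 80, 70, 90, 60, 85)
#' )
#' milk_production_24h(d)  # 377.14 mL/24 h
#' @export
milk_production_24h <- function(diary, window_h = c(20, 30), tolerance_g = 2) {
  v <- validate_diary(diary, window_h)
  diary <- event_volumes(diary, tolerance_g = tolerance_g)
  rem <- diary[diary$kind %in% REMOVAL_KINDS & !is.na(diary$volume_ml), ]
  if (nrow(rem) < 2L) {
    abort("fewer than 2 milk-removal events with usable weights")
  }
  sum(rem$volume_ml[-1L]) * 24 / v$t_hours
}

#' Infant 24 h intakes from a feed diary
#'
#' Computes breast-milk intake (direct breastfeeds plus bottle-fed
#' expressed milk), formula intake, and their total, all scaled to the
#' same 24/T window as [milk_production_24h()] (events ending after the
#' window origin, i.e. the end of the first milk-removal event). Pump
#' expressions are excluded: they are production, not intake.
#'
#' @inheritParams milk_production_24h
#' @return one-row tibble with `breastmilk_intake_24h`,
#'   `formula_intake_24h`, `total_intake_24h` (mL/24 h).
#' @export
diary_intakes <- function(diary, window_h = c(20, 30), tolerance_g = 2) {
  v <- validate_diary(diary, window_h)
  diary <- event_volumes(diary, tolerance_g = tolerance_g)
  win <- diary[diary$end_min > v$origin_min & !is.na(diary$volume_ml), ]
  scale <- 24 / v$t_hours
  bm <- sum(win$volume_ml[win$kind %in% c("breastfeed", "expressed_bottle")]) * scale
  fo <- sum(win$volume_ml[win$kind == "formula_bottle"]) * scale
  tibble::tibble(
    breastmilk_intake_24h = bm,
    formula_intake_24h = fo,
    total_intake_24h = bm + fo
  )
}

#' Infer the infant's naked weight
#'
#' Uses the measured naked weight when available, otherwise subtracts
#' 200 g from the first pre-feed (clothed) weight to account for clothing
#' and diaper. Returns `NA` when both are absent.
#'
#' @param naked_g measured naked weight (g), possibly `NA`.
#' @param first_prefeed_g first pre-feed clothed weight (g), possibly `NA`.
#' @param clothing_g clothing + diaper allowance in grams (default 200).
#' @return numeric vector of naked weights in grams.
#' @export
infer_naked_weight <- function(naked_g, first_prefeed_g, clothing_g = 200) {
  dplyr::coalesce(naked_g, first_prefeed_g - clothing_g)
}

#' Average daily infant weight gain, adjusted for early neonatal loss
#'
#' Healthy term newborns typically lose weight in the first days and
#' regain birth weight by about day 8, so 8 days are subtracted from the
#' infant's age: `gain = (current - birth) / (age_days - 8)`.
#'
#' @param current_g current naked weight (g).
#' @param birth_g birth weight (g).
#' @param age_days infant age in days; must exceed 8.
#' @return gain in g/day.
#' @export
avg_daily_weight_gain <- function(current_g, birth_g, age_days) {
  if (any(age_days <= 8, na.rm = TRUE)) {
    abort("average daily weight gain undefined for age_days <= 8")
  }
  (current_g - birth_g) / (age_days - 8)
}

#' Formula-to-growth ratio
#'
#' Millilitres of formula per gram of average daily weight gain. A dyad
#' with no formula has ratio 0 regardless of gain; a dyad receiving
#' formula with zero or negative gain gets `+Inf` -- the severest
#' presentation, ranked at maximal risk by the ROC machinery.
#'
#' @param formula_ml 24 h formula intake (mL).
#' @param gain_g_day average daily weight gain (g/day).
#' @return ratio in mL/g.
#' @export
formula_to_growth <- function(formula_ml, gain_g_day) {
  dplyr::case_when(
    is.na(formula_ml) | is.na(gain_g_day) ~ NA_real_,
    formula_ml == 0 ~ 0,
    gain_g_day > 0 ~ formula_ml / gain_g_day,
    TRUE ~ Inf
  )
}

#' Breast volume from bra band and cup size
#'
#' Looks up a (band, cup) pair in a configurable volume table; unmapped
#' sizes return `NA` with a warning. The shipped table
#' (`bra_volume_lookup_synthetic.csv`) is a synthetic placeholder -- all
#' downstream logic depends only on the *change* in breast volume and the
#' 100 cm3 minimal-growth threshold, so the table can be swapped for any
#' validated band/cup volume mapping.
#'
#' @param band numeric bra band size(s).
#' @param cup character cup size(s).
#' @param lookup tibble with columns band, cup, volume_cm3; defaults to
#'   the bundled synthetic table.
#' @return breast volume(s) in cm3.
#' @export
breast_volume <- function(band, cup, lookup = read_bra_lookup()) {
  key <- paste(band, toupper(cup))
  tab <- setNames(lookup$volume_cm3, paste(lookup$band, toupper(lookup$cup)))
  out <- unname(tab[key])
  unmapped <- !is.na(band) & !is.na(cup) & is.na(out)
  if (any(unmapped)) {
    warn(sprintf("%d bra size(s) not in the volume lookup; returned NA.",
                 sum(unmapped)))
  }
  out
}

#' @rdname breast_volume
#' @param path CSV path (columns band, cup, volume_cm3).
#' @export
read_bra_lookup <- function(path = system.file("extdata",
                                               "bra_volume_lookup_synthetic.csv",
                                               package = "milksupply")) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(band = "d", cup = "c",
                                          volume_cm3 = "d"))
}

#' Derive all per-dyad feeding and growth measures
#'
#' The measurement pipeline: computes 24 h milk production and intakes
#' from each dyad's diary, infers the naked weight, evaluates weight-for-
#' age z-scores (WAZ) at birth and at measurement against a growth
#' reference, their difference, the adjusted average daily weight gain,
#' the formula-to-growth ratio, and the binary risk flags that are
#' derived from continuous covariates (overweight, advanced maternal age,
#' minimal breast growth). Derived flags are `NA` whenever their inputs
#' are missing, so descriptive tables keep per-variable denominators.
#'
#' @param diaries tibble of feed events for all dyads (with `dyad_id`).
#' @param cohort per-dyad covariate tibble (one row per dyad).
#' @param reference growth reference from [read_growth_reference()].
#' @param window_h diary validity window in hours.
#' @param bmi_cut,age_cut,bv_cut thresholds defining overweight
#'   (BMI >= 25 kg/m2), advanced maternal age (>= 35 y), and minimal
#'   breast growth (change in BV < 100 cm3).
#' @return cohort tibble with derived columns appended.
#' @export
derive_dyad_measures <- function(diaries, cohort,
                                 reference = read_growth_reference(),
                                 window_h = c(20, 30),
                                 bmi_cut = 25, age_cut = 35, bv_cut = 100) {
  feeding <- diaries |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::group_modify(function(d, key) {
      mp <- milk_production_24h(d, window_h = window_h)
      dplyr::bind_cols(tibble::tibble(mp_24h = mp),
                       diary_intakes(d, window_h = window_h))
    }) |>
    dplyr::ungroup()

  out <- cohort |>
    dplyr::left_join(feeding, by = "dyad_id") |>
    dplyr::mutate(
      naked_weight_g = infer_naked_weight(.data$current_weight_naked_g,
                                          .data$first_prefeed_weight_g),
      waz_birth = waz(.data$birth_weight_g, 0, .data$infant_sex, reference),
      waz_current = waz(.data$naked_weight_g, .data$age_at_measurement_days,
                        .data$infant_sex, reference),
      delta_waz = .data$waz_current - .data$waz_birth,
      avg_daily_gain = avg_daily_weight_gain(.data$naked_weight_g,
                                             .data$birth_weight_g,
                                             .data$age_at_measurement_days),
      formula_to_growth = formula_to_growth(.data$formula_intake_24h,
                                            .data$avg_daily_gain),
      bv_change = .data$bv_post - .data$bv_pre,
      ow = .data$bmi >= bmi_cut,
      advanced_age = .data$maternal_age >= age_cut,
      minimal_breast_growth = .data$bv_change < bv_cut,
      fully_breastfeeding = .data$formula_intake_24h == 0
    )
  out
}
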