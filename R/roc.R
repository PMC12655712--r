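#' ROC curve for a low-milk-supply predictor
#'
#' Builds the full ROC curve of a continuous score against a binary
#' LMS-positive label. Thresholds are placed at midpoints between
#' consecutive distinct scores plus -Inf/+Inf sentinels. Direction is
#' handled by a sign convention, never by mutating the data: with
#' `direction = "higher"` a dyad is called positive when its score
#' exceeds the threshold; with `"lower"` when the score falls below it
#' (e.g. low milk production indicating LMS). `+Inf` scores (maximal-risk
#' markers such as an infinite formula-to-growth ratio) sort above all
#' finite scores.
#'
#' @param score numeric predictor (finite or `Inf`); `NA` rows dropped.
#' @param label logical or 0/1 vector, `TRUE` = LMS-positive.
#' @param direction `"higher"` or `"lower"`: which scores indicate LMS.
#' @param name predictor name carried into reports.
#' @return object of class `lms_roc`: threshold grid with sensitivity
#'   and specificity, AUC (trapezoid and rank-statistic), the
#'   Youden-optimal threshold and counts.
#' @export
roc_curve <- function(score, label, direction = c("higher", "lower"),
                      name = "score") {
  direction <- match.arg(direction)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC undefined: both classes must be represented")
  }
  s <- if (direction == "higher") score else -score

  u <- sort(unique(s))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  if (length(mids)) {
    # a midpoint with an infinite neighbour is degenerate; cut just above
    # (below) the largest (smallest) finite score instead
    hi <- !is.finite(mids) & mids > 0
    lo <- !is.finite(mids) & mids < 0
    mids[hi] <- max(u[is.finite(u)]) + 1
    mids[lo] <- min(u[is.finite(u)]) - 1
    mids <- unique(mids[is.finite(mids)])
  }
  thr_internal <- c(-Inf, mids, Inf)
  sens <- vapply(thr_internal, function(t) mean(s[label] > t), numeric(1))
  spec <- vapply(thr_internal, function(t) mean(s[!label] <= t), numeric(1))

  # tie-corrected rank statistic (Mann-Whitney with ties counted 1/2)
  rk <- rank(s)
  auc_rank <- (sum(rk[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # trapezoidal area over (1 - specificity, sensitivity)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc_trap <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) best <- best[which.max(sens[best])]  # favour sensitivity
  thresholds <- if (direction == "higher") thr_internal else -thr_internal

  structure(list(
    name = name, direction = direction,
    curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                           specificity = spec, youden_j = j),
    auc = auc_trap, auc_rank = auc_rank,
    optimal_threshold = thresholds[best],
    optimal = tibble::tibble(threshold = thresholds[best],
                             sensitivity = sens[best],
                             specificity = spec[best], youden_j = j[best]),
    n_pos = n_pos, n_neg = n_neg
  ), class = "lms_roc")
}

#' @export
print.lms_roc <- function(x, ...) {
  cat(sprintf(
    "<lms_roc> %s (%s-is-LMS): AUC = %.3f, cut-off = %.4g (sens %.3f, spec %.3f)\n",
    x$name, x$direction, x$auc, x$optimal_threshold,
    x$optimal$sensitivity, x$optimal$specificity))
  invisible(x)
}

#' Area under an ROC curve
#'
#' @param roc an `lms_roc`.
#' @param method `"trapezoid"` or `"rank"` (Mann-Whitney with ties
#'   counted one half); the two agree to numerical precision.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc, method = c("trapezoid", "rank")) {
  method <- match.arg(method)
  if (method == "trapezoid") roc$auc else roc$auc_rank
}

#' Youden-optimal threshold of an ROC curve
#'
#' The threshold maximising `J = sensitivity + specificity - 1`, ties
#' broken toward higher sensitivity (false negatives being the greater
#' clinical concern in supply screening).
#'
#' @param roc an `lms_roc`.
#' @return the optimal threshold (scalar, on the original score scale).
#' @export
youden_optimal <- function(roc) roc$optimal_threshold

#' Sensitivity, specificity and Youden's J at a fixed threshold
#'
#' Exact integer confusion-count bookkeeping at a given cut: with
#' `direction = "lower"` a dyad is called positive when `score <
#' threshold` (e.g. milk production below 600 mL/24 h), with `"higher"`
#' when `score > threshold`.
#'
#' @inheritParams roc_curve
#' @param threshold the cut value.
#' @return one-row tibble: threshold, tp, fn, tn, fp, sensitivity,
#'   specificity, youden_j.
#' @export
metrics_at <- function(score, label, threshold,
                       direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  called <- if (direction == "higher") score > threshold else score < threshold
  tp <- sum(called & label); fn <- sum(!called & label)
  fp <- sum(called & !label); tn <- sum(!called & !label)
  tibble::tibble(threshold = threshold, tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 youden_j = tp / (tp + fn) + tn / (tn + fp) - 1)
}

#' Compare two diagnostic thresholds for the same predictor
#'
#' Evaluates both cuts (e.g. the legacy 600 mL/24 h milk-production
#' threshold against a newly derived one) and their metric differences.
#'
#' @inheritParams metrics_at
#' @param threshold_old,threshold_new the two cuts.
#' @return tibble with one row per threshold plus a `delta` row
#'   (new minus old).
#' @export
threshold_comparison <- function(score, label, threshold_old, threshold_new,
                                 direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  old <- metrics_at(score, label, threshold_old, direction)
  new <- metrics_at(score, label, threshold_new, direction)
  delta <- new[c("sensitivity", "specificity", "youden_j")] -
    old[c("sensitivity", "specificity", "youden_j")]
  dplyr::bind_rows(
    dplyr::mutate(old, which = "old", .before = 1),
    dplyr::mutate(new, which = "new", .before = 1),
    dplyr::bind_cols(tibble::tibble(which = "delta",
                                    threshold = threshold_new - threshold_old,
                                    tp = NA_integer_, fn = NA_integer_,
                                    tn = NA_integer_, fp = NA_integer_),
                     delta)
  )
}

#' ROC panel over the standard LMS predictor set
#'
#' Five curves: 24 h milk production and infant breast-milk intake on
#' all dyads (lower-is-LMS); average daily weight gain on all dyads
#' (lower-is-LMS); formula intake and formula-to-growth ratio restricted
#' to partially breastfeeding dyads (higher-is-LMS). Subgroup curves
#' below `min_n` usable dyads are flagged low-n; a curve that cannot be
#' built (e.g. no formula users) is reported with the reason and no
#' metrics.
#'
#' @param data per-dyad tibble with the derived measures and a `group`
#'   column ("NMS"/"LMS", e.g. from [assign_profiles()]).
#' @param min_n minimum subgroup size before a curve is flagged.
#' @return tibble: predictor, n, n_pos, direction, auc, cutoff,
#'   sensitivity, specificity, youden_j, low_n, note; the `lms_roc`
#'   objects ride along in a `roc` list-column.
#' @export
predictor_panel <- function(data, min_n = 20) {
  if (!"group" %in% names(data)) abort("data needs a 'group' column (NMS/LMS)")
  lms <- data$group == "LMS"
  partial <- !is.na(data$formula_intake_24h) & data$formula_intake_24h > 0
  spec_tbl <- tibble::tibble(
    predictor = c("mp_24h", "breastmilk_intake_24h", "avg_daily_gain",
                  "formula_intake_24h", "formula_to_growth"),
    direction = c("lower", "lower", "lower", "higher", "higher"),
    subset = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  rows <- purrr::pmap(spec_tbl, function(predictor, direction, subset) {
    use <- if (subset) partial else rep(TRUE, nrow(data))
    sc <- data[[predictor]][use]
    lb <- lms[use]
    ok <- !is.na(sc) & !is.na(lb)
    note <- NA_character_
    roc <- NULL
    if (sum(ok & lb) == 0 || sum(ok & !lb) == 0) {
      note <- "one class absent; curve not built"
    } else {
      roc <- roc_curve(sc[ok], lb[ok], direction = direction,
                       name = predictor)
    }
    tibble::tibble(
      predictor = predictor, n = sum(ok), n_pos = sum(ok & lb),
      direction = direction,
      auc = if (is.null(roc)) NA_real_ else roc$auc,
      cutoff = if (is.null(roc)) NA_real_ else roc$optimal_threshold,
      sensitivity = if (is.null(roc)) NA_real_ else roc$optimal$sensitivity,
      specificity = if (is.null(roc)) NA_real_ else roc$optimal$specificity,
      youden_j = if (is.null(roc)) NA_real_ else roc$optimal$youden_j,
      low_n = sum(ok) < min_n, note = note,
      roc = list(roc)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy-roc
#' @export
tidy.lms_roc <- function(x, ...) x$curve

#' Tidiers and plot for ROC objects
#'
#' `tidy()` returns the threshold grid; `glance()` the headline metrics.
#'
#' @param x an `lms_roc`.
#' @param ... unused.
#' @name tidy-roc
#' @export
glance.lms_roc <- function(x, ...) {
  tibble::tibble(predictor = x$name, direction = x$direction, auc = x$auc,
                 optimal_threshold = x$optimal_threshold,
                 sensitivity = x$optimal$sensitivity,
                 specificity = x$optimal$specificity,
                 youden_j = x$optimal$youden_j,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.lms_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point",
                      x = 1 - object$optimal$specificity,
                      y = object$optimal$sensitivity, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (AUC = %.3f)", object$name, object$auc),
                  x = "1 - specificity", y = "sensitivity")
}
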