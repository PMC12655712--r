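#' Percentage with one-decimal half-up rounding
#'
#' `round(100 * count / denominator, 1)` with half-up (not banker's)
#' rounding, the convention of printed clinical tables. Internal
#' computations elsewhere keep full precision; this is for reporting.
#'
#' @param count numerator.
#' @param denominator positive denominator.
#' @return percentage rounded to one decimal.
#' @examples
#' percent(284, 460)  # 61.7
#' percent(31, 47)    # 66.0
#' @export
percent <- function(count, denominator) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  round_half_up(100 * count / denominator, 1)
}

#' Descriptive summary of one cohort variable
#'
#' Continuous variables get mean, SD and range; logical/categorical
#' variables get count and percentage. Percentages use the
#' available-data denominator; the missing count uses the total cohort
#' denominator, matching clinical-table convention.
#'
#' @param data cohort tibble.
#' @param variable column name.
#' @return one-row tibble (continuous: mean/sd/min/max; categorical:
#'   count/pct per level collapsed into `value`) with `n_available`,
#'   `n_missing`, `pct_missing`.
#' @export
describe <- function(data, variable) {
  if (!variable %in% names(data)) abort(sprintf("unknown variable '%s'", variable))
  x <- data[[variable]]
  n_total <- length(x)
  n_missing <- sum(is.na(x))
  n_avail <- n_total - n_missing
  base <- tibble::tibble(variable = variable, n_available = n_avail,
                         n_missing = n_missing,
                         pct_missing = percent(n_missing, n_total))
  if (n_avail == 0) {
    return(dplyr::mutate(base, type = "empty", value = NA_character_))
  }
  if (is.numeric(x)) {
    xs <- x[!is.na(x)]
    dplyr::mutate(base, type = "continuous",
                  mean = mean(xs), sd = sd(xs), min = min(xs), max = max(xs),
                  value = sprintf("%.1f ± %.1f (%.1f–%.1f)",
                                  mean(xs), sd(xs), min(xs), max(xs)))
  } else {
    if (is.logical(x)) {
      cnt <- sum(x, na.rm = TRUE)
      dplyr::mutate(base, type = "categorical", count = cnt,
                    pct = percent(cnt, n_avail),
                    value = sprintf("%d (%.1f%%)", cnt, percent(cnt, n_avail)))
    } else {
      tab <- sort(table(x), decreasing = TRUE)
      dplyr::mutate(base, type = "categorical",
                    count = as.integer(tab[1]),
                    pct = percent(as.integer(tab[1]), n_avail),
                    value = paste(sprintf("%s: %d (%.1f%%)", names(tab),
                                          as.integer(tab),
                                          percent(as.integer(tab), n_avail)),
                                  collapse = "; "))
    }
  }
}

#' Cohort characteristics table
#'
#' Runs [describe()] over a set of variables, producing a participant-
#' characteristics table in long form.
#'
#' @param data cohort tibble.
#' @param variables column names (default: every column except dyad_id).
#' @return tibble with one row per variable.
#' @export
describe_cohort <- function(data, variables = setdiff(names(data), "dyad_id")) {
  purrr::map_dfr(variables, function(v) describe(data, v))
}

#' Pairwise Wilcoxon rank-sum tests across groups
#'
#' Compares a continuous variable between every pair of groups with the
#' rank-sum test: the exact null distribution when the combined sample
#' is small (<= `exact_n`) and has no ties, the tie-corrected normal
#' approximation otherwise. Empty groups are skipped with a marker.
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 non-empty groups expected).
#' @param exact_n combined-size bound for the exact distribution.
#' @return tibble: group_i, group_j, n_i, n_j, statistic, p_value, method.
#' @export
pairwise_wilcoxon <- function(values, groups, exact_n = 20) {
  keep <- !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  lv <- levels(groups)
  if (length(lv) < 2) abort("need at least 2 groups")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    xi <- values[groups == pr[1] & !is.na(values)]
    xj <- values[groups == pr[2] & !is.na(values)]
    if (!length(xi) || !length(xj)) {
      return(tibble::tibble(group_i = pr[1], group_j = pr[2],
                            n_i = length(xi), n_j = length(xj),
                            statistic = NA_real_, p_value = NA_real_,
                            method = "skipped: empty group"))
    }
    use_exact <- (length(xi) + length(xj)) <= exact_n &&
      !any(duplicated(c(xi, xj)))
    wt <- suppressWarnings(
      wilcox.test(xi, xj, exact = use_exact, correct = !use_exact)
    )
    tibble::tibble(group_i = pr[1], group_j = pr[2],
                   n_i = length(xi), n_j = length(xj),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = if (use_exact) "exact" else "normal approximation")
  })
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Hypergeometric enumeration with the point-probability (minimum-
#' likelihood) two-sided rule: the p-value sums every table, with the
#' observed margins, whose probability does not exceed the observed
#' table's. A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(abs(tab - round(tab)) > 1e-8)) {
    abort("tab must be a 2 x 2 matrix of non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Risk-factor prevalence by milk-supply class
#'
#' A class-by-factor prevalence report: per class, the count and
#' percentage of dyads with each risk factor, the class with the highest
#' prevalence marked, and the matrix of pairwise Fisher's exact tests.
#' Percentages use the class sample size as denominator by default
#' (printed-table convention); `denominator = "available"` restricts to
#' dyads with non-missing data on the factor.
#'
#' @param data tibble with a class column and logical risk-factor columns.
#' @param class_col name of the class column.
#' @param factors character vector of risk-factor columns.
#' @param denominator `"class_size"` or `"available"`.
#' @param alpha significance level for the pairwise matrix.
#' @return list with `prevalence` (class x factor long tibble) and
#'   `pairwise` (factor, class_i, class_j, p_value, significant).
#' @export
class_prevalence_table <- function(data, class_col = "class",
                                   factors = RISK_FACTORS,
                                   denominator = c("class_size", "available"),
                                   alpha = 0.05) {
  denominator <- match.arg(denominator)
  cls <- factor(data[[class_col]])
  lv <- levels(cls)
  prevalence <- purrr::map_dfr(factors, function(f) {
    x <- data[[f]]
    rows <- purrr::map_dfr(lv, function(cl) {
      in_cl <- cls == cl
      denom <- if (denominator == "class_size") sum(in_cl) else
        sum(in_cl & !is.na(x))
      cnt <- sum(x & in_cl, na.rm = TRUE)
      tibble::tibble(factor = f, class = cl, n_class = sum(in_cl),
                     count = cnt,
                     pct = if (denom > 0) percent(cnt, denom) else NA_real_)
    })
    dplyr::mutate(rows, highest = .data$pct == max(.data$pct, na.rm = TRUE))
  })
  pairwise <- purrr::map_dfr(factors, function(f) {
    x <- data[[f]]
    purrr::map_dfr(utils::combn(lv, 2, simplify = FALSE), function(pr) {
      i <- cls == pr[1] & !is.na(x)
      j <- cls == pr[2] & !is.na(x)
      tab <- matrix(c(sum(x[i]), sum(!x[i]), sum(x[j]), sum(!x[j])), 2, 2)
      p <- if (any(colSums(tab) == 0)) NA_real_ else fisher_exact(tab)
      tibble::tibble(factor = f, class_i = pr[1], class_j = pr[2],
                     p_value = p, significant = !is.na(p) & p < alpha)
    })
  })
  list(prevalence = prevalence, pairwise = pairwise)
}
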