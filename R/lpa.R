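#' Indicators used for milk-supply profiling
#' @export
LPA_INDICATORS <- c("mp_24h", "total_intake_24h", "formula_intake_24h",
                    "waz_current", "delta_waz")

#' Prepare the indicator matrix for latent profile analysis
#'
#' Takes complete-case rows on the chosen indicators, square-root
#' transforms columns whose absolute sample skewness exceeds
#' `skew_threshold` (shifting to non-negative support first if needed),
#' then z-standardises every column. Transform flags and the
#' standardisation constants are recorded so class means can be mapped
#' back to the measurement scale.
#'
#' @param data per-dyad measures tibble (e.g. from
#'   [derive_dyad_measures()]); needs a `dyad_id` column.
#' @param indicators character vector of indicator columns.
#' @param skew_threshold absolute skewness above which a column is
#'   square-root transformed (default 1).
#' @return object of class `indicator_matrix`: list with the transformed
#'   standardised matrix `x`, the untransformed matrix `raw`, the
#'   complete-case `data` rows, and a `transform` tibble (indicator,
#'   sqrt flag, shift, centre, scale).
#' @export
prepare_indicators <- function(data, indicators = LPA_INDICATORS,
                               skew_threshold = 1) {
  missing_cols <- setdiff(indicators, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing indicator column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[indicators])
  data <- data[keep, , drop = FALSE]
  raw <- as.matrix(data[indicators])
  n <- nrow(raw)
  if (n < 2L) abort("need at least 2 complete-case rows")

  tr <- purrr::map_dfr(indicators, function(v) {
    x <- raw[, v]
    if (sd(x) == 0) {
      abort(sprintf("indicator '%s' has zero variance", v))
    }
    sk <- sample_skewness(x)
    use_sqrt <- abs(sk) > skew_threshold
    shift <- if (use_sqrt && min(x) < 0) -min(x) else 0
    y <- if (use_sqrt) sqrt(x + shift) else x
    tibble::tibble(indicator = v, skewness = sk, sqrt = use_sqrt,
                   shift = shift, centre = mean(y), scale = sd(y))
  })
  x <- vapply(seq_along(indicators), function(j) {
    v <- raw[, j]
    if (tr$sqrt[j]) v <- sqrt(v + tr$shift[j])
    (v - tr$centre[j]) / tr$scale[j]
  }, numeric(n))
  colnames(x) <- indicators
  structure(list(x = x, raw = raw, data = data, transform = tr),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix> %d x %d (sqrt: %s)\n", nrow(x$x), ncol(x$x),
              paste(x$transform$indicator[x$transform$sqrt],
                    collapse = ", ")))
  invisible(x)
}

as_indicator_x <- function(x) {
  if (inherits(x, "indicator_matrix")) x$x else as.matrix(x)
}

# k-means++ seeding: spread initial centres, then hard-assign.
kmeanspp_assign <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  dist2 <- vapply(seq_len(k), function(j) {
    rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
  }, numeric(n))
  max.col(-dist2, ties.method = "first")
}

em_log_dens <- function(x, prop, mu, sigma2, x2 = NULL) {
  # sigma2: d-vector (equal) or k x d matrix (varying)
  n <- nrow(x); k <- nrow(mu)
  if (is.matrix(sigma2)) {
    # (x - mu)^2 / (2 s2) expanded into three matrix products
    if (is.null(x2)) x2 <- x^2
    inv2 <- 1 / (2 * sigma2)                      # k x d
    const <- log(prop) - 0.5 * rowSums(log(2 * pi * sigma2)) -
      rowSums(mu^2 * inv2)
    x %*% t(2 * mu * inv2) - x2 %*% t(inv2) +
      matrix(const, n, k, byrow = TRUE)
  } else {
    inv2 <- 1 / (2 * sigma2)
    a <- drop(x^2 %*% inv2)
    b <- x %*% t(mu / matrix(sigma2, k, length(sigma2), byrow = TRUE))
    ck <- rowSums(mu^2 * matrix(inv2, k, length(sigma2), byrow = TRUE))
    const <- -0.5 * sum(log(2 * pi * sigma2))
    sweep(b, 1, a) + matrix(log(prop) - ck + const, n, k, byrow = TRUE)
  }
}

em_once <- function(x, k, assign0, max_iter, tol, var_floor, variance,
                    params = NULL) {
  n <- nrow(x); d <- ncol(x)
  x2 <- x^2
  if (!is.null(params)) {
    # warm start: E-step responsibilities under the supplied parameters
    ld <- em_log_dens(x, params$prop, params$mu, params$sigma2, x2 = x2)
    r <- exp(ld - row_logsumexp(ld))
  } else {
    r <- matrix(0, n, k)
    r[cbind(seq_len(n), assign0)] <- 1
  }
  ll_prev <- -Inf
  colsum_x2 <- colSums(x2)
  for (iter in seq_len(max_iter)) {
    nk <- colSums(r)
    if (any(nk < 1e-6)) return(NULL)  # collapsed class
    prop <- nk / n
    s <- crossprod(r, x)
    mu <- s / nk
    if (variance == "equal") {
      sigma2 <- pmax((colsum_x2 - colSums(mu * s)) / n, var_floor)
    } else {
      sigma2 <- pmax((crossprod(r, x2) - nk * mu^2) / nk, var_floor)
    }
    ld <- em_log_dens(x, prop, mu, sigma2, x2 = x2)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    if (ll < ll_prev - 1e-6) {
      abort("EM log-likelihood decreased; this indicates a numerical fault")
    }
    r <- exp(ld - lse)
    if (ll - ll_prev < tol) {
      return(list(prop = prop, mu = mu, sigma2 = sigma2, posterior = r,
                  loglik = ll, iter = iter, converged = TRUE))
    }
    ll_prev <- ll
  }
  list(prop = prop, mu = mu, sigma2 = sigma2, posterior = r, loglik = ll_prev,
       iter = max_iter, converged = FALSE)
}

#' Fit a K-class latent profile model
#'
#' Gaussian finite mixture on standardised indicators, fitted by EM with
#' k-means++ style initialisation and random restarts; the best restart
#' by final log-likelihood is kept. Covariances are zero (the profile
#' model); the default lets the diagonal variances vary by class, which
#' a zero-inflated indicator such as formula intake requires -- under a
#' shared variance the many exact zeros collapse the pooled variance and
#' the likelihood rewards splitting the supplementing class instead of
#' separating real profiles. `variance = "equal"` gives the classical
#' equal-variance profile model. The log-likelihood is asserted
#' non-decreasing at every EM iteration.
#'
#' @param x an [prepare_indicators()] object or a numeric matrix.
#' @param k number of classes (>= 1).
#' @param n_restarts random restarts (default 20).
#' @param max_iter EM iteration cap.
#' @param tol absolute log-likelihood improvement declaring convergence.
#' @param var_floor variance floor preventing degeneracy.
#' @param variance `"equal"` (shared diagonal) or `"varying"`.
#' @param seed optional seed.
#' @return object of class `lpa_model` with mixing proportions, class
#'   means, variances, posterior matrix, log-likelihood, BIC,
#'   classification entropy, per-class average posteriors, modal
#'   assignment and smallest-class share.
#' @export
fit_lpa <- function(x, k, n_restarts = 20, max_iter = 1000, tol = 1e-8,
                    var_floor = 0.05, variance = c("varying", "equal"),
                    seed = NULL) {
  variance <- match.arg(variance)
  prep <- if (inherits(x, "indicator_matrix")) x else NULL
  x <- as_indicator_x(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x); d <- ncol(x)
  if (k < 1) abort("k must be >= 1")
  if (n <= 5 * k) abort("need n > 5k observations")
  if (!is.null(seed)) set.seed(seed)

  if (k == 1L) {
    mu <- matrix(colMeans(x), 1, d, dimnames = list(NULL, colnames(x)))
    sigma2 <- pmax(colMeans((x - matrix(mu, n, d, byrow = TRUE))^2), var_floor)
    if (variance == "varying") sigma2 <- matrix(sigma2, 1, d)
    ll <- sum(em_log_dens(x, 1, mu, if (is.matrix(sigma2)) sigma2 else sigma2))
    fit <- list(prop = 1, mu = mu, sigma2 = sigma2,
                posterior = matrix(1, n, 1), loglik = ll, iter = 0L,
                converged = TRUE)
  } else {
    fit <- NULL
    failures <- 0L
    for (r in seq_len(n_restarts)) {
      f <- tryCatch(
        em_once(x, k, kmeanspp_assign(x, k), max_iter, tol, var_floor,
                variance),
        error = function(e) NULL
      )
      if (is.null(f)) { failures <- failures + 1L; next }
      if (is.null(fit) || f$loglik > fit$loglik) fit <- f
    }
    if (is.null(fit)) {
      abort(sprintf(
        "all %d EM restarts collapsed (empty class) for k = %d", n_restarts, k
      ))
    }
  }

  n_par <- if (variance == "equal") (k - 1) + k * d + d else
    (k - 1) + k * d + k * d
  assignment <- max.col(fit$posterior, ties.method = "first")
  counts <- tabulate(assignment, nbins = k)
  avg_post <- vapply(seq_len(k), function(j) {
    if (counts[j] == 0) NA_real_ else mean(fit$posterior[assignment == j, j])
  }, numeric(1))
  colnames(fit$mu) <- colnames(x)
  structure(list(
    k = k, n = n, d = d, variance = variance,
    prop = fit$prop, mean = fit$mu, sigma2 = fit$sigma2,
    loglik = fit$loglik, n_par = n_par,
    bic = -2 * fit$loglik + n_par * log(n),
    posterior = fit$posterior,
    entropy = classification_entropy(fit$posterior),
    avg_posterior = avg_post,
    assignment = assignment,
    class_counts = counts,
    smallest_share = min(counts) / n,
    converged = fit$converged, iterations = fit$iter,
    prep = prep
  ), class = "lpa_model")
}

#' @export
print.lpa_model <- function(x, ...) {
  cat(sprintf(
    "<lpa_model> k = %d, n = %d, loglik = %.2f, BIC = %.1f, entropy = %.3f\n",
    x$k, x$n, x$loglik, x$bic, x$entropy))
  invisible(x)
}

#' @export
logLik.lpa_model <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' Classification entropy of a posterior matrix
#'
#' `1 - sum(-p * log p) / (n * log k)`; 1 means perfectly separated
#' classes, 0 means uniform posteriors. Defined as 1 for a single class.
#'
#' @param p n x k posterior matrix (rows sum to 1).
#' @return value in `[0, 1]`.
#' @export
classification_entropy <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) == 1L) return(1)
  terms <- ifelse(p > 0, -p * log(p), 0)
  1 - sum(terms) / (nrow(p) * log(ncol(p)))
}

#' Simulate data from a fitted latent profile model
#'
#' @param model an `lpa_model`.
#' @param n number of rows.
#' @param seed optional seed.
#' @return numeric matrix.
#' @export
simulate_lpa <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(model$k, n, replace = TRUE, prob = model$prop)
  s2 <- if (is.matrix(model$sigma2)) model$sigma2 else
    matrix(model$sigma2, model$k, model$d, byrow = TRUE)
  mu <- model$mean[z, , drop = FALSE]
  sdm <- sqrt(s2[z, , drop = FALSE])
  mu + matrix(rnorm(n * model$d), n, model$d) * sdm
}

#' Bootstrap likelihood ratio test for K versus K - 1 classes
#'
#' Parametric bootstrap: simulates `n_boot` datasets from the fitted
#' (K-1)-class model, refits both models on each, and computes
#' `p = (1 + #(boot LRT >= observed LRT)) / (n_successes + 1)`. Bootstrap
#' refits that fail (all restarts collapsed) are logged and excluded; at
#' least `min_success` of `n_boot` must succeed.
#'
#' @param x indicator matrix or `indicator_matrix` object.
#' @param k number of classes under the alternative (>= 2).
#' @param n_boot bootstrap replicates (default 99).
#' @param seed optional seed, threaded to every bootstrap fit.
#' @param model0,model1 optionally, prefitted (k-1)- and k-class models.
#' @param boot_restarts,boot_tol,boot_max_iter EM settings for the
#'   bootstrap refits (cheaper than the observed-data fits).
#' @param min_success minimum fraction of successful bootstrap refits.
#' @param variance variance structure, see [fit_lpa()].
#' @param var_floor variance floor for the bootstrap refits.
#' @return list with `statistic` (observed LRT), `p_value`, `n_boot`,
#'   `n_success` and the vector of bootstrap statistics.
#' @export
blrt <- function(x, k, n_boot = 99, seed = NULL, model0 = NULL, model1 = NULL,
                 boot_restarts = 2, boot_tol = 1e-6, boot_max_iter = 300,
                 min_success = 0.8, variance = "varying", var_floor = 0.05) {
  if (k < 2) abort("blrt requires k >= 2")
  xm <- as_indicator_x(x)
  if (!is.null(seed)) set.seed(seed)
  model0 <- model0 %||% fit_lpa(xm, k - 1, variance = variance)
  model1 <- model1 %||% fit_lpa(xm, k, variance = variance)
  obs <- max(0, 2 * (model1$loglik - model0$loglik))

  # each bootstrap refit gets a warm start at the observed-data estimates
  # (preventing under-fitted null models from inflating the statistic)
  # plus cheap random restarts
  warm0 <- list(prop = model0$prop, mu = model0$mean, sigma2 = model0$sigma2)
  warm1 <- list(prop = model1$prop, mu = model1$mean, sigma2 = model1$sigma2)
  boot_fit <- function(xb, kk, warm) {
    best <- tryCatch(
      em_once(xb, kk, NULL, boot_max_iter, boot_tol, var_floor, variance,
              params = warm),
      error = function(e) NULL)
    for (r in seq_len(boot_restarts)) {
      f <- tryCatch(
        em_once(xb, kk, kmeanspp_assign(xb, kk), boot_max_iter, boot_tol,
                var_floor, variance),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (is.null(best)) NA_real_ else best$loglik
  }
  stats <- vapply(seq_len(n_boot), function(b) {
    xb <- simulate_lpa(model0, model0$n)
    l0 <- boot_fit(xb, k - 1, warm0)
    l1 <- boot_fit(xb, k, warm1)
    if (is.na(l0) || is.na(l1)) NA_real_ else max(0, 2 * (l1 - l0))
  }, numeric(1))
  ok <- !is.na(stats)
  if (mean(ok) < min_success) {
    abort(sprintf("only %d/%d bootstrap refits succeeded", sum(ok), n_boot))
  }
  p <- (1 + sum(stats[ok] >= obs - 1e-12)) / (sum(ok) + 1)
  list(statistic = obs, p_value = p, n_boot = n_boot, n_success = sum(ok),
       boot_stats = stats[ok])
}

#' Fit and select the number of latent profiles
#'
#' Fits models over `k_range` and evaluates the five selection criteria:
#' (1) BIC lower than at K-1; (2) classification entropy at least
#' `entropy`; (3) a significant bootstrap likelihood ratio test of K vs
#' K-1; (4) average posterior membership probability at least
#' `avg_posterior` in every class; (5) smallest class holding more than
#' `min_share` of individuals. The selected model is the *largest* K
#' passing all criteria (K = 1 passes trivially). A full audit trail is
#' retained.
#'
#' @inheritParams blrt
#' @param k_range contiguous integer range starting at 1.
#' @param criteria named list of thresholds: `entropy` (0.8),
#'   `avg_posterior` (0.5), `min_share` (0.05), `alpha` (0.05).
#' @param n_restarts restarts for the observed-data fits.
#' @return object of class `lpa_selection`: fitted `models`, a per-K
#'   `report` tibble, `selected_k` (NA if no K passes) and the criteria.
#' @export
select_model <- function(x, k_range = 1:5, n_boot = 99, seed = NULL,
                         criteria = list(entropy = 0.8, avg_posterior = 0.5,
                                         min_share = 0.05, alpha = 0.05),
                         n_restarts = 20, boot_restarts = 2,
                         variance = "varying") {
  if (k_range[1] != 1L || any(diff(k_range) != 1L)) {
    abort("k_range must be contiguous and start at 1")
  }
  prep <- if (inherits(x, "indicator_matrix")) x else NULL
  xm <- as_indicator_x(x)
  if (!is.null(seed)) set.seed(seed)
  models <- lapply(k_range, function(k) {
    fit_lpa(xm, k, n_restarts = n_restarts, variance = variance)
  })
  names(models) <- paste0("k", k_range)

  blrt_p <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)[-1]) {
    blrt_p[i] <- blrt(xm, k_range[i], n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else
                        derive_seed(seed, k_range[i]),
                      model0 = models[[i - 1]], model1 = models[[i]],
                      boot_restarts = boot_restarts,
                      variance = variance)$p_value
  }

  report <- tibble::tibble(
    k = k_range,
    loglik = vapply(models, function(m) m$loglik, numeric(1)),
    bic = vapply(models, function(m) m$bic, numeric(1)),
    entropy = vapply(models, function(m) m$entropy, numeric(1)),
    min_avg_posterior = vapply(models, function(m) min(m$avg_posterior),
                               numeric(1)),
    smallest_share = vapply(models, function(m) m$smallest_share, numeric(1)),
    blrt_p = blrt_p
  )
  report <- report |>
    dplyr::mutate(
      bic_improves = .data$k == 1 | .data$bic < dplyr::lag(.data$bic),
      entropy_ok = .data$entropy >= criteria$entropy,
      posterior_ok = .data$min_avg_posterior >= criteria$avg_posterior,
      share_ok = .data$smallest_share > criteria$min_share,
      blrt_ok = .data$k == 1 | (!is.na(.data$blrt_p) &
                                  .data$blrt_p < criteria$alpha),
      passes = .data$bic_improves & .data$entropy_ok & .data$posterior_ok &
        .data$share_ok & .data$blrt_ok
    )
  selected <- if (any(report$passes)) {
    as.integer(max(report$k[report$passes]))
  } else {
    NA_integer_
  }
  structure(list(models = models, report = report, selected_k = selected,
                 criteria = criteria, prep = prep),
            class = "lpa_selection")
}

#' @export
print.lpa_selection <- function(x, ...) {
  cat(sprintf("<lpa_selection> selected k = %s\n",
              ifelse(is.na(x$selected_k), "none", x$selected_k)))
  print(x$report)
  invisible(x)
}

#' Class means on the original measurement scale
#'
#' Posterior-weighted means of the untransformed indicator columns, one
#' row per latent class.
#'
#' @param model an `lpa_model`.
#' @param prep the `indicator_matrix` the model was fitted to (taken from
#'   the model if it was fitted directly on one).
#' @return tibble: class, n, then one column per indicator.
#' @export
class_profiles <- function(model, prep = model$prep) {
  if (is.null(prep)) abort("supply the indicator_matrix used for fitting")
  r <- model$posterior
  nk <- colSums(r)
  mu <- t(r) %*% prep$raw / nk
  dplyr::bind_cols(
    tibble::tibble(class = seq_len(model$k), n = model$class_counts),
    tibble::as_tibble(mu)
  )
}

# Canonical clinical labelling from original-scale class means:
# highest-MP class with production exceeding intake -> oversupply;
# of the rest, lowest MP -> severe low supply; then lowest WAZ ->
# slow growth; remainder -> adequate.
label_classes <- function(profiles) {
  k <- nrow(profiles)
  lab <- rep(NA_character_, k)
  left <- seq_len(k)
  if (k >= 2) {
    top <- left[which.max(profiles$mp_24h[left])]
    if (profiles$mp_24h[top] > profiles$total_intake_24h[top]) {
      lab[top] <- "oversupply"
      left <- setdiff(left, top)
    }
    if (length(left) >= 2) {
      sev <- left[which.min(profiles$mp_24h[left])]
      lab[sev] <- "severe_lms"
      left <- setdiff(left, sev)
    }
    if (length(left) >= 2) {
      slow <- left[which.min(profiles$waz_current[left])]
      lab[slow] <- "slow_growth"
      left <- setdiff(left, slow)
    }
  }
  lab[left] <- "adequate"
  lab
}

CANONICAL_ORDER <- c(adequate = 1L, oversupply = 2L, severe_lms = 3L,
                     slow_growth = 4L)

#' Assign dyads to canonical milk-supply classes and NMS/LMS groups
#'
#' Modal posterior assignment (ties to the lower canonical index, with a
#' message) followed by canonical relabelling of the fitted classes --
#' ordering by mean milk production and applying clinical rules so class
#' identities are stable across seeds: adequate (1), oversupply (2),
#' severe low supply (3), slow growth (4). Adequate and oversupply form
#' the normal-milk-supply (NMS) group; severe low supply and slow growth
#' the low-milk-supply (LMS) group.
#'
#' @inheritParams class_profiles
#' @return tibble: dyad_id, class (canonical), label, posterior (modal
#'   class posterior), group ("NMS"/"LMS"); the canonical class summary
#'   is attached as attribute `"classes"`.
#' @export
assign_profiles <- function(model, prep = model$prep) {
  if (is.null(prep)) abort("supply the indicator_matrix used for fitting")
  prof <- class_profiles(model, prep)
  lab <- label_classes(prof)
  canon <- unname(CANONICAL_ORDER[lab])
  # several adequate classes arise when the top-production class shows no
  # expression surplus (no oversupply) or when k > 4; the highest-production
  # adequate class keeps index 1 and the extras get indices beyond 4
  adequate <- which(lab == "adequate")
  if (length(adequate) > 1) {
    ord <- adequate[order(prof$mp_24h[adequate], decreasing = TRUE)]
    canon[ord[1]] <- 1L
    canon[ord[-1]] <- 4L + seq_along(ord[-1])
  }
  if (anyDuplicated(canon) || anyNA(canon)) {
    abort("ambiguous canonical class mapping; inspect class_profiles()")
  }
  post_max <- apply(model$posterior, 1, max)
  raw_assign <- max.col(model$posterior, ties.method = "first")
  n_tied <- sum(rowSums(model$posterior >= post_max - 1e-12) > 1)
  if (n_tied > 0) {
    rlang::inform(sprintf(
      "%d dyad(s) had tied posteriors; assigned to the lower canonical index",
      n_tied))
  }
  group <- ifelse(lab %in% c("adequate", "oversupply"), "NMS", "LMS")
  out <- tibble::tibble(
    dyad_id = prep$data$dyad_id,
    class = unname(canon[raw_assign]),
    label = lab[raw_assign],
    posterior = post_max,
    group = group[raw_assign]
  )
  summary_tbl <- dplyr::arrange(
    dplyr::bind_cols(tibble::tibble(canonical = unname(canon), label = lab,
                                    group = group), prof),
    .data$canonical)
  attr(out, "classes") <- summary_tbl
  out
}

#' @rdname tidy-lpa
#' @export
tidy.lpa_model <- function(x, ...) {
  mu <- tibble::as_tibble(x$mean)
  dplyr::bind_cols(tibble::tibble(class = seq_len(x$k),
                                  proportion = as.numeric(x$prop)), mu) |>
    tidyr::pivot_longer(-c("class", "proportion"), names_to = "indicator",
                        values_to = "mean")
}

#' Tidiers for latent profile objects
#'
#' `tidy()` returns class-by-indicator means (standardised scale);
#' `glance()` one row of model-level fit statistics.
#'
#' @param x an `lpa_model` or `lpa_selection`.
#' @param ... unused.
#' @name tidy-lpa
#' @export
glance.lpa_model <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik, n_par = x$n_par,
                 bic = x$bic, entropy = x$entropy,
                 smallest_share = x$smallest_share,
                 converged = x$converged)
}

#' @rdname tidy-lpa
#' @export
tidy.lpa_selection <- function(x, ...) x$report

#' @rdname tidy-lpa
#' @export
glance.lpa_selection <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 k_max = max(x$report$k),
                 n = x$models[[1]]$n)
}

#' Plot the model-selection trace
#'
#' BIC, entropy and BLRT p-value against the number of classes, with the
#' selected K marked.
#'
#' @param object an `lpa_selection`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lpa_selection <- function(object, ...) {
  long <- object$report |>
    dplyr::select("k", "bic", "entropy", "blrt_p") |>
    tidyr::pivot_longer(-"k", names_to = "criterion")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of classes", y = NULL)
  if (!is.na(object$selected_k)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_k,
                                 linetype = "dashed")
  }
  p
}

#' Plot class profiles
#'
#' Standardised indicator means per latent class.
#'
#' @param object an `lpa_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lpa_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$indicator, y = .data$mean,
                               group = factor(.data$class),
                               colour = factor(.data$class))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "standardised mean", colour = "class")
}
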