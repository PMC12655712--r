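#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood fit of a K-level outcome on a design matrix built
#' from `predictors`, with the first (or given) outcome level as the
#' reference carrying zero coefficients. Newton iterations on the
#' multinomial log-likelihood with step-halving; the Wald covariance
#' comes from the observed information at the optimum. Odds ratios and
#' 95% Wald confidence intervals are reported per non-reference level.
#' A small ridge stabiliser regularises the information matrix; clear
#' separation (diverging coefficients) raises a warning and a stronger
#' ridge fallback, never silent shrinkage.
#'
#' @param data tibble; complete cases on outcome and predictors are used.
#' @param outcome name of the outcome column (coerced to factor).
#' @param predictors character vector of predictor columns.
#' @param reference reference outcome level (default: first factor level).
#' @param ridge stabiliser added to the information matrix diagonal.
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the score (gradient) norm.
#' @return object of class `multinom_fit`.
#' @export
fit_multinomial <- function(data, outcome, predictors, reference = NULL,
                            ridge = 1e-8, max_iter = 100, tol = 1e-6) {
  predictors <- setdiff(predictors, "1")
  vars <- c(outcome, predictors)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  y <- factor(d[[outcome]])
  if (!is.null(reference)) y <- stats::relevel(y, ref = as.character(reference))
  if (nlevels(y) < 2) abort("outcome must have at least 2 observed levels")
  d <- droplevels(d)
  form <- if (length(predictors)) reformulate(predictors) else ~1
  xm <- model.matrix(form, data = d)
  fit <- multinom_newton(xm, y, ridge = ridge, max_iter = max_iter, tol = tol)
  fit$outcome <- outcome
  fit$predictors <- predictors
  fit
}

multinom_newton <- function(xm, y, ridge = 1e-8, max_iter = 100, tol = 1e-6,
                            penalty = 0) {
  n <- nrow(xm); p <- ncol(xm)
  xm0 <- xm
  # standardise non-intercept columns for conditioning; coefficients and
  # covariance are mapped back to the original scale afterwards
  has_int <- colnames(xm)[1] == "(Intercept)"
  ctr <- rep(0, p); scl <- rep(1, p)
  for (j in seq_len(p)) {
    if (has_int && j == 1L) next
    s <- sd(xm[, j])
    if (is.finite(s) && s > 0) {
      ctr[j] <- if (has_int) mean(xm[, j]) else 0
      scl[j] <- s
      xm[, j] <- (xm[, j] - ctr[j]) / s
    }
  }
  lev <- levels(y)
  k <- length(lev)
  km1 <- k - 1L
  yi <- as.integer(y)
  ymat <- matrix(0, n, km1)
  for (j in seq_len(km1)) ymat[, j] <- as.numeric(yi == j + 1L)

  beta <- matrix(0, km1, p)
  loglik_fn <- function(beta) {
    eta <- xm %*% t(beta)
    denom <- row_logsumexp(cbind(0, eta))
    sum(eta[cbind(seq_len(n), yi - 1L)[yi > 1L, , drop = FALSE]]) -
      sum(denom) - 0.5 * penalty * sum(beta^2)
  }
  ll <- loglik_fn(beta)
  converged <- FALSE
  grad_norm <- NA_real_
  for (iter in seq_len(max_iter)) {
    eta <- xm %*% t(beta)
    denom <- row_logsumexp(cbind(0, eta))
    pr <- exp(eta - denom)             # n x (k-1), non-reference probs
    grad <- t(xm) %*% (ymat - pr)      # p x (k-1)
    g <- as.vector(grad) - penalty * as.vector(t(beta))
    grad_norm <- sqrt(sum(g^2))
    if (grad_norm < tol) { converged <- TRUE; break }
    hess <- matrix(0, km1 * p, km1 * p)
    for (a in seq_len(km1)) {
      for (b in a:km1) {
        w <- if (a == b) pr[, a] * (1 - pr[, a]) else -pr[, a] * pr[, b]
        blk <- crossprod(xm, xm * w)
        ia <- (a - 1L) * p + seq_len(p)
        ib <- (b - 1L) * p + seq_len(p)
        hess[ia, ib] <- blk
        if (a != b) hess[ib, ia] <- blk
      }
    }
    diag(hess) <- diag(hess) + ridge + penalty
    step <- solve(hess, g)
    # step-halving keeps the log-likelihood non-decreasing
    lambda <- 1
    repeat {
      beta_new <- beta + t(matrix(step * lambda, p, km1))
      ll_new <- loglik_fn(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + t(matrix(step * lambda, p, km1))
    ll <- loglik_fn(beta)
  }
  if (!converged && grad_norm > sqrt(tol)) {
    if (max(abs(beta)) > 15 && penalty == 0) {
      warn("possible separation: coefficients diverging; refitting with a ridge penalty")
      return(multinom_newton(xm0, y, ridge = ridge, max_iter = max_iter,
                             tol = tol, penalty = 1e-3 * n / 100))
    }
    abort(sprintf("Newton iterations did not converge (gradient norm %.3g)",
                  grad_norm))
  }

  # observed information (no penalty term) for Wald inference
  eta <- xm %*% t(beta)
  denom <- row_logsumexp(cbind(0, eta))
  pr <- exp(eta - denom)
  hess <- matrix(0, km1 * p, km1 * p)
  for (a in seq_len(km1)) {
    for (b in a:km1) {
      w <- if (a == b) pr[, a] * (1 - pr[, a]) else -pr[, a] * pr[, b]
      blk <- crossprod(xm, xm * w)
      ia <- (a - 1L) * p + seq_len(p)
      ib <- (b - 1L) * p + seq_len(p)
      hess[ia, ib] <- blk
      if (a != b) hess[ib, ia] <- blk
    }
  }
  vcov <- tryCatch(solve(hess + diag(ridge, km1 * p)),
                   error = function(e) matrix(NA_real_, km1 * p, km1 * p))
  # map coefficients and covariance back to the original column scale
  amat <- diag(1 / scl)
  if (has_int) amat[1, ] <- amat[1, ] - c(0, ctr[-1] / scl[-1])
  tfull <- matrix(0, km1 * p, km1 * p)
  for (a in seq_len(km1)) {
    ia <- (a - 1L) * p + seq_len(p)
    tfull[ia, ia] <- amat
  }
  beta <- t(apply(beta, 1, function(b) drop(amat %*% b)))
  if (p == 1L) beta <- matrix(beta, km1, 1L)
  vcov <- tfull %*% vcov %*% t(tfull)
  se <- t(matrix(sqrt(pmax(diag(vcov), 0)), p, km1))
  dimnames(beta) <- list(lev[-1], colnames(xm))
  dimnames(se) <- dimnames(beta)

  structure(list(
    coefficients = beta, se = se, vcov = vcov,
    levels = lev, reference = lev[1], terms = colnames(xm),
    loglik = ll, n = n, n_par = km1 * p,
    fitted = cbind(1 - rowSums(pr), pr),
    converged = converged, iterations = iter, grad_norm = grad_norm,
    penalty = penalty
  ), class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("<multinom_fit> %d levels (ref '%s'), %d terms, n = %d, AIC = %.1f\n",
              length(x$levels), x$reference, length(x$terms), x$n, AIC(x)))
  invisible(x)
}

#' @export
logLik.multinom_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' @rdname tidy-multinom
#' @export
tidy.multinom_fit <- function(x, conf_level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  purrr::map_dfr(rownames(x$coefficients), function(lv) {
    b <- x$coefficients[lv, ]
    s <- x$se[lv, ]
    tibble::tibble(
      level = lv, term = x$terms, estimate = unname(b),
      std_error = unname(s),
      or = exp(unname(b)),
      ci_low = exp(unname(b - zq * s)), ci_high = exp(unname(b + zq * s)),
      p_value = 2 * pnorm(-abs(unname(b) / unname(s)))
    )
  })
}

#' Tidiers for multinomial fits
#'
#' `tidy()` gives one row per non-reference level and term with the
#' coefficient, odds ratio, Wald CI and p-value (forest-plot-ready);
#' `glance()` one row of fit statistics.
#'
#' @param x a `multinom_fit`.
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... unused.
#' @name tidy-multinom
#' @export
glance.multinom_fit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, n_par = x$n_par,
                 aic = AIC(x), converged = x$converged,
                 iterations = x$iterations)
}

#' Forest plot of odds ratios
#'
#' @param object a `multinom_fit`.
#' @param ... unused.
#' @return a ggplot (intercept rows omitted, log-scaled OR axis).
#' @export
autoplot.multinom_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL)
}

#' Backward elimination over risk factors by AIC
#'
#' Removes, one at a time, the risk factor whose removal most improves
#' AIC, until no removal improves it. Confounders are locked: they stay
#' in every model and are never candidates for removal.
#'
#' @inheritParams fit_multinomial
#' @param risk_factors candidate predictors subject to elimination.
#' @param confounders predictors locked into every model.
#' @return character vector of retained risk factors.
#' @export
backward_aic <- function(data, outcome, risk_factors, confounders,
                         reference = NULL, ridge = 1e-8) {
  current <- risk_factors
  fit <- fit_multinomial(data, outcome, c(current, confounders),
                         reference = reference, ridge = ridge)
  best_aic <- AIC(fit)
  repeat {
    if (!length(current)) break
    aics <- vapply(current, function(f) {
      preds <- c(setdiff(current, f), confounders)
      if (!length(preds)) preds <- "1"
      tryCatch(AIC(fit_multinomial(data, outcome, preds,
                                   reference = reference, ridge = ridge)),
               error = function(e) Inf)
    }, numeric(1))
    if (min(aics) < best_aic) {
      best_aic <- min(aics)
      current <- setdiff(current, current[which.min(aics)])
    } else break
  }
  current
}

#' Bootstrap stability selection of risk factors
#'
#' Draws `B` bootstrap resamples of the analysis rows (complete cases on
#' outcome, risk factors and confounders), runs the within-resample
#' selector (backward elimination by AIC, confounders locked) on each,
#' and counts how often each risk factor is retained. Factors selected
#' in more than `retention` of the resamples enter the final model,
#' which is fitted on the original data together with all confounders.
#' Resamples missing an outcome level are redrawn (logged, bounded).
#'
#' @inheritParams backward_aic
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param retention selection-frequency threshold (default 0.5,
#'   exceeded strictly).
#' @param max_redraw redraw bound per resample.
#' @return object of class `stability_selection`: `frequencies` tibble
#'   (factor, count, frequency, retained), the `retained` set, the
#'   `final_model`, `B`, and redraw diagnostics.
#' @export
bootstrap_stability <- function(data, outcome, risk_factors, confounders,
                                B = 500, seed = NULL, retention = 0.5,
                                reference = NULL, ridge = 1e-8,
                                max_redraw = 100) {
  if (B < 1) abort("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  vars <- c(outcome, risk_factors, confounders)
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  lev <- unique(d[[outcome]])
  counts <- setNames(integer(length(risk_factors)), risk_factors)
  redraws <- 0L
  for (b in seq_len(B)) {
    tries <- 0L
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      db <- d[idx, , drop = FALSE]
      if (length(unique(db[[outcome]])) == length(lev)) break
      tries <- tries + 1L
      redraws <- redraws + 1L
      if (tries > max_redraw) abort("resample redraw bound exceeded")
    }
    # factors constant in the resample cannot be estimated: not selected
    usable <- risk_factors[vapply(risk_factors, function(f) {
      length(unique(db[[f]])) > 1
    }, logical(1))]
    kept <- if (length(usable)) {
      tryCatch(backward_aic(db, outcome, usable, confounders,
                            reference = reference, ridge = ridge),
               error = function(e) character(0))
    } else character(0)
    counts[kept] <- counts[kept] + 1L
  }
  freq <- tibble::tibble(
    factor = risk_factors, count = as.integer(counts),
    frequency = as.numeric(counts) / B,
    retained = as.numeric(counts) / B > retention
  )
  retained <- freq$factor[freq$retained]
  final <- fit_multinomial(d, outcome, c(retained, confounders),
                           reference = reference, ridge = ridge)
  structure(list(frequencies = freq, retained = retained,
                 final_model = final, B = B, n = n, redraws = redraws,
                 confounders = confounders, retention = retention),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("<stability_selection> B = %d, retained: %s\n", x$B,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  print(x$frequencies)
  invisible(x)
}

#' @rdname tidy-stability
#' @export
tidy.stability_selection <- function(x, ...) x$frequencies

#' Tidiers for stability-selection objects
#'
#' @param x a `stability_selection`.
#' @param ... unused.
#' @name tidy-stability
#' @export
glance.stability_selection <- function(x, ...) {
  tibble::tibble(B = x$B, n = x$n, n_retained = length(x$retained),
                 redraws = x$redraws)
}

#' Four-level composite of two binary risk factors
#'
#' Codes co-occurrence as neither / A only / B only / both, with
#' "neither" as reference; rows missing either flag are `NA`.
#'
#' @param a_flag,b_flag logical vectors.
#' @param labels level names (neither, A only, B only, both).
#' @return factor with four levels.
#' @export
make_composite <- function(a_flag, b_flag,
                           labels = c("neither", "a_only", "b_only", "both")) {
  idx <- 1L + as.integer(a_flag) + 2L * as.integer(b_flag)
  factor(labels[idx], levels = labels)
}

#' Multinomial model with a composite risk factor
#'
#' Builds the four-level composite of two binary factors, then fits the
#' class outcome on the composite's three non-reference levels adjusting
#' for the locked confounders and any other retained predictors (the two
#' source factors are excluded as separate terms). An empty composite
#' level is dropped with a warning and its OR reported as undefined.
#'
#' @inheritParams fit_multinomial
#' @param factor_a,factor_b names of the two binary source columns.
#' @param other_predictors additional retained predictors to adjust for.
#' @return list with the `multinom_fit` (`model`), the composite level
#'   `counts`, and the composite column name.
#' @export
fit_composite_model <- function(data, outcome, factor_a, factor_b,
                                confounders, other_predictors = character(0),
                                reference = NULL, ridge = 1e-8) {
  comp_name <- paste0(factor_a, "_x_", factor_b)
  data[[comp_name]] <- make_composite(data[[factor_a]], data[[factor_b]],
                                      labels = c("neither",
                                                 paste0(factor_a, "_only"),
                                                 paste0(factor_b, "_only"),
                                                 "both"))
  counts <- table(data[[comp_name]], useNA = "no")
  if (any(counts == 0)) {
    warn(sprintf("empty composite level(s): %s; odds ratios undefined there",
                 paste(names(counts)[counts == 0], collapse = ", ")))
    data[[comp_name]] <- droplevels(data[[comp_name]])
  }
  preds <- c(comp_name, setdiff(other_predictors, c(factor_a, factor_b)),
             confounders)
  model <- fit_multinomial(data, outcome, preds, reference = reference,
                           ridge = ridge)
  list(model = model, counts = counts, composite = comp_name)
}
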