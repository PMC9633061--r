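# Signal-detection, psychometric and trial-level statistics for Go/No-go
# data: d-prime with rate clamping, Weibull psychometric fits with a free
# amplitude, model-vs-behavior agreement (R^2 / MAE), likelihood-ratio
# tests on trialwise logistic models, and catch-trial Go-rate comparisons.

#' Summarize Go/No-go counts into clamped hit and false-alarm rates
#'
#' @param hits,n_go hit count and number of Go trials.
#' @param false_alarms,n_nogo FA count and number of No-go trials.
#' @param floor,ceiling rate clamps (defaults 0.01 and 0.99).
#' @return a `rate_summary` with raw counts and clamped `hit_rate`,
#'   `fa_rate`.
#' @export
rate_summary <- function(hits, n_go, false_alarms, n_nogo,
                         floor = 0.01, ceiling = 0.99) {
  if (n_go <= 0 || n_nogo <= 0) stop("both trial counts must be > 0", call. = FALSE)
  if (hits > n_go || false_alarms > n_nogo || hits < 0 || false_alarms < 0) {
    stop("counts inconsistent with trial totals", call. = FALSE)
  }
  clamp <- function(p) pmin(pmax(p, floor), ceiling)
  structure(list(hits = hits, n_go_trials = n_go,
                 false_alarms = false_alarms, n_nogo_trials = n_nogo,
                 hit_rate = clamp(hits / n_go),
                 fa_rate = clamp(false_alarms / n_nogo),
                 floor = floor, ceiling = ceiling),
            class = "rate_summary")
}

#' Sensitivity index d'
#'
#' `d' = qnorm(H) - qnorm(FA)` on clamped rates. With the default
#' floor/ceiling of 0.01/0.99 the attainable ceiling is
#' `qnorm(.99) - qnorm(.01) = 4.6527`.
#'
#' @param summary a [rate_summary()], or a clamped hit rate when `fa` is
#'   given.
#' @param fa optional false-alarm rate (clamped by the caller) for the
#'   two-rate form `dprime(h, fa)`.
#' @return d' value.
#' @export
dprime <- function(summary, fa = NULL) {
  if (inherits(summary, "rate_summary")) {
    stats::qnorm(summary$hit_rate) - stats::qnorm(summary$fa_rate)
  } else {
    stats::qnorm(summary) - stats::qnorm(fa)
  }
}

#' Fit a Weibull psychometric function
#'
#' Nonlinear least squares of `A * (1 - exp(-(x/alpha)^beta))` to
#' performance values (d' or Go proportions) across stimulus levels. The
#' free amplitude `A` absorbs the lapse-rate factor `(1 - lambda)`, which
#' is not separately identifiable from a single scale factor, so `A`
#' estimates `amplitude * (1 - lambda)`. The threshold is read where the
#' fitted curve crosses `threshold_criterion` (default d' = 1).
#'
#' @param levels stimulus levels (positive; >= 4 required).
#' @param perf performance at each level.
#' @param threshold_criterion performance criterion defining the threshold.
#' @return a `psychometric_fit`: `alpha`, `beta`, `amplitude`,
#'   `threshold`, `extrapolated` flag, `residuals`, `fitted`.
#' @export
fit_psychometric <- function(levels, perf, threshold_criterion = 1) {
  if (length(levels) < 4) stop("need >= 4 levels", call. = FALSE)
  if (length(levels) != length(perf)) stop("length mismatch", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be positive (shift the axis first)",
                             call. = FALSE)
  weib <- function(x, a, b, A) A * (1 - exp(-(x / a)^b))
  sse <- function(th) {
    a <- exp(th[1]); b <- exp(th[2]); A <- exp(th[3])
    sum((perf - weib(levels, a, b, A))^2)
  }
  # coarse multi-start then BFGS polish
  starts <- expand.grid(a = stats::quantile(levels, c(.25, .5, .75)),
                        b = c(0.5, 1, 2, 4),
                        A = max(perf) * c(1, 1.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- log(as.numeric(starts[i, ]))
    fit <- tryCatch(stats::optim(th0, sse, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("psychometric fit failed to converge; residuals unavailable",
         call. = FALSE)
  }
  a <- exp(best$par[1]); b <- exp(best$par[2]); A <- exp(best$par[3])
  fitted <- weib(levels, a, b, A)
  thr <- if (A > threshold_criterion) {
    a * (-log(1 - threshold_criterion / A))^(1 / b)
  } else NA_real_
  structure(list(alpha = a, beta = b, amplitude = A, threshold = thr,
                 threshold_criterion = threshold_criterion,
                 extrapolated = !is.na(thr) &&
                   (thr < min(levels) || thr > max(levels)),
                 residuals = perf - fitted, fitted = fitted,
                 sse = best$value),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_fit> alpha %.4g, beta %.4g, amplitude %.4g; ",
                     "threshold(perf=%g) = %.4g%s\n"),
              x$alpha, x$beta, x$amplitude, x$threshold_criterion,
              x$threshold, if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
  invisible(x)
}

#' Agreement between model and behavioral d' values
#'
#' R^2 of the least-squares line of model d' regressed on behavioral d',
#' plus the mean absolute error between the two vectors.
#'
#' @param d_model,d_behavior equal-length numeric vectors (n >= 3).
#' @return list with `r2` and `mae`.
#' @export
model_behavior_agreement <- function(d_model, d_behavior) {
  if (length(d_model) != length(d_behavior) || length(d_model) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::var(d_behavior) < 1e-12) {
    stop("behavior vector has zero variance; R^2 undefined", call. = FALSE)
  }
  fit <- stats::lm(d_model ~ d_behavior)
  list(r2 = summary(fit)$r.squared,
       mae = mean(abs(d_model - d_behavior)))
}

#' Likelihood-ratio test on trialwise logistic models
#'
#' Fits full and null logistic (logit-link) models of the binary response
#' by maximum likelihood and compares them with a likelihood-ratio chi^2.
#' The subject random intercept of the original design is approximated by
#' per-subject fixed intercepts (added to both models when a `subject`
#' column is present), and the degrees of freedom are the difference in
#' parameter counts.
#'
#' @param trials data.frame with a binary `response` column (0/1 or
#'   "Go"/"NoGo") and predictor columns; an optional `subject` column adds
#'   per-subject intercepts to both models.
#' @param full_formula,null_formula model formulas on the predictor columns
#'   (response on the left-hand side), e.g.
#'   `response ~ stimulus_type * parameter_value` vs
#'   `response ~ stimulus_type`.
#' @return a `trial_model_result`: `coefficients`, `loglik_full`,
#'   `loglik_null`, `chi2`, `df`, `p`.
#' @export
trialwise_lrt <- function(trials, full_formula, null_formula) {
  trials <- as.data.frame(trials)
  if (is.character(trials$response) || is.factor(trials$response)) {
    trials$response <- as.integer(as.character(trials$response) == "Go")
  }
  if (!all(trials$response %in% c(0, 1))) {
    stop("response must be binary", call. = FALSE)
  }
  add_subject <- "subject" %in% names(trials) &&
    length(unique(trials$subject)) > 1
  augment <- function(f) {
    if (!add_subject) return(f)
    stats::update(f, . ~ . + factor(subject))
  }
  fit <- function(f) {
    m <- stats::glm(augment(f), family = stats::binomial(), data = trials)
    if (!m$converged) {
      stop("logistic fit did not converge (separation or degenerate design)",
           call. = FALSE)
    }
    m
  }
  mf <- fit(full_formula); mn <- fit(null_formula)
  ll_f <- as.numeric(stats::logLik(mf)); ll_n <- as.numeric(stats::logLik(mn))
  df <- length(stats::coef(mf)) - length(stats::coef(mn))
  chi2 <- max(0, 2 * (ll_f - ll_n))
  structure(list(coefficients = stats::coef(mf), loglik_full = ll_f,
                 loglik_null = ll_n, chi2 = chi2, df = df,
                 p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                     else NA_real_),
            class = "trial_model_result")
}

#' @export
print.trial_model_result <- function(x, ...) {
  cat(sprintf("<trial_model_result> LRT chi2 = %.3f, df = %d, p = %s\n",
              x$chi2, x$df,
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Catch-trial Go-rate summary and paired comparison
#'
#' Computes the Go rate per (syllable identity, regular/catch) cell for
#' each subject and pairs regular vs catch rates within subject and
#' syllable identity with a paired t-test.
#'
#' @param trials data.frame with columns `subject`, `category` (syllable
#'   identity), `trial_class` ("regular"/"catch") and `response`
#'   ("Go"/"NoGo" or 0/1).
#' @return list with `rates` (data.frame subject x category x class Go
#'   rates) and `test` (paired t-test over the per-subject differences; `p`
#'   is NA with a flag when all differences are identical zero variance).
#' @export
catch_trial_summary <- function(trials) {
  trials <- as.data.frame(trials)
  if (is.character(trials$response) || is.factor(trials$response)) {
    trials$response <- as.integer(as.character(trials$response) == "Go")
  }
  cells <- stats::aggregate(response ~ subject + category + trial_class,
                            data = trials, FUN = mean)
  names(cells)[names(cells) == "response"] <- "go_rate"
  counts <- stats::aggregate(response ~ subject + category + trial_class,
                             data = trials, FUN = length)
  if (any(counts$response == 0)) stop("empty design cell", call. = FALSE)
  wide <- stats::reshape(cells, direction = "wide",
                         idvar = c("subject", "category"),
                         timevar = "trial_class")
  reg <- wide$go_rate.regular; cat_ <- wide$go_rate.catch
  if (any(is.na(reg)) || any(is.na(cat_))) stop("empty design cell", call. = FALSE)
  d <- reg - cat_
  test <- if (stats::sd(d) < 1e-12) {
    list(statistic = NA_real_, p = NA_real_, degenerate = TRUE,
         mean_difference = mean(d))
  } else {
    tt <- stats::t.test(reg, cat_, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value, degenerate = FALSE,
         mean_difference = mean(d))
  }
  list(rates = cells, test = test)
}
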