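# Long-term-spectrum classifier baseline: one linear max-margin classifier
# per category (one-vs-rest) on per-channel cochleagram statistics, with a
# winner-take-all comparison of decision values. Because no SVM library is
# assumed, the classifier is a small primal solver: squared-hinge loss with
# an L2 penalty, minimized by BFGS on standardized predictors.

#' Long-term spectrum feature of a cochleagram
#'
#' Per-channel temporal variance of the cochleagram rows (the default
#' reading of spectral power as rate variance at each CF). The alternative
#' reading — per-channel temporal mean — is selectable.
#'
#' @param c a `cochleagram` with at least 2 frames.
#' @param statistic `"variance"` (default) or `"mean"`.
#' @return numeric vector of length `n_channels`.
#' @export
long_term_spectrum <- function(c, statistic = c("variance", "mean")) {
  statistic <- match.arg(statistic)
  if (ncol(c$values) < 2) stop("need >= 2 frames", call. = FALSE)
  if (statistic == "variance") apply(c$values, 1, stats::var)
  else rowMeans(c$values)
}

# Primal linear classifier: minimize lambda/2 ||w||^2 +
# mean(max(0, 1 - y f)^2), f = X w + b. Deterministic given the data.
linsvm_fit <- function(X, y, lambda = 1e-2) {
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    marg <- 1 - y * (X %*% w + b)
    lambda / 2 * sum(w^2) + mean(pmax(marg, 0)^2)
  }
  grad <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    marg <- as.numeric(1 - y * (X %*% w + b))
    act <- pmax(marg, 0)
    gw <- lambda * w - 2 / nrow(X) * as.numeric(crossprod(X, act * y))
    gb <- -2 / nrow(X) * sum(act * y)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[1:d], b = fit$par[d + 1])
}

#' Train a one-vs-rest long-term-spectrum classifier
#'
#' Linear max-margin classifier (squared-hinge primal, L2 penalty) on
#' standardized long-term-spectrum features, with k-fold cross-validated
#' misclassification loss.
#'
#' @param corpus a `call_corpus`.
#' @param category positive-class label; all other categories are negatives.
#' @param params [cochleagram_params()].
#' @param statistic forwarded to [long_term_spectrum()].
#' @param n_folds cross-validation folds (default 10).
#' @param lambda L2 penalty.
#' @param seed fold-assignment seed.
#' @param cochleagrams optional named precomputed cochleagram cache.
#' @return a `spectrum_classifier`: weights, bias, standardization
#'   parameters, `cv_loss`, `category`.
#' @export
train_spectrum_classifier <- function(corpus, category,
                                      params = cochleagram_params(),
                                      statistic = "variance",
                                      n_folds = 10, lambda = 1e-2, seed = 1,
                                      cochleagrams = NULL) {
  calls <- corpus_calls(corpus, split = "train")
  cats <- vapply(calls, function(cl) cl$category, "")
  if (sum(cats == category) < 2 || sum(cats != category) < 2) {
    stop("each class needs at least 2 training calls", call. = FALSE)
  }
  feats <- t(vapply(calls, function(cl) {
    cc <- if (!is.null(cochleagrams) && !is.null(cochleagrams[[cl$exemplar_id]]))
      cochleagrams[[cl$exemplar_id]] else compute_cochleagram(cl, params)
    long_term_spectrum(cc, statistic)
  }, numeric(params$n_channels)))
  y <- ifelse(cats == category, 1, -1)
  mu <- colMeans(feats); sg <- apply(feats, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  X <- sweep(sweep(feats, 2, mu), 2, sg, "/")

  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  errs <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- linsvm_fit(X[tr, , drop = FALSE], y[tr], lambda)
    pred <- sign(X[!tr, , drop = FALSE] %*% m$w + m$b)
    mean(pred != y[!tr])
  }, 0)
  model <- linsvm_fit(X, y, lambda)
  structure(list(category = category, w = model$w, b = model$b,
                 mu = mu, sigma = sg, statistic = statistic,
                 cv_loss = mean(errs, na.rm = TRUE)),
            class = "spectrum_classifier")
}

#' Signed decision value of a spectrum classifier on a stimulus
#'
#' @param clf a `spectrum_classifier`.
#' @param c a `cochleagram`.
#' @return signed distance-like decision value (positive favors the class).
#' @export
spectrum_decision <- function(clf, c) {
  x <- (long_term_spectrum(c, clf$statistic) - clf$mu) / clf$sigma
  as.numeric(sum(clf$w * x) + clf$b)
}

#' Winner-take-all decision between two spectrum classifiers
#'
#' @param target_clf,distractor_clf trained `spectrum_classifier`s.
#' @param c a `cochleagram` of the stimulus.
#' @return `"Go"` if the target classifier's decision value exceeds the
#'   distractor's, else `"NoGo"`.
#' @export
spectrum_wta <- function(target_clf, distractor_clf, c) {
  if (spectrum_decision(target_clf, c) > spectrum_decision(distractor_clf, c))
    "Go" else "NoGo"
}

#' Serialize / deserialize a spectrum classifier as JSON
#' @param clf a `spectrum_classifier`.
#' @param path file path.
#' @return `save_spectrum_classifier()`: path invisibly;
#'   `load_spectrum_classifier()`: a `spectrum_classifier`.
#' @export
save_spectrum_classifier <- function(clf, path) {
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_spectrum_classifier
#' @export
load_spectrum_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "spectrum_classifier")
}
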