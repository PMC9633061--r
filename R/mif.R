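# Maximally informative features (MIFs): rectangular spectrotemporal
# fragments of training cochleagrams, each with a detection threshold on its
# maximum normalized cross-correlation (r_max) against a stimulus and a
# log-likelihood-ratio weight. Feature sets are selected greedily to
# maximize the mutual information between the ensemble detection score and
# the category label; detection responses feed a winner-take-all Go/No-go
# decision stage with guess/lapse bounds on the Go probability.

# ---------------------------------------------------------------------------
# candidate sampling

#' Sample candidate spectrotemporal features from target cochleagrams
#'
#' Rectangular blocks are cut at uniformly drawn positions from the target
#' category's training cochleagrams. Durations are drawn uniformly in
#' `[min_dur_ms, max_dur_ms]`, CF extents uniformly from `min_channels` up
#' to the full channel count.
#'
#' @param cochleagrams list of `cochleagram` (target training calls).
#' @param n number of candidates (default 1500).
#' @param max_dur_ms maximum feature duration, ms (default 200; 75 in the
#'   constrained short-feature variant).
#' @param min_dur_ms minimum feature duration, ms.
#' @param min_channels minimum CF extent, channels.
#' @param seed integer seed.
#' @return list of `candidate_feature`: `patch` (matrix), `cf_lo`, `cf_hi`
#'   (row indices), `duration_ms`, `source_call`, `offset` (channel, frame).
#' @export
sample_candidates <- function(cochleagrams, n = 1500, max_dur_ms = 200,
                              min_dur_ms = 20, min_channels = 4, seed = 1) {
  if (length(cochleagrams) == 0) stop("no cochleagrams supplied", call. = FALSE)
  frame_rate <- cochleagrams[[1]]$frame_rate
  min_fr <- max(2L, round(min_dur_ms / 1000 * frame_rate))
  usable <- vapply(cochleagrams, function(cc) ncol(cc$values) >= min_fr, TRUE)
  if (!any(usable)) stop("no cochleagram long enough for minimum feature duration",
                         call. = FALSE)
  cochleagrams <- cochleagrams[usable]
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      src <- sample.int(length(cochleagrams), 1)
      cc <- cochleagrams[[src]]
      n_ch <- nrow(cc$values); n_fr <- ncol(cc$values)
      max_fr <- min(round(max_dur_ms / 1000 * frame_rate), n_fr)
      dur_fr <- sample(min_fr:max_fr, 1)
      ext_ch <- sample(min_channels:n_ch, 1)
      ch0 <- sample.int(n_ch - ext_ch + 1, 1)
      fr0 <- sample.int(n_fr - dur_fr + 1, 1)
      structure(list(
        patch = cc$values[ch0:(ch0 + ext_ch - 1), fr0:(fr0 + dur_fr - 1),
                          drop = FALSE],
        cf_lo = ch0, cf_hi = ch0 + ext_ch - 1,
        duration_ms = dur_fr / frame_rate * 1000,
        source_call = cc$source_id, offset = c(ch0, fr0)),
        class = "candidate_feature")
    })
  })
}

# ---------------------------------------------------------------------------
# normalized cross-correlation

# Full r(t) profile of a patch against the cochleagram rows it was cut from,
# sliding in time only. Zero-mean, unit-norm correlation per placement;
# degenerate (zero-variance) patches or windows score 0.
ncc_profile <- function(patch, values, cf_lo) {
  k <- nrow(patch); m <- ncol(patch)
  stopifnot(cf_lo >= 1, cf_lo + k - 1 <= nrow(values))
  T_ <- ncol(values)
  if (m > T_) stop("feature longer than cochleagram", call. = FALSE)
  L <- T_ - m + 1
  C <- values[cf_lo:(cf_lo + k - 1), , drop = FALSE]
  K <- k * m
  p_mean <- mean(patch)
  p_c <- patch - p_mean
  p_norm <- sqrt(sum(p_c^2))
  if (p_norm < 1e-12) return(numeric(L))  # constant template -> r = 0

  nfft <- 2^ceiling(log2(T_))
  FC <- stats::mvfft(rbind(t(C), matrix(0, nfft - T_, k)))
  FP <- stats::mvfft(rbind(t(patch), matrix(0, nfft - m, k)))
  S <- rowSums(FC * Conj(FP))
  cross <- Re(stats::fft(S, inverse = TRUE))[seq_len(L)] / nfft

  colsum <- colSums(C); colsq <- colSums(C^2)
  cs1 <- c(0, cumsum(colsum)); cs2 <- c(0, cumsum(colsq))
  idx <- seq_len(L)
  win_sum <- cs1[idx + m] - cs1[idx]
  win_ss <- cs2[idx + m] - cs2[idx]
  win_var <- pmax(win_ss - win_sum^2 / K, 0)
  denom <- p_norm * sqrt(win_var)
  r <- (cross - p_mean * win_sum) / denom
  r[denom < 1e-12] <- 0
  pmax(pmin(r, 1), -1)
}

#' Maximum normalized cross-correlation of a feature with a cochleagram
#'
#' The feature slides in time only, anchored at its native CF rows. Each
#' placement is scored by the zero-mean, unit-norm (Pearson) correlation
#' between the patch and the aligned cochleagram window; the maximum over
#' all valid placements is returned.
#'
#' @param feature a `candidate_feature` (or an `mif`, whose feature is used).
#' @param c a `cochleagram`.
#' @return r_max in `[-1, 1]`; 0 for a constant (degenerate) template.
#' @export
max_ncc <- function(feature, c) {
  if (inherits(feature, "mif")) feature <- feature$feature
  max(ncc_profile(feature$patch, c$values, feature$cf_lo))
}

# ---------------------------------------------------------------------------
# per-feature threshold / MI / weight

# Mutual information (bits) between a binary detection and the class label,
# from detection counts and class sizes, using the given priors.
binary_mi <- function(n_det_t, n_t, n_det_o, n_o, prior_t, prior_o) {
  p_d_t <- n_det_t / n_t; p_d_o <- n_det_o / n_o
  joint <- c(p_d_t * prior_t, (1 - p_d_t) * prior_t,
             p_d_o * prior_o, (1 - p_d_o) * prior_o)
  pd <- joint[1] + joint[3]
  marg <- c(pd * prior_t, (1 - pd) * prior_t, pd * prior_o, (1 - pd) * prior_o)
  ok <- joint > 0
  sum(joint[ok] * log2(joint[ok] / marg[ok]))
}

#' Fit a feature's detection threshold, merit and weight
#'
#' Sweeps candidate thresholds (midpoints between consecutive sorted unique
#' r_max values over both classes) and keeps the one maximizing the mutual
#' information between detection (`r_max > threshold`) and class. The
#' feature's weight is the log-likelihood ratio
#' `ln P(detect | target) / P(detect | other)` with add-one smoothing.
#'
#' @param rmax_target,rmax_other r_max values on target and other calls.
#' @param priors optional `c(p_target, p_other)`; empirical by default.
#' @return list with `threshold`, `merit` (bits), `weight` (natural log).
#' @export
fit_feature <- function(rmax_target, rmax_other, priors = NULL) {
  if (length(rmax_target) == 0 || length(rmax_other) == 0) {
    stop("both r_max lists must be non-empty", call. = FALSE)
  }
  n_t <- length(rmax_target); n_o <- length(rmax_other)
  if (is.null(priors)) priors <- c(n_t, n_o) / (n_t + n_o)
  u <- sort(unique(c(rmax_target, rmax_other)))
  if (length(u) < 2) {
    return(list(threshold = u[1], merit = 0, weight = 0))
  }
  thr <- (u[-1] + u[-length(u)]) / 2
  mi <- vapply(thr, function(th) {
    binary_mi(sum(rmax_target > th), n_t, sum(rmax_other > th), n_o,
              priors[1], priors[2])
  }, 0)
  best <- which.max(mi)
  th <- thr[best]
  n_det_t <- sum(rmax_target > th); n_det_o <- sum(rmax_other > th)
  w <- log((n_det_t + 1) / (n_t + 2)) - log((n_det_o + 1) / (n_o + 2))
  list(threshold = th, merit = mi[best], weight = w)
}

# ---------------------------------------------------------------------------
# greedy ensemble selection

# MI (bits) of thresholded ensemble score vs class, maximized over score
# thresholds (midpoints between consecutive unique scores).
ensemble_mi <- function(scores, is_target, priors = NULL) {
  n_t <- sum(is_target); n_o <- sum(!is_target)
  if (is.null(priors)) priors <- c(n_t, n_o) / (n_t + n_o)
  u <- sort(unique(scores))
  if (length(u) < 2) return(0)
  thr <- (u[-1] + u[-length(u)]) / 2
  max(vapply(thr, function(th) {
    binary_mi(sum(scores[is_target] > th), n_t,
              sum(scores[!is_target] > th), n_o, priors[1], priors[2])
  }, 0))
}

#' Greedily select a maximally informative, least redundant feature set
#'
#' Forward selection over fitted candidates: at each step the candidate that
#' maximizes the mutual information between the ensemble's weighted
#' detection score (the [fd_response()] formula applied to the current set
#' plus the candidate, score threshold re-optimized each step) and the
#' class label is added. Selection halts at `max_n` features or when the
#' incremental MI gain drops below `min_gain_bits`, which yields
#' variable-size sets.
#'
#' @param fits list of per-candidate fits (as from [fit_feature()]), each
#'   augmented with `feature` and `rmax` (r_max vector over training calls).
#' @param is_target logical vector over training calls.
#' @param max_n maximum set size (default 20).
#' @param min_gain_bits stopping tolerance on the MI gain (default 1e-3).
#' @param category label stored on the set.
#' @param instantiation_index stored on the set.
#' @return an `mif_set`: `category`, `mifs` (list of `mif`),
#'   `instantiation_index`, `training_auc` (NA until evaluated),
#'   `selected_idx` (indices into `fits`), `ensemble_mi_trace`.
#' @export
greedy_select <- function(fits, is_target, max_n = 20, min_gain_bits = 1e-3,
                          category = NA_character_, instantiation_index = 1L) {
  usable <- which(vapply(fits, function(f) f$merit > 0 && f$weight > 0, TRUE))
  if (length(usable) == 0) stop("no informative candidate (merit > 0)",
                                call. = FALSE)
  n_calls <- length(is_target)
  D <- do.call(rbind, lapply(fits, function(f) as.numeric(f$rmax > f$threshold)))
  w <- vapply(fits, function(f) f$weight, 0)

  selected <- integer(0)
  numer <- numeric(n_calls); denom <- 0
  mi_cur <- 0; trace <- numeric(0)
  remaining <- usable
  while (length(selected) < max_n && length(remaining) > 0) {
    gains <- vapply(remaining, function(ci) {
      sc <- (numer + w[ci] * D[ci, ]) / (denom + w[ci])
      ensemble_mi(sc, is_target)
    }, 0)
    best <- which.max(gains)
    if (gains[best] - mi_cur < min_gain_bits) break
    ci <- remaining[best]
    selected <- c(selected, ci)
    numer <- numer + w[ci] * D[ci, ]
    denom <- denom + w[ci]
    mi_cur <- gains[best]
    trace <- c(trace, mi_cur)
    remaining <- remaining[remaining != ci]
  }
  mifs <- lapply(selected, function(ci) {
    structure(list(feature = fits[[ci]]$feature,
                   threshold = fits[[ci]]$threshold,
                   weight = fits[[ci]]$weight,
                   merit = fits[[ci]]$merit), class = "mif")
  })
  structure(list(category = category, mifs = mifs,
                 instantiation_index = as.integer(instantiation_index),
                 training_auc = NA_real_,
                 selected_idx = selected, ensemble_mi_trace = trace),
            class = "mif_set")
}

#' @export
print.mif_set <- function(x, ...) {
  cat(sprintf("<mif_set> %s #%d: %d MIFs, training AUC %s\n",
              x$category, x$instantiation_index, length(x$mifs),
              if (is.na(x$training_auc)) "unset" else
                sprintf("%.3f", x$training_auc)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# detection responses, WTA, AUC

# Detection vector of a set's MIFs on one cochleagram. Features longer than
# the stimulus are scored as not detected.
detect_mifs <- function(mifset, c) {
  vapply(mifset$mifs, function(m) {
    if (ncol(m$feature$patch) > ncol(c$values)) return(FALSE)
    max_ncc(m, c) > m$threshold
  }, TRUE)
}

#' Feature-detection response of an MIF set on a stimulus
#'
#' Sum of the weights of detected MIFs (each counted once) divided by the
#' sum of all the set's weights, giving a response in `[0, 1]`.
#'
#' @param mifset an `mif_set`.
#' @param c a `cochleagram`.
#' @return response in `[0, 1]`.
#' @export
fd_response <- function(mifset, c) {
  det <- detect_mifs(mifset, c)
  w <- vapply(mifset$mifs, function(m) m$weight, 0)
  sum(w[det]) / sum(w)
}

#' Winner-take-all Go probability
#'
#' Evidence is the target minus the distractor feature-detection response;
#' positive evidence maps to `p_max`, negative to `p_min` (guess/lapse
#' bounds), an exact tie to 0.5.
#'
#' @param target_resp,distractor_resp FD responses in `[0, 1]`.
#' @param p_min,p_max Go-probability bounds (defaults 0.1 and 0.9).
#' @return Go probability.
#' @export
wta_decide <- function(target_resp, distractor_resp, p_min = 0.1, p_max = 0.9) {
  evidence <- target_resp - distractor_resp
  ifelse(evidence > 0, p_max, ifelse(evidence < 0, p_min, 0.5))
}

#' Realize stochastic Go/No-go responses
#'
#' A uniform draw `X` in (0, 1) is compared with the Go probability;
#' the response is Go iff `X < go_probability`.
#'
#' @param go_probability numeric vector of Go probabilities.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (and advanced).
#' @return list with `response` (character, "Go"/"NoGo") and `draw` (the
#'   uniform variates).
#' @export
simulate_response <- function(go_probability, seed = NULL) {
  draw <- if (is.null(seed)) stats::runif(length(go_probability))
          else with_seed(seed, stats::runif(length(go_probability)))
  list(response = ifelse(draw < go_probability, "Go", "NoGo"), draw = draw)
}

# Trapezoidal ROC AUC over observed scores; tied score distributions
# contribute 0.5 per tie (equivalent to the rank-statistic form).
auc_scores <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, -Inf, Inf)))
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' ROC area under the curve of an MIF set
#'
#' Scores positives and negatives with [fd_response()] and integrates the
#' ROC curve (trapezoid rule; ties contribute 0.5).
#'
#' @param mifset an `mif_set`.
#' @param positives,negatives lists of `cochleagram`.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(mifset, positives, negatives) {
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("need non-empty positive and negative sets", call. = FALSE)
  }
  auc_scores(vapply(positives, function(c) fd_response(mifset, c), 0),
             vapply(negatives, function(c) fd_response(mifset, c), 0))
}

#' Per-MIF relative detection rates
#'
#' For each MIF: fraction of within-category calls in which it is detected
#' minus the fraction of outside-category calls, together with the MIF's
#' center frequency, bandwidth and duration.
#'
#' @param mifset an `mif_set`.
#' @param within_calls,outside_calls lists of `cochleagram`.
#' @param cfs CF grid in Hz (to report center frequency/bandwidth);
#'   defaults to the grid of the first within-call.
#' @return data.frame with columns `mif`, `rate_within`, `rate_outside`,
#'   `relative_rate`, `cf_hz`, `bandwidth_oct`, `duration_ms`.
#' @export
relative_detection_rate <- function(mifset, within_calls, outside_calls,
                                    cfs = NULL) {
  if (length(within_calls) == 0 || length(outside_calls) == 0) {
    stop("need non-empty within and outside call lists", call. = FALSE)
  }
  if (is.null(cfs)) cfs <- within_calls[[1]]$cfs
  det_rate <- function(calls) {
    d <- vapply(calls, function(c) detect_mifs(mifset, c),
                logical(length(mifset$mifs)))
    if (is.null(dim(d))) d <- matrix(d, nrow = length(mifset$mifs))
    rowMeans(d)
  }
  rw <- det_rate(within_calls); ro <- det_rate(outside_calls)
  info <- t(vapply(mifset$mifs, function(m) {
    f <- m$feature
    c(cf_hz = sqrt(cfs[f$cf_lo] * cfs[f$cf_hi]),
      bandwidth_oct = log2(cfs[f$cf_hi] / cfs[f$cf_lo]),
      duration_ms = f$duration_ms)
  }, c(cf_hz = 0, bandwidth_oct = 0, duration_ms = 0)))
  data.frame(mif = seq_along(mifset$mifs), rate_within = rw,
             rate_outside = ro, relative_rate = rw - ro, info)
}

# ---------------------------------------------------------------------------
# training

#' Train multiple disjoint MIF-set instantiations for one category
#'
#' Samples candidate features from the target category's training
#' cochleagrams, fits each candidate's threshold/merit/weight against the
#' negative class, then repeatedly runs greedy selection, removing each
#' selected feature from the pool before training the next instantiation so
#' the sets are feature-wise disjoint. Each set's training AUC is recorded.
#'
#' @param corpus a `call_corpus`.
#' @param category target category label.
#' @param n_instantiations number of disjoint sets (default 5).
#' @param n_candidates candidate pool size (default 1500).
#' @param max_dur_ms maximum feature duration, ms (default 200).
#' @param max_n maximum MIFs per set (default 20).
#' @param min_gain_bits greedy stopping tolerance (default 1e-3).
#' @param mode `"one-vs-many"` (negatives are all other categories) or
#'   `"one-vs-one"` (negatives are `partner` only).
#' @param partner partner category for one-vs-one mode.
#' @param params [cochleagram_params()].
#' @param seed integer seed.
#' @param cochleagrams optional named list of precomputed train
#'   cochleagrams keyed by exemplar id (cache; computed when missing).
#' @return list of `mif_set` (length `n_instantiations`, or fewer with a
#'   warning if the informative candidate pool is exhausted).
#' @export
train_instantiations <- function(corpus, category, n_instantiations = 5,
                                 n_candidates = 1500, max_dur_ms = 200,
                                 max_n = 20, min_gain_bits = 1e-3,
                                 mode = c("one-vs-many", "one-vs-one"),
                                 partner = NULL,
                                 params = cochleagram_params(), seed = 1,
                                 cochleagrams = NULL) {
  mode <- match.arg(mode)
  targets <- corpus_calls(corpus, categories = category, split = "train")
  negatives_cat <- if (mode == "one-vs-one") {
    if (is.null(partner)) stop("one-vs-one mode needs `partner`", call. = FALSE)
    partner
  } else {
    cats <- unique(vapply(corpus$calls, function(cl) cl$category, ""))
    setdiff(cats, category)
  }
  others <- corpus_calls(corpus, categories = negatives_cat, split = "train")
  if (length(targets) == 0 || length(others) == 0) {
    stop("corpus lacks target or non-target training calls", call. = FALSE)
  }
  get_coch <- function(cl) {
    id <- cl$exemplar_id
    if (!is.null(cochleagrams) && !is.null(cochleagrams[[id]])) {
      cochleagrams[[id]]
    } else compute_cochleagram(cl, params)
  }
  coch_t <- lapply(targets, get_coch)
  coch_o <- lapply(others, get_coch)
  all_coch <- c(coch_t, coch_o)
  is_target <- c(rep(TRUE, length(coch_t)), rep(FALSE, length(coch_o)))

  cands <- sample_candidates(coch_t, n = n_candidates,
                             max_dur_ms = max_dur_ms, seed = seed)
  R <- rmax_matrix(cands, all_coch)
  fits <- lapply(seq_along(cands), function(i) {
    f <- fit_feature(R[i, is_target], R[i, !is_target])
    f$feature <- cands[[i]]
    f$rmax <- R[i, ]
    f
  })

  sets <- list()
  pool <- seq_along(fits)
  for (inst in seq_len(n_instantiations)) {
    informative <- pool[vapply(fits[pool],
                               function(f) f$merit > 0 && f$weight > 0, TRUE)]
    if (length(informative) == 0) {
      warning(sprintf("candidate pool exhausted after %d instantiation(s)",
                      length(sets)))
      break
    }
    ms <- greedy_select(fits[pool], is_target, max_n = max_n,
                        min_gain_bits = min_gain_bits, category = category,
                        instantiation_index = inst)
    # map back to global candidate indices and shrink the pool
    global_idx <- pool[ms$selected_idx]
    ms$selected_idx <- global_idx
    pool <- setdiff(pool, global_idx)
    # training AUC from the already-computed detection matrix
    w <- vapply(ms$mifs, function(m) m$weight, 0)
    det <- do.call(rbind, lapply(seq_along(global_idx), function(j) {
      as.numeric(R[global_idx[j], ] > ms$mifs[[j]]$threshold)
    }))
    scores <- as.numeric(crossprod(det, w)) / sum(w)
    ms$training_auc <- auc_scores(scores[is_target], scores[!is_target])
    sets[[length(sets) + 1]] <- ms
  }
  sets
}

# r_max of every candidate against every cochleagram; FFT path with cached
# per-cochleagram row FFTs and channel cumsums.
rmax_matrix <- function(features, cochleagrams) {
  nf <- length(features); nc <- length(cochleagrams)
  R <- matrix(0, nf, nc)
  # per-feature centered patch stats
  pstats <- lapply(features, function(f) {
    p <- f$patch
    pm <- mean(p)
    list(mean = pm, norm = sqrt(sum((p - pm)^2)), k = nrow(p), m = ncol(p))
  })
  for (j in seq_len(nc)) {
    V <- cochleagrams[[j]]$values
    T_ <- ncol(V)
    nfft <- 2^ceiling(log2(T_))
    FC <- stats::mvfft(rbind(t(V), matrix(0, nfft - T_, nrow(V))))
    cs1 <- rbind(0, apply(V, 2, cumsum))      # (n_ch+1) x T channel cumsums
    cs2 <- rbind(0, apply(V^2, 2, cumsum))
    for (i in seq_len(nf)) {
      f <- features[[i]]; ps <- pstats[[i]]
      m <- ps$m
      if (m > T_) { R[i, j] <- NA_real_; next }
      if (ps$norm < 1e-12) { R[i, j] <- 0; next }
      L <- T_ - m + 1
      FP <- stats::mvfft(rbind(t(f$patch), matrix(0, nfft - m, ps$k)))
      S <- rowSums(FC[, f$cf_lo:f$cf_hi, drop = FALSE] * Conj(FP))
      cross <- Re(stats::fft(S, inverse = TRUE))[seq_len(L)] / nfft
      rowsum_t <- cs1[f$cf_hi + 1, ] - cs1[f$cf_lo, ]
      rowsq_t <- cs2[f$cf_hi + 1, ] - cs2[f$cf_lo, ]
      t1 <- c(0, cumsum(rowsum_t)); t2 <- c(0, cumsum(rowsq_t))
      idx <- seq_len(L)
      win_sum <- t1[idx + m] - t1[idx]
      win_var <- pmax((t2[idx + m] - t2[idx]) - win_sum^2 / (ps$k * m), 0)
      denom <- ps$norm * sqrt(win_var)
      r <- (cross - ps$mean * win_sum) / denom
      r[denom < 1e-12] <- 0
      R[i, j] <- max(pmin(pmax(r, -1), 1))
    }
  }
  R
}

# ---------------------------------------------------------------------------
# serialization

#' Serialize / deserialize an MIF set as JSON
#'
#' Thresholds, weights, merits and the spectrotemporal patches themselves
#' are stored in a single portable JSON document.
#'
#' @param mifset an `mif_set`.
#' @param path file path.
#' @return `save_mifset()`: path invisibly; `load_mifset()`: an `mif_set`.
#' @export
save_mifset <- function(mifset, path) {
  obj <- list(
    category = mifset$category,
    instantiation_index = mifset$instantiation_index,
    training_auc = mifset$training_auc,
    mifs = lapply(mifset$mifs, function(m) {
      list(threshold = m$threshold, weight = m$weight, merit = m$merit,
           cf_lo = m$feature$cf_lo, cf_hi = m$feature$cf_hi,
           duration_ms = m$feature$duration_ms,
           source_call = m$feature$source_call,
           patch = lapply(seq_len(nrow(m$feature$patch)),
                          function(i) m$feature$patch[i, ]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mifset
#' @export
load_mifset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mifs <- lapply(obj$mifs, function(m) {
    patch <- do.call(rbind, lapply(m$patch, function(r) unlist(r)))
    structure(list(
      feature = structure(list(patch = patch, cf_lo = m$cf_lo,
                               cf_hi = m$cf_hi,
                               duration_ms = m$duration_ms,
                               source_call = m$source_call,
                               offset = c(m$cf_lo, NA)),
                          class = "candidate_feature"),
      threshold = m$threshold, weight = m$weight, merit = m$merit),
      class = "mif")
  })
  structure(list(category = obj$category, mifs = mifs,
                 instantiation_index = obj$instantiation_index,
                 training_auc = obj$training_auc),
            class = "mif_set")
}
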