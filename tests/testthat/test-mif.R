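test_that("max_ncc equals brute-force correlation on random toy instances", {
  set.seed(314)
  for (i in 1:10) {
    V <- matrix(stats::rexp(10 * 20), 10, 20)
    k <- sample(2:6, 1); m <- sample(2:8, 1)
    lo <- sample.int(10 - k + 1, 1)
    t0 <- sample.int(20 - m + 1, 1)
    patch <- V[lo:(lo + k - 1), t0:(t0 + m - 1), drop = FALSE] +
      matrix(stats::rnorm(k * m, sd = 0.1), k, m)
    feat <- structure(list(patch = patch, cf_lo = lo, cf_hi = lo + k - 1,
                           duration_ms = m, source_call = "toy",
                           offset = c(lo, t0)),
                      class = "candidate_feature")
    cc <- toy_cochleagram(V)
    expect_equal(max_ncc(feat, cc), oracle_max_ncc(patch, V, lo),
                 tolerance = 1e-9)
  }
})

test_that("max_ncc contract cases: self-match, degenerate patch, length error", {
  set.seed(11)
  V <- matrix(stats::rexp(8 * 30), 8, 30)
  cc <- toy_cochleagram(V)
  feat <- structure(list(patch = V[2:5, 10:17], cf_lo = 2, cf_hi = 5,
                         duration_ms = 8, source_call = "t",
                         offset = c(2, 10)), class = "candidate_feature")
  expect_equal(max_ncc(feat, cc), 1, tolerance = 1e-9)

  const <- feat; const$patch <- matrix(0.7, 4, 8)
  expect_identical(max_ncc(const, cc), 0)

  long <- feat; long$patch <- matrix(1:124, 4, 31) * 1.0
  expect_error(max_ncc(long, cc), "longer")
})

test_that("fit_feature matches exhaustive threshold enumeration", {
  # perfect separation, equal priors
  fit <- fit_feature(c(0.9, 0.8), c(0.2, 0.3))
  expect_equal(fit$merit, 1)
  expect_gt(fit$threshold, 0.3)
  expect_lt(fit$threshold, 0.8)
  expect_gt(fit$weight, 0)

  # no information
  expect_equal(fit_feature(c(0.5, 0.5), c(0.5, 0.5))$merit, 0)

  # overlapping toy sets vs brute-force enumeration over midpoints
  rt <- c(0.9, 0.6, 0.4); ro <- c(0.5, 0.3)
  u <- sort(unique(c(rt, ro)))
  mids <- (u[-1] + u[-length(u)]) / 2
  is_t <- c(rep(TRUE, 3), rep(FALSE, 2))
  mi_or <- vapply(mids, function(th) {
    oracle_mi(c(rt, ro) > th, is_t)
  }, 0)
  fit2 <- fit_feature(rt, ro)
  expect_equal(fit2$merit, max(mi_or), tolerance = 1e-12)
  expect_equal(fit2$threshold, mids[which.max(mi_or)])
})

test_that("greedy selection achieves the exhaustive-subset optimum on a toy problem", {
  # 10 calls (5 targets); c1 and c2 are complementary perfect halves,
  # c3 duplicates c1, c4 is weakly informative, c5 is uninformative.
  is_t <- rep(c(TRUE, FALSE), each = 5)
  det <- list(
    c1 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    c2 = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0),
    c3 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    c4 = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0),
    c5 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  fits <- lapply(det, function(d) {
    list(threshold = 0.5, merit = if (sum(d) > 0) 0.2 else 0, weight = 1,
         rmax = d, feature = structure(list(patch = matrix(1, 2, 2),
                                            cf_lo = 1, cf_hi = 2,
                                            duration_ms = 2,
                                            source_call = "toy",
                                            offset = c(1, 1)),
                                       class = "candidate_feature"))
  })
  sel <- greedy_select(fits, is_t, max_n = 3, min_gain_bits = 1e-3)

  # independent exhaustive search over all subsets of size <= 3
  usable <- which(vapply(fits, function(f) f$merit > 0, TRUE))
  subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(usable, k, simplify = FALSE)
  }), recursive = FALSE)
  score_mi <- function(idx) {
    sc <- Reduce(`+`, lapply(idx, function(i) det[[i]])) / length(idx)
    u <- sort(unique(sc))
    if (length(u) < 2) return(0)
    mids <- (u[-1] + u[-length(u)]) / 2
    max(vapply(mids, function(th) oracle_mi(sc > th, is_t), 0))
  }
  best_mi <- max(vapply(subsets, score_mi, 0))
  expect_equal(score_mi(sel$selected_idx), best_mi, tolerance = 1e-12)
  # the optimum here is the complementary pair; the duplicate adds nothing
  expect_setequal(sel$selected_idx, c(1, 2))
})

test_that("fd_response is the weight-normalized detected fraction", {
  set.seed(21)
  V <- matrix(stats::rexp(10 * 50), 10, 50)
  cc <- toy_cochleagram(V)
  spans <- list(list(rows = 1:3, cols = 5:12),
                list(rows = 4:6, cols = 20:30),
                list(rows = 7:9, cols = 35:44))
  # all verbatim patches (r_max = 1); thresholds decide detection
  ms <- toy_mifset(cc, spans, thresholds = c(0.9, 0.9, 0.9),
                   weights = c(1, 2, 3))
  expect_equal(fd_response(ms, cc), 1)

  ms_none <- toy_mifset(cc, spans, thresholds = c(2, 2, 2),
                        weights = c(1, 2, 3))
  expect_equal(fd_response(ms_none, cc), 0)

  ms_partial <- toy_mifset(cc, spans, thresholds = c(0.9, 0.9, 2),
                           weights = c(1, 2, 3))
  expect_equal(fd_response(ms_partial, cc), 0.5)

  # a feature longer than the stimulus counts as not detected
  short <- toy_cochleagram(V[, 1:6])
  expect_equal(fd_response(ms_none, short), 0)
  expect_lte(fd_response(ms, short), 1)
})

test_that("WTA bounds and stochastic realization follow the X < P(GO) rule", {
  expect_equal(wta_decide(0.8, 0.3), 0.9)
  expect_equal(wta_decide(0.3, 0.8), 0.1)
  expect_equal(wta_decide(0.5, 0.5), 0.5)

  expect_true(all(simulate_response(rep(0, 500), seed = 1)$response == "NoGo"))
  expect_true(all(simulate_response(rep(1, 500), seed = 2)$response == "Go"))
  sim <- simulate_response(rep(0.9, 1e5), seed = 3)
  expect_equal(mean(sim$response == "Go"), 0.9, tolerance = 0.005)
  expect_identical(sim$response, ifelse(sim$draw < 0.9, "Go", "NoGo"))
})

test_that("AUC matches the rank-statistic formulation including ties", {
  pos <- c(0.9, 0.8, 0.7); neg <- c(0.2, 0.1, 0.05)
  expect_equal(callcat:::auc_scores(pos, neg), 1)
  expect_equal(callcat:::auc_scores(c(0.5, 0.5), c(0.5, 0.5)), 0.5)

  set.seed(5)
  for (i in 1:5) {
    p <- round(stats::runif(7), 1)   # rounding forces ties
    n <- round(stats::runif(9), 1)
    w <- stats::wilcox.test(p, n, exact = FALSE)
    auc_rank <- unname(w$statistic) / (length(p) * length(n))
    expect_equal(callcat:::auc_scores(p, n), auc_rank, tolerance = 1e-12)
  }
})

test_that("relative detection rates equal hand-computed fractions", {
  set.seed(33)
  V <- matrix(stats::rexp(10 * 40), 10, 40)
  cc <- toy_cochleagram(V)
  spans <- list(list(rows = 1:4, cols = 3:10), list(rows = 5:8, cols = 15:25))
  ms <- toy_mifset(cc, spans, thresholds = c(0.9, 0.9), weights = c(1, 1))
  other <- toy_cochleagram(matrix(stats::rexp(10 * 40), 10, 40))
  res <- relative_detection_rate(ms, list(cc, cc, other), list(other))
  # both MIFs are verbatim cuts of cc: detected in cc, almost surely not in
  # an independent exponential matrix
  manual_within <- rowMeans(cbind(c(1, 1), c(1, 1),
                                  sapply(ms$mifs, function(m)
                                    max_ncc(m, other) > m$threshold)))
  manual_outside <- sapply(ms$mifs, function(m) max_ncc(m, other) > m$threshold)
  expect_equal(res$relative_rate, manual_within - as.numeric(manual_outside))
  expect_true(all(res$bandwidth_oct > 0))
})

test_that("candidate sampling respects bounds and bookkeeping", {
  cochs <- fx_train_cochs()
  targets <- cochs[grep("^wheek", names(cochs))]
  cands <- sample_candidates(targets, n = 60, max_dur_ms = 200, seed = 9)
  expect_length(cands, 60)
  for (f in cands) {
    expect_lte(f$duration_ms, 200)
    expect_gte(f$duration_ms, 20)
    src <- targets[[f$source_call]]
    expect_identical(f$patch,
                     src$values[f$cf_lo:f$cf_hi,
                                f$offset[2]:(f$offset[2] + ncol(f$patch) - 1),
                                drop = FALSE])
  }
  short <- sample_candidates(targets, n = 25, max_dur_ms = 75, seed = 9)
  expect_true(all(vapply(short, `[[`, 0, "duration_ms") <= 75))

  c1 <- sample_candidates(targets, n = 10, seed = 4)
  c2 <- sample_candidates(targets, n = 10, seed = 4)
  expect_identical(c1, c2)
})

test_that("trained instantiations are disjoint, capped and reproducible", {
  models <- fx_models()
  for (ct in names(models)) {
    sets <- models[[ct]]
    expect_length(sets, 5)
    idx <- lapply(sets, `[[`, "selected_idx")
    expect_identical(anyDuplicated(unlist(idx)), 0L)
    for (s in sets) {
      expect_lte(length(s$mifs), 20)
      expect_gte(length(s$mifs), 1)
      expect_true(all(vapply(s$mifs, function(m) m$weight, 0) > 0))
      expect_true(all(vapply(s$mifs, function(m) m$merit, 0) >= 0))
      # ensemble MI trace is non-decreasing
      if (length(s$ensemble_mi_trace) > 1) {
        expect_true(all(diff(s$ensemble_mi_trace) >= -1e-12))
      }
    }
  }
  # reproducibility on a small re-run
  s1 <- train_instantiations(fx_corpus(), "wheek", n_instantiations = 2,
                             n_candidates = 60, seed = 77,
                             cochleagrams = fx_train_cochs())
  s2 <- train_instantiations(fx_corpus(), "wheek", n_instantiations = 2,
                             n_candidates = 60, seed = 77,
                             cochleagrams = fx_train_cochs())
  expect_equal(s1, s2)
})

test_that("MIF set JSON serialization round-trips", {
  ms <- fx_models()$chut[[1]]
  tmp <- tempfile(fileext = ".json")
  save_mifset(ms, tmp)
  back <- load_mifset(tmp)
  expect_equal(back$category, ms$category)
  expect_equal(back$training_auc, ms$training_auc)
  expect_length(back$mifs, length(ms$mifs))
  expect_equal(back$mifs[[1]]$threshold, ms$mifs[[1]]$threshold)
  expect_equal(back$mifs[[1]]$feature$patch, ms$mifs[[1]]$feature$patch)
})
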