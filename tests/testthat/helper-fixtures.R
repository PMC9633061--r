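# Shared fixtures, built once per test run and memoized. The corpus/model
# scale (4 categories x 8 train + 8 holdout exemplars, 500 candidate
# features, 5 instantiations) is the reduced desk scale used throughout.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_corpus <- function() memo("corpus", function() {
  generate_corpus(default_call_specs(), n_train = 8, n_holdout = 8, seed = 11)
})

fx_train_cochs <- function() memo("train_cochs", function() {
  calls <- corpus_calls(fx_corpus(), split = "train")
  cochs <- lapply(calls, compute_cochleagram)
  names(cochs) <- vapply(calls, function(cl) cl$exemplar_id, "")
  cochs
})

fx_holdout_cochs <- function() memo("holdout_cochs", function() {
  calls <- corpus_calls(fx_corpus(), split = "holdout")
  cochs <- lapply(calls, compute_cochleagram)
  names(cochs) <- vapply(calls, function(cl) cl$exemplar_id, "")
  cochs
})

fx_models <- function() memo("models", function() {
  cats <- c("chut", "purr", "wheek", "whine")
  models <- lapply(cats, function(ct) {
    train_instantiations(fx_corpus(), ct, n_instantiations = 5,
                         n_candidates = 500, seed = 21,
                         cochleagrams = fx_train_cochs())
  })
  names(models) <- cats
  models
})

# Independent mutual-information oracle on a 2x2 detection-by-class table
# (plain counting; bits). Used to check fit_feature and greedy selection.
oracle_mi <- function(det, is_target) {
  n <- length(det)
  p <- function(cond) sum(cond) / n
  mi <- 0
  for (d in c(TRUE, FALSE)) for (t in c(TRUE, FALSE)) {
    pj <- p(det == d & is_target == t)
    if (pj > 0) mi <- mi + pj * log2(pj / (p(det == d) * p(is_target == t)))
  }
  mi
}

# Brute-force normalized cross-correlation oracle: correlate the flattened
# patch against every aligned window with stats::cor.
oracle_max_ncc <- function(patch, values, cf_lo) {
  k <- nrow(patch); m <- ncol(patch)
  L <- ncol(values) - m + 1
  best <- -Inf
  for (t in seq_len(L)) {
    win <- values[cf_lo:(cf_lo + k - 1), t:(t + m - 1)]
    r <- suppressWarnings(stats::cor(as.vector(patch), as.vector(win)))
    if (is.na(r)) r <- 0
    best <- max(best, r)
  }
  best
}

# A small handmade mif_set over a toy cochleagram: mif i is cut verbatim
# from `coch` (so r_max = 1) with the given threshold and weight.
toy_mifset <- function(coch, spans, thresholds, weights, category = "toy") {
  mifs <- lapply(seq_along(thresholds), function(i) {
    sp <- spans[[i]]
    patch <- coch$values[sp$rows, sp$cols, drop = FALSE]
    structure(list(
      feature = structure(list(patch = patch, cf_lo = sp$rows[1],
                               cf_hi = sp$rows[length(sp$rows)],
                               duration_ms = length(sp$cols) /
                                 coch$frame_rate * 1000,
                               source_call = "toy",
                               offset = c(sp$rows[1], sp$cols[1])),
                          class = "candidate_feature"),
      threshold = thresholds[i], weight = weights[i], merit = 1),
      class = "mif")
  })
  structure(list(category = category, mifs = mifs, instantiation_index = 1L,
                 training_auc = NA_real_), class = "mif_set")
}

toy_cochleagram <- function(values, frame_rate = 1000) {
  structure(list(values = values,
                 cfs = seq(200, 20000, length.out = nrow(values)),
                 frame_rate = frame_rate, source_id = "toy", params = NULL),
            class = "cochleagram")
}
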