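# Paradigm layer: builds randomized Go/No-go trial lists matching the
# printed designs, executes them against a pair of trained model
# instantiations (target and distractor MIF sets), and pools the executed
# records into per-condition rate summaries and d' values.

#' Define a behavioral paradigm
#'
#' Known paradigms and their factorial designs (2 categories x
#' `n_exemplars` x conditions x `n_repetitions` unless noted):
#' `"generalization"` (1 condition), `"snr"` (blocked by SNR level),
#' `"segment"` (13 lengths -> 1040 trials), `"tempo"` (9 conditions ->
#' 720), `"f0"` (9 conditions -> 720), `"reverse"` (2 -> 160), `"lowpass"`
#' (2 -> 160), `"isi_control"` (regular/silent, 20 reps -> 640),
#' `"isi_random"` (5 rebuilt variants -> 400), `"chimeric"` (800 regular +
#' 400 chimeric catch trials, 50% of catch trials rewarded at random).
#'
#' @param name paradigm name (above).
#' @param condition_values conditions; defaults to the paradigm's printed
#'   list.
#' @param n_exemplars_per_category exemplars per category (default 8).
#' @param n_repetitions repetitions (default 5).
#' @param design `"randomized"` or `"block"` (blocks by condition; default
#'   for snr).
#' @param session_size trials per bookkeeping session (default 40).
#' @return a `paradigm_spec`.
#' @export
paradigm_spec <- function(name, condition_values = NULL,
                          n_exemplars_per_category = 8, n_repetitions = 5,
                          design = NULL, session_size = 40) {
  name <- match.arg(name, c("generalization", "snr", "segment", "tempo",
                            "f0", "reverse", "lowpass", "isi_control",
                            "isi_random", "chimeric"))
  if (is.null(condition_values)) {
    condition_values <- switch(name,
      generalization = list("natural"),
      snr      = as.list(c(Inf, 12, 6, 3, 0, -3, -6, -12, -18)),
      segment  = as.list(c(50, 75, 100, 125, 150, 175, 200, 300, 400, 500,
                           600, 700, 800)),
      tempo    = as.list(c(0, -120, -100, -80, -60, -30, 30, 60, 80)),
      f0       = as.list(c(0, -50, -40, -30, -20, 20, 40, 50, 100)),
      reverse  = list("natural", "reversed"),
      lowpass  = list("natural", "lowpass"),
      isi_control = list("regular", "silent"),
      isi_random  = list("random"),
      chimeric    = list("chimeric"))
  }
  if (is.null(design)) design <- if (name == "snr") "block" else "randomized"
  if (name == "isi_control" && n_repetitions == 5) n_repetitions <- 20
  structure(list(name = name, condition_values = condition_values,
                 n_exemplars_per_category = n_exemplars_per_category,
                 n_repetitions = n_repetitions, design = design,
                 session_size = session_size),
            class = "paradigm_spec")
}

#' Build a randomized, unexecuted trial list for a paradigm
#'
#' Full factorial over categories, exemplars, conditions and repetitions,
#' order randomized by `seed` (or blocked by condition for block designs).
#' The chimeric paradigm produces 2/3 regular trials and 1/3 chimeric
#' catch trials with 50% of catch trials flagged rewarded at random.
#'
#' @param spec a [paradigm_spec()].
#' @param go_category,nogo_category category labels.
#' @param seed integer seed for ordering, variant assignment and catch
#'   rewards.
#' @return data.frame of unexecuted trials: `paradigm`, `stimulus_type`
#'   ("Go"/"NoGo"), `category`, `exemplar`, `condition`, `variant`,
#'   `trial_class` ("regular"/"catch"), `rewarded`, `session_id`, `index`.
#' @export
build_trial_list <- function(spec, go_category = "chut",
                             nogo_category = "purr", seed = 1) {
  n_ex <- spec$n_exemplars_per_category
  conds <- spec$condition_values
  reps <- spec$n_repetitions
  cats <- c(go_category, nogo_category)

  if (spec$name == "chimeric") {
    # regular:catch = 2:1; at default sizes 2 x 8 x 50 = 800 regular trials
    regular <- expand.grid(category = cats, exemplar = seq_len(n_ex),
                           rep = seq_len(10 * reps),
                           stringsAsFactors = FALSE)
    regular$condition <- "natural"; regular$variant <- NA_integer_
    regular$trial_class <- "regular"
    catch <- expand.grid(category = cats, exemplar = seq_len(n_ex),
                         variant = 1:5, rep = seq_len(reps),
                         stringsAsFactors = FALSE)
    catch$condition <- "chimeric"; catch$trial_class <- "catch"
    grid <- rbind(regular[c("category", "exemplar", "condition", "variant",
                            "trial_class")],
                  catch[c("category", "exemplar", "condition", "variant",
                          "trial_class")])
  } else if (spec$name == "isi_random") {
    grid <- expand.grid(category = cats, exemplar = seq_len(n_ex),
                        variant = 1:5, rep = seq_len(reps),
                        stringsAsFactors = FALSE)
    grid$condition <- "random"; grid$trial_class <- "regular"
    grid <- grid[c("category", "exemplar", "condition", "variant",
                   "trial_class")]
  } else {
    grid <- expand.grid(category = cats, exemplar = seq_len(n_ex),
                        cond_i = seq_along(conds), rep = seq_len(reps),
                        stringsAsFactors = FALSE)
    grid$condition <- unlist(conds)[grid$cond_i]
    grid$variant <- NA_integer_
    grid$trial_class <- "regular"
    grid <- grid[c("category", "exemplar", "condition", "variant",
                   "trial_class")]
  }

  grid$stimulus_type <- ifelse(grid$category == go_category, "Go", "NoGo")
  n <- nrow(grid)
  grid <- with_seed(seed, {
    ord <- if (spec$design == "block" && spec$name != "chimeric") {
      # one condition per session block; block order and within-block
      # order both randomized
      blocks <- split(seq_len(n), match(grid$condition, unlist(conds)))
      unlist(lapply(sample(blocks), sample))
    } else sample.int(n)
    g <- grid[ord, ]
    g$rewarded <- g$trial_class == "regular" & g$stimulus_type == "Go"
    is_catch <- g$trial_class == "catch"
    if (any(is_catch)) {
      half <- sample(which(is_catch), round(sum(is_catch) / 2))
      g$rewarded[is_catch] <- FALSE
      g$rewarded[half] <- TRUE
    }
    g
  })
  grid$index <- seq_len(n)
  grid$session_id <- ceiling(grid$index / spec$session_size)
  grid$paradigm <- spec$name
  rownames(grid) <- NULL
  grid
}

# Manipulation spec for one trial of a paradigm.
trial_manipulation <- function(paradigm, condition, variant, seed) {
  switch(paradigm,
    generalization = manipulation_spec("none"),
    snr      = manipulation_spec("snr", as.numeric(condition), seed = seed),
    segment  = manipulation_spec("segment", as.numeric(condition)),
    tempo    = manipulation_spec("tempo", as.numeric(condition)),
    f0       = manipulation_spec("f0", as.numeric(condition)),
    reverse  = if (condition == "reversed") manipulation_spec("reverse")
               else manipulation_spec("none"),
    lowpass  = if (condition == "lowpass") manipulation_spec("lowpass", 3000)
               else manipulation_spec("none"),
    isi_control = if (condition == "silent")
                    manipulation_spec("isi", "silent")
                  else manipulation_spec("none"),
    isi_random  = manipulation_spec("isi", "random", seed = seed,
                                    variant = variant),
    chimeric    = if (condition == "chimeric")
                    manipulation_spec("isi", "chimeric", seed = seed,
                                      variant = variant)
                  else manipulation_spec("none"),
    stop("unknown paradigm: ", paradigm, call. = FALSE))
}

#' Execute a trial list against a trained model pair
#'
#' Each unique stimulus (category, exemplar, condition, variant) is
#' synthesized once: the manipulation is applied, the cochleagram computed,
#' and the feature-detection responses of every target and distractor MIF
#' set evaluated and cached. Each instantiation (paired target/distractor
#' set) is then treated as one subject: all trials are realized per subject
#' through the winner-take-all stage, stochastically
#' (`X < P(GO)`) or deterministically (Go iff evidence > 0).
#'
#' @param target_mifsets,distractor_mifsets lists of `mif_set` of equal
#'   length (instantiations).
#' @param trials trial list from [build_trial_list()].
#' @param corpus the `call_corpus` supplying exemplars.
#' @param split which corpus split supplies exemplars (default "train";
#'   the generalization paradigm uses "holdout").
#' @param params [cochleagram_params()].
#' @param seed integer seed for stochastic manipulations and responses.
#' @param deterministic logical; TRUE replaces the stochastic response
#'   stage by Go iff evidence > 0 (ties -> NoGo counted at P = 0.5 would be
#'   ambiguous, so an exact tie is scored NoGo).
#' @param p_min,p_max WTA Go-probability bounds.
#' @return data.frame of executed records: the trial columns plus
#'   `subject`, `target_resp`, `distractor_resp`, `evidence`,
#'   `go_probability`, `draw`, `response`, `outcome`.
#' @export
run_experiment <- function(target_mifsets, distractor_mifsets, trials,
                           corpus, split = "train",
                           params = cochleagram_params(), seed = 1,
                           deterministic = FALSE, p_min = 0.1, p_max = 0.9) {
  stopifnot(length(target_mifsets) == length(distractor_mifsets))
  n_inst <- length(target_mifsets)
  paradigm <- trials$paradigm[1]

  calls <- corpus_calls(corpus, split = split)
  names(calls) <- vapply(calls, function(cl) cl$exemplar_id, "")
  by_cat <- split(calls, vapply(calls, function(cl) cl$category, ""))
  cats <- unique(trials$category)
  # donor ISI pools (per category, from training calls)
  train_calls <- corpus_calls(corpus, split = "train")
  isi_pool <- lapply(cats, function(ct) {
    isi_values(Filter(function(cl) cl$category == ct, train_calls))
  })
  names(isi_pool) <- cats
  other_cat <- function(ct) cats[cats != ct][1]

  seeds <- derive_seeds(seed, nrow(trials) + 1)
  resp_seed <- seeds[length(seeds)]

  # evaluate unique stimuli once
  key <- paste(trials$category, trials$exemplar, trials$condition,
               trials$variant, sep = "|")
  uniq <- !duplicated(key)
  fd_cache <- new.env(parent = emptyenv())
  failed <- character(0)
  for (i in which(uniq)) {
    ct <- trials$category[i]
    ex <- by_cat[[ct]][[trials$exemplar[i]]]
    if (is.null(ex)) { failed <- c(failed, key[i]); next }
    mspec <- trial_manipulation(paradigm, trials$condition[i],
                                trials$variant[i], seeds[i])
    donor <- if (mspec$kind == "isi" && identical(mspec$parameter, "chimeric"))
      isi_pool[[other_cat(ct)]] else isi_pool[[ct]]
    stim <- tryCatch(apply_manipulation(ex, mspec, donor_isis = donor),
                     error = function(e) NULL)
    if (is.null(stim)) { failed <- c(failed, key[i]); next }
    cc <- compute_cochleagram(stim, params)
    assign(key[i], list(
      t = vapply(target_mifsets, function(m) fd_response(m, cc), 0),
      d = vapply(distractor_mifsets, function(m) fd_response(m, cc), 0)),
      envir = fd_cache)
  }

  out <- do.call(rbind, lapply(seq_len(n_inst), function(s) {
    df <- trials
    df$subject <- s
    fd <- lapply(key, function(k) {
      if (exists(k, envir = fd_cache)) get(k, envir = fd_cache) else NULL
    })
    ok <- !vapply(fd, is.null, TRUE)
    df$flagged <- !ok
    df$target_resp <- NA_real_; df$distractor_resp <- NA_real_
    df$target_resp[ok] <- vapply(fd[ok], function(x) x$t[s], 0)
    df$distractor_resp[ok] <- vapply(fd[ok], function(x) x$d[s], 0)
    df
  }))
  out$evidence <- out$target_resp - out$distractor_resp
  out$go_probability <- wta_decide(out$target_resp, out$distractor_resp,
                                   p_min, p_max)
  if (deterministic) {
    out$draw <- NA_real_
    out$response <- ifelse(out$evidence > 0, "Go", "NoGo")
  } else {
    sim <- simulate_response(out$go_probability, seed = resp_seed)
    out$draw <- sim$draw
    out$response <- sim$response
  }
  out$response[is.na(out$evidence)] <- NA_character_
  out$outcome <- ifelse(out$trial_class == "catch", "catch",
    ifelse(out$stimulus_type == "Go",
           ifelse(out$response == "Go", "hit", "miss"),
           ifelse(out$response == "Go", "FA", "CR")))
  rownames(out) <- NULL
  out
}

#' Pool executed records into per-condition rate summaries and d'
#'
#' Pools hits and false alarms per (subject, condition) over all regular
#' trials, applies the default rate clamps, and computes d'. Catch and
#' flagged trials are excluded.
#'
#' @param records executed records from [run_experiment()].
#' @param floor,ceiling rate clamps.
#' @return data.frame with columns `subject`, `paradigm`,
#'   `condition_value`, `condition_sign`, `n_go`, `n_nogo`, `hits`, `fas`,
#'   `hit_rate`, `fa_rate`, `dprime`.
#' @export
summarize_trials <- function(records, floor = 0.01, ceiling = 0.99) {
  r <- records[records$trial_class == "regular" &
                 !is.na(records$response), ]
  if ("flagged" %in% names(r)) r <- r[!r$flagged, ]
  keys <- unique(r[c("subject", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- r[r$subject == keys$subject[i] & r$condition == keys$condition[i], ]
    go <- sub[sub$stimulus_type == "Go", ]
    ng <- sub[sub$stimulus_type == "NoGo", ]
    if (nrow(go) == 0 || nrow(ng) == 0) {
      stop("condition needs both Go and No-go trials", call. = FALSE)
    }
    rs <- rate_summary(sum(go$response == "Go"), nrow(go),
                       sum(ng$response == "Go"), nrow(ng),
                       floor = floor, ceiling = ceiling)
    num <- suppressWarnings(as.numeric(keys$condition[i]))
    data.frame(subject = keys$subject[i], paradigm = sub$paradigm[1],
               condition_value = keys$condition[i],
               condition_sign = if (is.na(num)) NA_real_ else sign(num),
               n_go = rs$n_go_trials, n_nogo = rs$n_nogo_trials,
               hits = rs$hits, fas = rs$false_alarms,
               hit_rate = rs$hit_rate, fa_rate = rs$fa_rate,
               dprime = dprime(rs))
  })
  out <- do.call(rbind, rows)
  out[order(out$subject), ]
}
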