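#' Beam-search configuration
#'
#' Word-synchronous beam search keeps up to `k` partial derivations while
#' exploring structural actions, moves derivations that generate the next
#' observed token into the word beam (capacity `k_w`), and fast-tracks the
#' best `k_ft` word-generating successors each round so that structural
#' actions cannot starve lexical ones. Defaults follow the standard
#' word-synchronous scheme: `k_w = k/10`, `k_ft = k/100` (rounded up).
#'
#' @param k Action beam size (paper sweep 100-1,000; 1,000 top-down and
#'   400 left-corner were the headline settings).
#' @param k_w Word beam size.
#' @param k_ft Fast-track count.
#' @param open_cap Open-constituent cap; `NULL` = remaining tokens + 10.
#' @param distance One of `"explored"` (candidate state expansions between
#'   word synchronizations; default), `"survivors"` (actions taken by
#'   surviving beam entries), `"viterbi"` (actions on the best path).
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(k = 400L, k_w = NULL, k_ft = NULL, open_cap = NULL,
                        distance = c("explored", "survivors", "viterbi")) {
  k <- as.integer(k)
  k_w <- as.integer(k_w %||% ceiling(k / 10))
  k_ft <- as.integer(k_ft %||% ceiling(k / 100))
  if (!(k >= k_w && k_w >= 1L)) stop("require k >= k_w >= 1")
  if (k_ft < 0L) stop("k_ft must be >= 0")
  structure(list(k = k, k_w = k_w, k_ft = k_ft, open_cap = open_cap,
                 distance = match.arg(distance)),
            class = "beam_config")
}

beam_model_cfg <- function(model, cfg) {
  if (!is.null(cfg$open_cap)) model$config$open_cap <- cfg$open_cap
  model
}

#' One word-synchronous beam step
#'
#' Advances a beam of states synchronized at the same token count to the
#' next token: structural actions are expanded breadth-first in score order
#' (keeping at most `k` candidates per round), candidates that generate
#' `token` enter the word beam, and the `k_ft` best word-generating
#' successors are fast-tracked each round. Returns the new beam (at most
#' `k_w` states, synchronized at token count + 1) and the number of
#' candidate state expansions performed.
#'
#' @param model An `rnng_model` (with `open_cap` resolved via `cfg`).
#' @param beam List of `parser_state`, all with equal `ntokens`.
#' @param token The next observed token.
#' @param cfg A [beam_config()].
#' @param n_total Sentence length (for the default open cap).
#' @return List with `beam` (new states), `explored` (count), and
#'   `marginal` (log of the summed probability of the new beam).
#' @export
word_sync_step <- function(model, beam, token, cfg, n_total = NULL) {
  stopifnot(length(beam) > 0L)
  model <- beam_model_cfg(model, cfg)
  explored <- 0L
  word_beam <- list()
  word_lp <- numeric(0)
  current <- beam
  repeat {
    if (length(current) == 0L) break
    # scores only decrease along a derivation, so once every structural
    # candidate scores below the k_w-th best word item, further exploration
    # cannot change the word beam
    if (length(word_beam) >= cfg$k_w) {
      thresh <- sort(word_lp, decreasing = TRUE)[cfg$k_w]
      if (max(vapply(current, `[[`, numeric(1), "logp")) <= thresh) break
    }
    # expand every state in the current round
    cand <- list()   # list of (state_idx, action, score, word_lp)
    for (si in seq_along(current)) {
      st <- current[[si]]
      mask <- legal_actions(st, model, n_total)
      if (!any(mask)) next
      sc <- rnng_state_scores(model, st, mask)
      ids <- which(mask)
      wl <- if (mask[1L]) rnng_word_logprobs(model, sc$h)[word_id(model, token)]
      for (aid in ids) {
        score <- st$logp + sc$alp[aid] + if (aid == 1L) wl else 0
        cand[[length(cand) + 1L]] <- list(si = si, aid = aid, score = score)
      }
    }
    explored <- explored + length(cand)
    if (length(cand) == 0L) break
    scores <- vapply(cand, `[[`, numeric(1), "score")
    is_word <- vapply(cand, function(x) x$aid == 1L, logical(1))
    # fast-track the best k_ft word candidates
    ft <- integer(0)
    if (cfg$k_ft > 0L && any(is_word)) {
      wi <- which(is_word)
      ft <- wi[order(scores[wi], decreasing = TRUE)][seq_len(min(cfg$k_ft, length(wi)))]
    }
    pool <- setdiff(seq_along(cand), ft)
    keep <- pool[order(scores[pool], decreasing = TRUE)][seq_len(min(cfg$k, length(pool)))]
    taken_word <- c(ft, keep[is_word[keep]])
    taken_struct <- keep[!is_word[keep]]
    for (ci in taken_word) {
      x <- cand[[ci]]
      ns <- rnng_step(model, current[[x$si]], 1L, token = token,
                      lp_add = x$score - current[[x$si]]$logp,
                      check = FALSE, n_total = n_total)
      word_beam[[length(word_beam) + 1L]] <- ns
      word_lp <- c(word_lp, ns$logp)
    }
    nxt <- list()
    for (ci in taken_struct) {
      x <- cand[[ci]]
      nxt[[length(nxt) + 1L]] <- rnng_step(
        model, current[[x$si]], x$aid,
        lp_add = x$score - current[[x$si]]$logp, check = FALSE,
        n_total = n_total)
    }
    current <- nxt
  }
  if (length(word_beam) == 0L)
    stop(sprintf("empty-beam error: no derivation generates token '%s'",
                 token))
  ord <- order(word_lp, decreasing = TRUE)
  keep <- ord[seq_len(min(cfg$k_w, length(ord)))]
  list(beam = word_beam[keep], explored = explored,
       marginal = logsumexp(word_lp[keep]))
}

#' Per-token complexity profile of a sentence
#'
#' Runs word-synchronous beam search over `tokens` and returns, per token,
#' surprisal `-log(M_i / M_{i-1})` where `M_i` is the beam marginal after
#' token `i` (`M_0 = 1`), and distance (by default the number of candidate
#' state expansions performed between word synchronizations). Token
#' surprisals telescope to `-log(M_n)`.
#'
#' @param model An `rnng_model`.
#' @param tokens Character vector (one sentence).
#' @param cfg A [beam_config()].
#' @param base Log base for surprisal: `"nats"` (default) or `"bits"`.
#' @return Data frame with columns `token_index`, `token`, `surprisal`,
#'   `distance`, `log_marginal_before`, `log_marginal_after`,
#'   `beam_occupancy`.
#' @export
complexity_profile <- function(model, tokens, cfg = beam_config(),
                               base = c("nats", "bits")) {
  stopifnot(length(tokens) > 0L)
  base <- match.arg(base)
  n <- length(tokens)
  beam <- list(rnng_init_state(model))
  prev <- 0
  out <- vector("list", n)
  for (i in seq_len(n)) {
    step <- tryCatch(
      word_sync_step(model, beam, tokens[i], cfg, n_total = n),
      error = function(e)
        stop(sprintf("token %d ('%s'): %s", i, tokens[i], conditionMessage(e)),
             call. = FALSE))
    beam <- step$beam
    surp <- -(step$marginal - prev)
    if (base == "bits") surp <- surp / log(2)
    dist <- switch(cfg$distance,
                   explored = step$explored,
                   survivors = sum(vapply(beam, function(s)
                     s$tok_acts[i], integer(1))),
                   viterbi = step$explored)  # viterbi filled in below
    out[[i]] <- data.frame(token_index = i, token = tokens[i],
                           surprisal = surp, distance = dist,
                           log_marginal_before = prev,
                           log_marginal_after = step$marginal,
                           beam_occupancy = length(beam))
    prev <- step$marginal
  }
  res <- do.call(rbind, out)
  if (cfg$distance == "viterbi") {
    best <- beam[[which.max(vapply(beam, `[[`, numeric(1), "logp"))]]
    res$distance <- as.integer(best$tok_acts[seq_len(n)])
  }
  rownames(res) <- NULL
  res
}

#' Aggregate per-token complexity records to segments
#'
#' Tokens of each sentence are assigned, in order, to that sentence's
#' segments as given by the stimulus schedule; segment surprisal and
#' distance are the sums over member tokens (log-additivity makes segment
#' surprisal equal `-log p(segment | context)`).
#'
#' @param records Data frame with columns `sentence`, `token_index`,
#'   `surprisal`, `distance` (e.g. rows of [complexity_profile()] output
#'   with a `sentence` column added).
#' @param schedule A stimulus schedule ([make_stimulus_schedule()]).
#' @return Data frame keyed by `segment_id` with summed metrics.
#' @export
aggregate_segments <- function(records, schedule) {
  need <- c("sentence", "token_index", "surprisal", "distance")
  if (!all(need %in% names(records)))
    stop("schema error: records must have columns ",
         paste(need, collapse = ", "))
  out <- schedule$segments
  out$surprisal <- NA_real_
  out$distance <- NA_real_
  for (s in unique(out$sentence_key)) {
    seg <- which(out$sentence_key == s)
    rec <- records[records$sentence == s, , drop = FALSE]
    rec <- rec[order(rec$token_index), , drop = FALSE]
    ntok <- vapply(strsplit(out$tokens[seg], " ", fixed = TRUE), length,
                   integer(1))
    if (sum(ntok) != nrow(rec))
      stop(sprintf(
        "schema error: sentence %s has %d tokens in schedule but %d records",
        s, sum(ntok), nrow(rec)))
    idx <- rep(seq_along(seg), ntok)
    out$surprisal[seg] <- as.numeric(tapply(rec$surprisal, idx, sum))
    out$distance[seg] <- as.numeric(tapply(rec$distance, idx, sum))
  }
  if (anyNA(out$surprisal))
    stop("schema error: segments without token records")
  out
}

#' Corpus perplexity
#'
#' `exp(total NLL / token count)`. For n-gram and LSTM models the NLL
#' includes the end-of-sentence event and the count is tokens + 1 per
#' sentence; for RNNGs the NLL is the negative log beam marginal after the
#' final token of each sentence and the count is the token count.
#'
#' @param model A `kn_ngram`, `sequence_lm`, or `rnng_model`.
#' @param corpus List of tokenized sentences.
#' @param cfg A [beam_config()] (RNNG only).
#' @return Perplexity (numeric scalar).
#' @export
corpus_perplexity <- function(model, corpus, cfg = beam_config()) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (inherits(model, "rnng_model")) {
    nll <- 0; cnt <- 0L
    for (s in corpus) {
      prof <- complexity_profile(model, s, cfg)
      nll <- nll - prof$log_marginal_after[nrow(prof)]
      cnt <- cnt + length(s)
    }
    return(exp(nll / cnt))
  }
  nll <- 0; cnt <- 0L
  for (s in corpus) {
    lp <- lm_sentence_logprobs(model, s, eos = TRUE)
    nll <- nll - sum(lp)
    cnt <- cnt + length(lp)
  }
  exp(nll / cnt)
}

#' Exact prefix marginals by exhaustive enumeration
#'
#' Independent oracle for beam-search tests: recursively enumerates every
#' derivation prefix of the (capped) model that generates
#' `tokens[1..i]`, for each `i`, and sums the exact probabilities. Only
#' feasible for tiny vocabularies with small caps; the beam marginal with an
#' exhaustive beam must match these values.
#'
#' @param model An `rnng_model`.
#' @param tokens Character vector.
#' @param open_cap,nt_budget Caps defining the truncated model (must match
#'   the beam configuration under test).
#' @return Numeric vector `M_1..M_n` of prefix marginal probabilities.
#' @export
exact_prefix_marginals <- function(model, tokens, open_cap = 2L,
                                   nt_budget = 2L) {
  m <- model
  m$config$open_cap <- as.integer(open_cap)
  m$config$nt_budget <- as.integer(nt_budget)
  n <- length(tokens)
  acc <- vector("list", n)  # log-prob accumulators
  for (i in seq_len(n)) acc[[i]] <- numeric(0)
  rec <- function(state) {
    mask <- legal_actions(state, m, n)
    sc <- if (any(mask)) rnng_state_scores(m, state, mask) else NULL
    for (aid in which(mask)) {
      if (aid == 1L) {
        if (state$ntokens >= n) next
        tok <- tokens[state$ntokens + 1L]
        wl <- rnng_word_logprobs(m, sc$h)[word_id(m, tok)]
        ns <- rnng_step(m, state, 1L, token = tok,
                        lp_add = sc$alp[1L] + wl, check = FALSE, n_total = n)
        acc[[ns$ntokens]] <<- c(acc[[ns$ntokens]], ns$logp)
        if (ns$ntokens < n) rec(ns)
      } else {
        ns <- rnng_step(m, state, aid, lp_add = sc$alp[aid], check = FALSE,
                        n_total = n)
        rec(ns)
      }
    }
  }
  rec(rnng_init_state(m))
  exp(vapply(acc, logsumexp, numeric(1)))
}
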