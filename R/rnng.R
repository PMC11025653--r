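#' Recurrent neural network grammar (RNNG)
#'
#' A generative parser that jointly models a sentence and its constituency
#' tree as a sequence of GEN/NT/REDUCE actions. The partial parse lives on a
#' stack encoded by a stack LSTM: pushing an element advances the LSTM from
#' the state below it, popping reverts to the remembered state. On REDUCE
#' the completed constituent's element vectors are collapsed by the
#' composition function: a bidirectional LSTM reads `[label, children...]`
#' forwards and backwards and the two final states are combined by an affine
#' map plus tanh into a single vector that replaces the children on the
#' stack.
#'
#' Two transition strategies are supported. Top-down announces a constituent
#' (`NT`) before any of its children. Left-corner announces it immediately
#' after its first child is completed: `NT` pops that child and re-pushes it
#' inside the newly opened constituent.
#'
#' @param width Hidden/embedding width (desk default 64; full scale 256).
#' @param layers Stack-LSTM layers (desk default 1; full scale 2).
#' @param epochs,lr Training epochs and Adam learning rate.
#' @param nt_budget Maximum number of NT actions between two consecutive
#'   GENs (bounds unary chains so search always terminates).
#' @param open_cap Maximum number of simultaneously open constituents;
#'   `NULL` means "remaining tokens + 10", resolved per state.
#' @return `rnng_config()` returns a list of class `rnng_config`.
#' @export
rnng_config <- function(width = 64L, layers = 1L, epochs = 30L, lr = 1e-3,
                        nt_budget = 10L, open_cap = NULL) {
  structure(list(width = as.integer(width), layers = as.integer(layers),
                 epochs = as.integer(epochs), lr = lr,
                 nt_budget = as.integer(nt_budget), open_cap = open_cap),
            class = "rnng_config")
}

rnng_shapes <- function(nw, nnt, cfg) {
  w <- cfg$width
  sh <- list(E_w = c(nw, w), E_nt = c(nnt, w),
             W_act = c(2L + nnt, w), b_act = 2L + nnt,
             W_word = c(nw, w), b_word = nw,
             W_comp = c(w, 2L * w), b_comp = w,
             h_empty = w)
  for (l in seq_len(cfg$layers)) {
    sh <- c(sh, lstm_param_shapes(paste0("stack", l), w, w))
    sh <- c(sh, lstm_param_shapes(paste0("cf", l), w, w))
    sh <- c(sh, lstm_param_shapes(paste0("cb", l), w, w))
  }
  sh
}

#' Construct an (untrained) RNNG
#'
#' @param words Character vector of terminal vocabulary (must include
#'   `"<unk>"`).
#' @param nts Character vector of nonterminal labels.
#' @param strategy `"top_down"` or `"left_corner"`.
#' @param config An [rnng_config()].
#' @param seed Seed for parameter initialization.
#' @return Object of class `rnng_model`.
#' @export
rnng_model <- function(words, nts, strategy, config = rnng_config(),
                       seed = 1L) {
  strategy <- match.arg(strategy, c("top_down", "left_corner"))
  if (!"<unk>" %in% words) words <- c("<unk>", words)
  store <- param_store(rnng_shapes(length(words), length(nts), config),
                       seed = sub_seed(seed, "rnng-init"))
  for (l in seq_len(config$layers)) {
    lstm_init_forget_bias(store, paste0("stack", l), config$width)
    lstm_init_forget_bias(store, paste0("cf", l), config$width)
    lstm_init_forget_bias(store, paste0("cb", l), config$width)
  }
  structure(list(words = words, nts = nts, strategy = strategy,
                 config = config, params = store),
            class = "rnng_model")
}

word_id <- function(model, token) {
  i <- match(token, model$words)
  if (is.na(i)) 1L else i  # <unk>
}

# actions: 1 = GEN, 2 = REDUCE, 2 + j = NT(nts[j])
N_FIXED_ACTIONS <- 2L

#' Initial parser state
#'
#' A parser state holds the stack (elements with their stack-LSTM states),
#' the number of open constituents, tokens generated so far, the count of NT
#' actions since the last GEN, and the cumulative log probability.
#'
#' @param model An `rnng_model`.
#' @return Object of class `parser_state`.
#' @export
rnng_init_state <- function(model) {
  structure(list(stack = list(), open = 0L, ntokens = 0L,
                 nt_since_gen = 0L, logp = 0, tok_acts = integer(0)),
            class = "parser_state")
}

state_finished <- function(state) {
  length(state$stack) == 1L && state$open == 0L && state$ntokens >= 1L &&
    state$stack[[1L]]$kind == "closed"
}

resolve_open_cap <- function(cfg, n_total, ntokens) {
  if (!is.null(cfg$open_cap)) return(as.integer(cfg$open_cap))
  max(n_total - ntokens, 0L) + 10L
}

#' Legal actions of a parser state
#'
#' Top-down: `NT` is legal unless the open-constituent cap (or the NT
#' budget) is reached; `GEN` requires at least one open constituent;
#' `REDUCE` requires an open constituent with at least one completed child
#' (so never immediately after `NT`). Left-corner: `GEN` is legal at the
#' start or while a constituent is open; `NT` requires a completed item on
#' top of the stack (the left corner); `REDUCE` closes the innermost open
#' constituent (which always already contains its left corner, so unary
#' constituents are permitted). A state whose stack holds exactly one
#' completed constituent is terminal: no action is legal.
#'
#' @param state A `parser_state`.
#' @param model An `rnng_model` (supplies strategy and caps).
#' @param n_total Total sentence length used to resolve the default open cap
#'   (`NULL` uses an effectively unbounded cap only if `open_cap` is set).
#' @return Logical mask over the action inventory
#'   `(GEN, REDUCE, NT(label1), ...)`.
#' @export
legal_actions <- function(state, model, n_total = NULL) {
  cfg <- model$config
  nnt <- length(model$nts)
  mask <- logical(N_FIXED_ACTIONS + nnt)
  cap <- resolve_open_cap(cfg, n_total %||% (state$ntokens + 1e6), state$ntokens)
  top <- if (length(state$stack) > 0L)
    state$stack[[length(state$stack)]] else NULL
  nt_ok <- state$open < cap && state$nt_since_gen < cfg$nt_budget
  if (model$strategy == "top_down") {
    # a single completed constituent is absorbing under top-down: opening a
    # new nonterminal beside it could never be reduced into one root
    if (state_finished(state)) return(mask)
    mask[1L] <- state$open >= 1L
    mask[2L] <- state$open >= 1L && !is.null(top) && top$kind != "open"
    if (nt_ok) mask[N_FIXED_ACTIONS + seq_len(nnt)] <- TRUE
  } else {
    # left-corner: a completed root may still become the left corner of a
    # larger constituent, so NT stays legal and stopping is implicit
    mask[1L] <- length(state$stack) == 0L || state$open >= 1L
    mask[2L] <- state$open >= 1L && !is.null(top) && top$kind != "open"
    if (nt_ok && !is.null(top) && top$kind != "open")
      mask[N_FIXED_ACTIONS + seq_len(nnt)] <- TRUE
  }
  mask
}

# push an element (list with kind/label/tree/vec) onto the stack, advancing
# the stack LSTM from the states of the element below
stack_push <- function(model, state, elem, tape = NULL) {
  store <- model$params
  cfg <- model$config
  below <- if (length(state$stack) > 0L)
    state$stack[[length(state$stack)]]$states
  else lstm_zero_states(cfg$layers, cfg$width)
  st <- lstm_stack_step(tape, store, "stack", elem$vec, below, cfg$width)
  elem$states <- st$states
  elem$h <- st$h
  state$stack[[length(state$stack) + 1L]] <- elem
  state
}

state_top_h <- function(model, state, tape = NULL) {
  if (length(state$stack) == 0L)
    ad_param(tape, model$params, "h_empty")
  else state$stack[[length(state$stack)]]$h
}

rnng_compose <- function(model, nt_index, child_vecs, tape = NULL) {
  store <- model$params
  cfg <- model$config
  lab <- ad_embed(tape, ad_param(tape, store, "E_nt"), nt_index)
  seqv <- c(list(lab), child_vecs)
  fwd <- lstm_zero_states(cfg$layers, cfg$width)
  for (x in seqv) {
    st <- lstm_stack_step(tape, store, "cf", x, fwd, cfg$width)
    fwd <- st$states; hf <- st$h
  }
  bwd <- lstm_zero_states(cfg$layers, cfg$width)
  for (x in rev(seqv)) {
    st <- lstm_stack_step(tape, store, "cb", x, bwd, cfg$width)
    bwd <- st$states; hb <- st$h
  }
  both <- ad_concat(tape, list(hf, hb))
  ad_affine_tanh(tape, ad_param(tape, store, "W_comp"),
                 ad_param(tape, store, "b_comp"), both)
}

#' Apply one action to a parser state
#'
#' Structural transition only; the caller supplies the log-probability
#' increment (`lp_add`) so that training and beam search can score actions
#' however they need. Errors if the action is illegal in `state`.
#'
#' @param model An `rnng_model`.
#' @param state A `parser_state`.
#' @param action_id Integer action id (1 = GEN, 2 = REDUCE, 2+j = NT j).
#' @param token Terminal token, required for GEN.
#' @param lp_add Log-probability increment added to the state's cumulative
#'   log probability.
#' @param tape Optional autodiff tape (training path).
#' @param check Verify legality (default TRUE).
#' @param n_total Sentence length for cap resolution.
#' @return The successor `parser_state`.
#' @export
rnng_step <- function(model, state, action_id, token = NULL, lp_add = 0,
                      tape = NULL, check = TRUE, n_total = NULL) {
  if (check) {
    mask <- legal_actions(state, model, n_total)
    if (!mask[action_id])
      stop(sprintf("contract violation: action %d illegal in state (%d tokens, %d open)",
                   action_id, state$ntokens, state$open))
  }
  store <- model$params
  # actions between word boundaries are attributed to the upcoming token
  ai <- state$ntokens + 1L
  if (length(state$tok_acts) < ai) state$tok_acts <- c(state$tok_acts,
    integer(ai - length(state$tok_acts)))
  state$tok_acts[ai] <- state$tok_acts[ai] + 1L
  if (action_id == 1L) {            # GEN
    wi <- word_id(model, token)
    vec <- ad_embed(tape, ad_param(tape, store, "E_w"), wi)
    state <- stack_push(model, state, list(kind = "tok", tree = token,
                                           vec = vec), tape)
    state$ntokens <- state$ntokens + 1L
    state$nt_since_gen <- 0L
  } else if (action_id == 2L) {     # REDUCE
    n <- length(state$stack)
    j <- n
    while (j >= 1L && state$stack[[j]]$kind != "open") j <- j - 1L
    kids <- if (j < n) state$stack[(j + 1L):n] else list()
    marker <- state$stack[[j]]
    state$stack <- state$stack[seq_len(j - 1L)]
    vec <- rnng_compose(model, marker$nt_index, lapply(kids, `[[`, "vec"),
                        tape)
    tree <- syntax_tree(marker$label, lapply(kids, `[[`, "tree"))
    state <- stack_push(model, state, list(kind = "closed", label = marker$label,
                                           tree = tree, vec = vec), tape)
    state$open <- state$open - 1L
  } else {                          # NT
    j <- action_id - N_FIXED_ACTIONS
    lab <- model$nts[j]
    vec <- ad_embed(tape, ad_param(tape, store, "E_nt"), j)
    if (model$strategy == "left_corner") {
      n <- length(state$stack)
      corner <- state$stack[[n]]
      state$stack <- state$stack[seq_len(n - 1L)]
      state <- stack_push(model, state, list(kind = "open", label = lab,
                                             nt_index = j, vec = vec), tape)
      state <- stack_push(model, state, list(kind = corner$kind,
                                             label = corner$label,
                                             tree = corner$tree,
                                             vec = corner$vec), tape)
    } else {
      state <- stack_push(model, state, list(kind = "open", label = lab,
                                             nt_index = j, vec = vec), tape)
    }
    state$open <- state$open + 1L
    state$nt_since_gen <- state$nt_since_gen + 1L
  }
  state$logp <- state$logp + lp_add
  state
}

# masked action log-probabilities and word log-probabilities at a state
# (numeric; inference path)
rnng_state_scores <- function(model, state, mask) {
  store <- model$params
  h <- state_top_h(model, state, NULL)
  alogits <- as.vector(store$val$W_act %*% h) + store$val$b_act
  alp <- masked_log_softmax(alogits, mask)
  list(alp = alp, h = h)
}

rnng_word_logprobs <- function(model, h) {
  store <- model$params
  masked_log_softmax(as.vector(store$val$W_word %*% h) + store$val$b_word)
}

#' Negative log-likelihood of a tree's gold derivation
#'
#' Scores the oracle action sequence of `tree` under the model's strategy:
#' sum of masked-softmax action NLLs plus word NLLs at GEN steps. With a
#' `tape` this is the differentiable training objective.
#'
#' @param model An `rnng_model`.
#' @param tree A `syntax_tree`.
#' @param tape Optional autodiff tape.
#' @return List with `nll` (node or numeric), `n_actions`, `n_tokens`.
#' @export
rnng_tree_nll <- function(model, tree, tape = NULL) {
  seq <- derivation_oracle(tree, model$strategy)
  n_total <- length(tree_yield(tree))
  store <- model$params
  state <- rnng_init_state(model)
  nll <- NULL
  for (i in seq_along(seq$actions)) {
    a <- seq$actions[[i]]
    aid <- switch(a$type, GEN = 1L, REDUCE = 2L,
                  NT = N_FIXED_ACTIONS + match(a$arg, model$nts))
    if (is.na(aid))
      stop("data error: tree uses unknown nonterminal ", a$arg)
    mask <- legal_actions(state, model, n_total)
    if (!mask[aid])
      stop(sprintf("data error: gold action %d (%s) illegal at step %d",
                   aid, a$type, i))
    h <- state_top_h(model, state, tape)
    term <- ad_affine_pick_nll(tape, ad_param(tape, store, "W_act"),
                               ad_param(tape, store, "b_act"), h, aid, mask)
    if (a$type == "GEN") {
      term <- ad_add(tape, term,
                     ad_affine_pick_nll(tape, ad_param(tape, store, "W_word"),
                                        ad_param(tape, store, "b_word"), h,
                                        word_id(model, a$arg)))
    }
    nll <- if (is.null(nll)) term else ad_add(tape, nll, term)
    state <- rnng_step(model, state, aid, token = if (a$type == "GEN") a$arg,
                       lp_add = -ad_val(term), tape = tape, check = FALSE)
  }
  list(nll = nll, n_actions = length(seq$actions),
       n_tokens = n_total)
}

#' Joint log probability of (tree, sentence) under the model
#' @inheritParams rnng_tree_nll
#' @return Numeric log probability (`<= 0`).
#' @export
rnng_tree_logprob <- function(model, tree) {
  -ad_val(rnng_tree_nll(model, tree, NULL)$nll)
}

#' Train an RNNG on a treebank
#'
#' Converts each tree to its oracle action sequence under `strategy` and
#' minimizes the summed action + word NLL with Adam (one update per tree).
#' The returned model is tagged with its strategy; `history` holds per-epoch
#' mean per-action NLL.
#'
#' @param treebank List of `syntax_tree`.
#' @param strategy `"top_down"` or `"left_corner"`.
#' @param config An [rnng_config()].
#' @param seed Integer seed.
#' @param min_count Words rarer than this in the yields become `<unk>`.
#' @return A trained `rnng_model`.
#' @export
train_rnng <- function(treebank, strategy, config = rnng_config(), seed = 1L,
                       min_count = 2L) {
  stopifnot(length(treebank) >= 1L)
  yields <- lapply(treebank, tree_yield)
  counts <- table(unlist(yields, use.names = FALSE))
  words <- c("<unk>", sort(names(counts)[counts >= min_count]))
  labs <- unique(unlist(lapply(treebank, function(t) {
    rec <- function(x) if (is_terminal(x)) character(0) else
      c(x$label, unlist(lapply(x$children, rec)))
    rec(t)
  })))
  model <- rnng_model(words, sort(labs), strategy, config, seed)
  store <- model$params
  history <- numeric(config$epochs)
  rng <- local_rng(sub_seed(seed, "rnng-shuffle"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(treebank))
    tot <- 0; cnt <- 0L
    for (ti in ord) {
      tape <- ad_tape()
      fw <- rnng_tree_nll(model, treebank[[ti]], tape)
      loss <- ad_val(fw$nll)
      if (!is.finite(loss)) stop("training error: non-finite loss")
      grads <- ad_param_grads(tape, ad_backward(tape, fw$nll), store)
      adam_step(store, grads, lr = config$lr)
      tot <- tot + loss; cnt <- cnt + fw$n_actions
    }
    history[ep] <- tot / cnt
  }
  model$history <- history
  model
}
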