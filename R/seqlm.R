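#' Configuration for the recurrent sequence language model
#'
#' Desk-scale defaults (width 64, 1 layer) keep tests fast; `width = 256`,
#' `layers = 2` reproduce the full-scale architecture.
#'
#' @param width Hidden and input (embedding) dimension.
#' @param layers Number of recurrent (LSTM) layers.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @return A list of class `seqlm_config`.
#' @export
seqlm_config <- function(width = 64L, layers = 1L, epochs = 30L, lr = 1e-3) {
  structure(list(width = as.integer(width), layers = as.integer(layers),
                 epochs = as.integer(epochs), lr = lr),
            class = "seqlm_config")
}

seqlm_shapes <- function(V, cfg) {
  sh <- list(E = c(V, cfg$width),
             W_out = c(V, cfg$width), b_out = V)
  for (l in seq_len(cfg$layers))
    sh <- c(sh, lstm_param_shapes(paste0("lstm", l),
                                  cfg$width, cfg$width))
  sh
}

# forward over one sentence; returns total NLL (node if tape) and count of
# predicted tokens (each real token plus </s>, conditioned from <s>)
seqlm_sentence_nll <- function(model, tokens, tape = NULL) {
  cfg <- model$config
  store <- model$params
  v <- model$vocab
  ids <- vocab_map(v, tokens)
  bos <- match(v$bos, v$tokens)
  eos <- match(v$eos, v$tokens)
  inputs <- c(bos, ids)
  targets <- c(ids, eos)
  E <- ad_param(tape, store, "E")
  W_out <- ad_param(tape, store, "W_out")
  b_out <- ad_param(tape, store, "b_out")
  states <- lstm_zero_states(cfg$layers, cfg$width)
  nll <- NULL
  for (i in seq_along(inputs)) {
    x <- ad_embed(tape, E, inputs[i])
    st <- lstm_stack_step(tape, store, "lstm", x, states, cfg$width)
    states <- st$states
    term <- ad_affine_pick_nll(tape, W_out, b_out, st$h, targets[i])
    nll <- if (is.null(nll)) term else ad_add(tape, nll, term)
  }
  list(nll = nll, n = length(targets))
}

#' Train the LSTM sequence language model
#'
#' Minimizes sentence NLL (including the end-of-sentence event) with Adam,
#' one update per sentence. Fully deterministic under a fixed seed. Errors
#' if the loss becomes non-finite.
#'
#' @param sentences List of tokenized sentences.
#' @param config A [seqlm_config()].
#' @param seed Integer seed (parameter init and shuffling).
#' @param vocab Optional prebuilt `vocabulary`.
#' @param min_count Unknown-word threshold passed to [build_vocab()].
#' @return Object of class `sequence_lm` with a `history` of per-epoch mean
#'   per-token NLL.
#' @export
train_sequence_lm <- function(sentences, config = seqlm_config(), seed = 1L,
                              vocab = NULL, min_count = 2L) {
  if (length(sentences) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_vocab(sentences, min_count = min_count)
  V <- vocab_size(vocab)
  store <- param_store(seqlm_shapes(V, config), seed = sub_seed(seed, "init"))
  for (l in seq_len(config$layers))
    lstm_init_forget_bias(store, paste0("lstm", l), config$width)
  model <- structure(list(vocab = vocab, config = config, params = store),
                     class = "sequence_lm")
  history <- numeric(config$epochs)
  rng <- local_rng(sub_seed(seed, "shuffle"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(sentences))
    tot <- 0; cnt <- 0L
    for (si in ord) {
      tape <- ad_tape()
      fw <- seqlm_sentence_nll(model, sentences[[si]], tape)
      loss <- ad_val(fw$nll)
      if (!is.finite(loss)) stop("training error: non-finite loss")
      grads <- ad_param_grads(tape, ad_backward(tape, fw$nll), store)
      adam_step(store, grads, lr = config$lr)
      tot <- tot + loss; cnt <- cnt + fw$n
    }
    history[ep] <- tot / cnt
  }
  model$history <- history
  model
}

#' @export
lm_logprob.sequence_lm <- function(model, token, context = character(0)) {
  lp <- seqlm_step_logprobs(model, context)
  lp[vocab_map(model$vocab, token)]
}

# distribution over the next token given a context (numeric log-softmax)
seqlm_step_logprobs <- function(model, context) {
  cfg <- model$config
  store <- model$params
  v <- model$vocab
  inputs <- c(match(v$bos, v$tokens), vocab_map(v, context))
  states <- lstm_zero_states(cfg$layers, cfg$width)
  E <- store$val$E
  for (i in seq_along(inputs)) {
    st <- lstm_stack_step(NULL, store, "lstm", E[inputs[i], ], states,
                          cfg$width)
    states <- st$states
    h <- st$h
  }
  logits <- as.vector(store$val$W_out %*% h) + store$val$b_out
  masked_log_softmax(logits)
}

#' @export
lm_sentence_logprobs.sequence_lm <- function(model, tokens, eos = TRUE) {
  cfg <- model$config
  store <- model$params
  v <- model$vocab
  ids <- vocab_map(v, tokens)
  inputs <- c(match(v$bos, v$tokens), ids)
  targets <- c(ids, match(v$eos, v$tokens))
  states <- lstm_zero_states(cfg$layers, cfg$width)
  E <- store$val$E
  out <- numeric(length(targets))
  for (i in seq_along(inputs)) {
    st <- lstm_stack_step(NULL, store, "lstm", E[inputs[i], ], states,
                          cfg$width)
    states <- st$states
    logits <- as.vector(store$val$W_out %*% st$h) + store$val$b_out
    out[i] <- masked_log_softmax(logits)[targets[i]]
  }
  if (eos) out else out[-length(out)]
}
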