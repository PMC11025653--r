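#' Vocabulary construction
#'
#' Builds dense token/index maps with reserved symbols for unknown tokens
#' (`<unk>`) and sentence boundaries (`<s>`, `</s>`). Tokens rarer than
#' `min_count` in the training corpus are mapped to `<unk>`.
#'
#' @param sentences List of character vectors (tokenized sentences).
#' @param min_count Tokens with training count below this become `<unk>`
#'   (default 2, i.e. hapax legomena are unknown).
#' @return Object of class `vocabulary`: `tokens` (character, index = position),
#'   plus `unk`, `bos`, `eos` symbols.
#' @export
build_vocab <- function(sentences, min_count = 2L) {
  counts <- table(unlist(sentences, use.names = FALSE))
  keep <- names(counts)[counts >= min_count]
  toks <- c("<unk>", "<s>", "</s>", sort(keep))
  structure(list(tokens = toks, unk = "<unk>", bos = "<s>", eos = "</s>"),
            class = "vocabulary")
}

#' @rdname build_vocab
#' @param vocab A `vocabulary`.
#' @param tokens Character vector.
#' @return `vocab_map()` returns integer indices (unknowns mapped to `<unk>`).
#' @export
vocab_map <- function(vocab, tokens) {
  i <- match(tokens, vocab$tokens)
  i[is.na(i)] <- 1L
  i
}

#' @rdname build_vocab
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

# content vocabulary = everything except <s> (never predicted); </s> is
# predicted by sentence-level models, so it stays in the support
ngram_support <- function(vocab) setdiff(vocab$tokens, vocab$bos)

key <- function(toks) paste(toks, collapse = "\x1f")

#' Fit an interpolated modified Kneser-Ney 5-gram model
#'
#' A fifth-order Markov language model with modified Kneser-Ney smoothing:
#' highest-order raw counts, lower-order continuation counts, and per-order
#' discounts D1, D2, D3+ derived from count-of-count statistics
#' (Y = n1/(n1+2 n2); D1 = 1 - 2Y n2/n1; D2 = 2 - 3Y n3/n2;
#' D3+ = 3 - 4Y n4/n3, clamped to be valid on tiny corpora). The backoff
#' chain terminates in a unigram distribution interpolated with the uniform
#' distribution over the support, so every token has positive probability.
#' For every context the distribution sums to exactly 1 (verifiable by
#' brute-force summation).
#'
#' @param sentences List of tokenized sentences (character vectors).
#' @param vocab A `vocabulary`; built from `sentences` when `NULL`.
#' @param order Markov order n (default 5).
#' @return Object of class `kn_ngram`.
#' @export
fit_kn5 <- function(sentences, vocab = NULL, order = 5L) {
  if (length(sentences) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_vocab(sentences)
  if (vocab_size(vocab) == 0L) stop("empty vocabulary")
  # map tokens, pad with BOS x (order-1) and EOS
  padded <- lapply(sentences, function(s) {
    s <- vocab$tokens[vocab_map(vocab, s)]
    c(rep(vocab$bos, order - 1L), s, vocab$eos)
  })
  # raw counts per n-gram order 1..order
  raw <- vector("list", order)
  for (k in seq_len(order)) {
    grams <- unlist(lapply(padded, function(s) {
      n <- length(s)
      if (n < k) return(character(0))
      vapply(seq_len(n - k + 1L), function(i) key(s[i:(i + k - 1L)]),
             character(1))
    }), use.names = FALSE)
    raw[[k]] <- table(grams)
  }
  # continuation counts for orders 1..order-1: number of distinct left
  # extensions N1+(. w_1..w_k)
  cont <- vector("list", order - 1L)
  for (k in seq_len(order - 1L)) {
    hi <- raw[[k + 1L]]
    parts <- strsplit(names(hi), "\x1f", fixed = TRUE)
    suffixes <- vapply(parts, function(p) key(p[-1L]), character(1))
    cont[[k]] <- table(suffixes)  # counts distinct predecessors
    # (each (k+1)-gram type contributes 1)
  }
  # adjusted counts used at each order: raw at top, continuation below;
  # n-grams whose final token is <s> are dropped (<s> is conditioned on,
  # never predicted), which keeps every context's distribution over the
  # prediction support summing to exactly 1
  drop_bos_final <- function(tab) {
    if (length(tab) == 0L) return(tab)
    last <- vapply(strsplit(names(tab), "\x1f", fixed = TRUE),
                   function(p) p[length(p)], character(1))
    tab[last != vocab$bos]
  }
  used <- vector("list", order)
  used[[order]] <- drop_bos_final(raw[[order]])
  for (k in seq_len(order - 1L)) used[[k]] <- drop_bos_final(cont[[k]])
  # discounts from count-of-counts of the counts actually used at each order
  discounts <- lapply(used, function(tab) kn_discounts(as.integer(tab)))
  structure(list(vocab = vocab, order = order, used = used,
                 discounts = discounts,
                 support = ngram_support(vocab)),
            class = "kn_ngram")
}

kn_discounts <- function(counts) {
  n <- tabulate(counts, nbins = 4L)
  Y <- if (n[1] + 2 * n[2] > 0) n[1] / (n[1] + 2 * n[2]) else 0.5
  d <- c(
    if (n[1] > 0 && n[2] > 0) 1 - 2 * Y * n[2] / n[1] else 0.5,
    if (n[2] > 0 && n[3] > 0) 2 - 3 * Y * n[3] / n[2] else 1.0,
    if (n[3] > 0 && n[4] > 0) 3 - 4 * Y * n[4] / n[3] else 1.5)
  # floor away from zero: a zero discount would zero the backoff mass gamma
  # for some contexts and give unseen continuations probability 0
  pmin(pmax(d, 0.1), c(1, 2, 3))
}

disc_of <- function(d, c) ifelse(c >= 3, d[3], ifelse(c == 2, d[2], d[1]))

# probability of `word` under context tokens (character), recursing down the
# backoff chain; context/word already mapped into the vocabulary
kn_prob <- function(model, word, context) {
  V <- length(model$support)
  p <- 1 / V  # uniform base below the unigram
  for (k in seq_len(model$order)) {  # k = order being interpolated in
    ctx <- if (k == 1L) character(0) else
      context[max(1L, length(context) - k + 2L):length(context)]
    if (k > 1L && length(context) < k - 1L) break
    tab <- model$used[[k]]
    d <- model$discounts[[k]]
    pref <- if (k == 1L) "" else paste0(key(ctx), "\x1f")
    nm <- names(tab)
    sel <- if (k == 1L) !grepl("\x1f", nm, fixed = TRUE) else
      startsWith(nm, pref) &
      !grepl("\x1f", substring(nm, nchar(pref) + 1L), fixed = TRUE)
    cs <- as.numeric(tab[sel])
    if (length(cs) == 0L || sum(cs) == 0) next  # unseen context: skip order
    tot <- sum(cs)
    ds <- disc_of(d, cs)
    gamma <- sum(pmin(ds, cs)) / tot
    wkey <- paste0(pref, word)
    cw <- tab[wkey]
    cw <- if (is.na(cw)) 0 else as.numeric(cw)
    num <- max(cw - disc_of(d, max(cw, 1)), 0)
    p <- num / tot + gamma * p
  }
  p
}

#' Log probability of a token in context
#'
#' For `kn_ngram` models the context is truncated to the last `order - 1`
#' tokens (Markov property). Unknown tokens are mapped to `<unk>`, so the
#' value is always finite. Surprisal is the negative of this value.
#'
#' @param model A `kn_ngram` or `sequence_lm`.
#' @param token Single token (character).
#' @param context Character vector of preceding tokens (sentence-initial
#'   context is padded with `<s>` internally).
#' @return Log probability (natural log), finite and `<= 0`.
#' @export
lm_logprob <- function(model, token, context = character(0)) {
  UseMethod("lm_logprob")
}

#' @export
lm_logprob.kn_ngram <- function(model, token, context = character(0)) {
  v <- model$vocab
  token <- v$tokens[vocab_map(v, token)]
  context <- c(rep(v$bos, model$order - 1L),
               v$tokens[vocab_map(v, context)])
  context <- context[(length(context) - model$order + 2L):length(context)]
  log(kn_prob(model, token, context))
}

#' Per-token log probabilities of a sentence (including `</s>`)
#'
#' @param model A language model.
#' @param tokens Tokenized sentence.
#' @param eos Include the end-of-sentence event (default TRUE).
#' @return Numeric vector of log probabilities, one per predicted token.
#' @export
lm_sentence_logprobs <- function(model, tokens, eos = TRUE) {
  UseMethod("lm_sentence_logprobs")
}

#' @export
lm_sentence_logprobs.kn_ngram <- function(model, tokens, eos = TRUE) {
  tgt <- if (eos) c(tokens, model$vocab$eos) else tokens
  vapply(seq_along(tgt), function(i)
    lm_logprob(model, tgt[i], if (i > 1L) tgt[seq_len(i - 1L)] else character(0)),
    numeric(1))
}
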