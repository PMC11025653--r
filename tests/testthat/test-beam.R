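exhaustive_cfg <- beam_config(k = 100000L, k_w = 100000L, k_ft = 0L,
                              open_cap = 2L)

capped <- function(m) { m$config$nt_budget <- 2L; m$config$open_cap <- 2L; m }

test_that("beam configuration defaults and validation", {
  cfg <- beam_config(k = 400)
  expect_equal(cfg$k_w, 40L)
  expect_equal(cfg$k_ft, 4L)
  expect_error(beam_config(k = 5, k_w = 10), "k >= k_w")
})

test_that("exhaustive beam surprisal matches the enumeration oracle", {
  # random and trained parameters, both strategies
  models <- list(
    rand_td = capped(rnng_model(c("a", "b"), c("S", "X"), "top_down",
                                rnng_config(width = 8), seed = 3)),
    rand_lc = capped(rnng_model(c("a", "b"), c("S", "X"), "left_corner",
                                rnng_config(width = 8), seed = 4)),
    trained_td = capped(ambig_rnng("top_down")),
    trained_lc = capped(ambig_rnng("left_corner")))
  for (nm in names(models)) {
    m <- models[[nm]]
    for (toks in list(c("a", "b"), c("b", "b", "a"))) {
      M <- exact_prefix_marginals(m, toks, open_cap = 2L, nt_budget = 2L)
      prof <- complexity_profile(m, toks, exhaustive_cfg)
      expected <- -log(M / c(1, M[-length(M)]))
      expect_equal(prof$surprisal, expected, tolerance = 1e-6,
                   info = paste(nm, paste(toks, collapse = " ")))
      # telescoping
      expect_equal(sum(prof$surprisal), -log(M[length(M)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("beam marginals are non-increasing lower bounds of the exact ones", {
  m <- capped(ambig_rnng("left_corner"))
  toks <- c("b", "b", "a")
  M <- exact_prefix_marginals(m, toks, open_cap = 2L, nt_budget = 2L)
  for (k in c(2L, 5L, 20L)) {
    prof <- complexity_profile(m, toks,
                               beam_config(k = k, k_w = k, k_ft = 1L,
                                           open_cap = 2L))
    Mb <- exp(prof$log_marginal_after)
    expect_true(all(diff(Mb) < 1e-12))
    expect_true(all(Mb <= M + 1e-12))
  }
})

test_that("summed joint tree probabilities are a subprobability below the
           prefix marginal", {
  g <- toy_grammar("ambiguous")
  en <- enumerate_trees(g, 3)
  for (strat in c("top_down", "left_corner")) {
    m <- capped(ambig_rnng(strat))
    toks <- c("a", "b")
    M <- exact_prefix_marginals(m, toks, open_cap = 2L, nt_budget = 2L)
    trees <- Filter(function(e) identical(tree_yield(e$tree), toks), en)
    joint <- sum(vapply(trees, function(e)
      exp(rnng_tree_logprob(m, e$tree)), numeric(1)))
    expect_gt(joint, 0)
    expect_lte(joint, M[length(M)] + 1e-12)
  }
})

test_that("beam size and exploration-count invariants hold", {
  m <- capped(ambig_rnng("top_down"))
  cfg <- beam_config(k = 6L, k_w = 3L, k_ft = 1L, open_cap = 2L)
  beam <- list(rnng_init_state(m))
  for (tok in c("a", "b")) {
    st <- word_sync_step(m, beam, tok, cfg, n_total = 2L)
    expect_lte(length(st$beam), cfg$k_w)
    expect_gte(st$explored, length(st$beam))
    expect_true(all(vapply(st$beam, `[[`, integer(1), "ntokens") ==
                      st$beam[[1]]$ntokens))
    beam <- st$beam
  }
})

test_that("an impossible token reports an empty-beam error with its index", {
  m <- rnng_model(c("a", "b"), c("S", "X"), "top_down",
                  rnng_config(width = 8), seed = 1)
  expect_error(complexity_profile(m, c("a", "b"),
                                  beam_config(k = 10, open_cap = 0L)),
               "token 1.*empty-beam")
})

test_that("distance variants are integer-valued and at least 1 per token", {
  m <- capped(ambig_rnng("left_corner"))
  for (dv in c("explored", "survivors", "viterbi")) {
    prof <- complexity_profile(m, c("a", "b"),
                               beam_config(k = 10, distance = dv,
                                           open_cap = 2L))
    expect_true(all(prof$distance >= 1))
    expect_equal(prof$distance, round(prof$distance))
  }
})

test_that("surprisal can be reported in bits", {
  m <- capped(ambig_rnng("top_down"))
  nats <- complexity_profile(m, c("a", "b"), exhaustive_cfg, base = "nats")
  bits <- complexity_profile(m, c("a", "b"), exhaustive_cfg, base = "bits")
  expect_equal(bits$surprisal, nats$surprisal / log(2))
})

test_that("segment aggregation is additive and validates token counts", {
  tb <- sample_treebank(toy_grammar("headfinal"), 8, max_len = 8, seed = 31)
  sch <- make_stimulus_schedule(tb, blocks = 1, seed = 4)
  sents <- schedule_sentences(sch)
  recs <- do.call(rbind, lapply(names(sents), function(k)
    data.frame(sentence = k, token_index = seq_along(sents[[k]]),
               surprisal = seq_along(sents[[k]]) * 0.5,
               distance = rep(2, length(sents[[k]])))))
  agg <- aggregate_segments(recs, sch)
  ntok <- vapply(strsplit(agg$tokens, " "), length, integer(1))
  expect_equal(agg$distance, 2 * ntok)
  expect_equal(sum(agg$surprisal), sum(recs$surprisal))
  # single-token segments are the identity mapping
  one <- agg[ntok == 1, ]
  expect_true(all(one$distance == 2))
  # a missing token is a schema error
  expect_error(aggregate_segments(recs[-1, ], sch), "schema error")
})

test_that("uniform models have perplexity V and beams at exhaustive k win", {
  sents <- list(c("a", "b"), c("b", "a"))
  v <- build_vocab(sents, min_count = 1)
  m <- structure(list(vocab = v, config = seqlm_config(width = 8),
                      params = rnngbold:::param_store(
                        rnngbold:::seqlm_shapes(vocab_size(v),
                                                seqlm_config(width = 8)),
                        seed = 1, init_scale = 0)),
                 class = "sequence_lm")
  # zero weights: exactly uniform over the vocabulary at every step
  expect_equal(corpus_perplexity(m, sents), vocab_size(v))
  rn <- capped(ambig_rnng("top_down"))
  ppl_ex <- corpus_perplexity(rn, list(c("a", "b")), exhaustive_cfg)
  for (k in c(2L, 4L, 10L)) {
    ppl_k <- corpus_perplexity(rn, list(c("a", "b")),
                               beam_config(k = k, k_w = k, k_ft = 1L,
                                           open_cap = 2L))
    expect_gte(ppl_k, ppl_ex - 1e-9)
  }
  expect_error(corpus_perplexity(rn, list()), "empty corpus")
})

test_that("memorized model yields low per-token surprisal", {
  m <- memo_rnng("top_down")
  prof <- complexity_profile(m, tree_yield(memo_tree()), beam_config(k = 50))
  expect_true(all(prof$surprisal < 0.6))
})
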