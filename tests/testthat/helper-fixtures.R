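# Shared fixtures. Expensive objects (trained models, designs) are cached in
# a process-level environment so that test files running in the same session
# reuse them instead of retraining.

cached_fixture <- function(name, expr) {
  cache_name <- ".rnngbold_test_cache"
  if (!exists(cache_name, envir = globalenv(), inherits = FALSE))
    assign(cache_name, new.env(parent = emptyenv()), envir = globalenv())
  cache <- get(cache_name, envir = globalenv())
  if (!exists(name, envir = cache, inherits = FALSE))
    assign(name, force(expr), envir = cache)
  get(name, envir = cache)
}

fixture_headfinal <- function() toy_grammar("headfinal")
fixture_ambiguous <- function() toy_grammar("ambiguous")

# memorization fixture: one head-final sentence repeated 50x
memo_tree <- function() read_bracketed(
  "(S (NP (N inu) (P ga)) (VP (NP (N hon) (P wo)) (V yonda)))")
memo_treebank <- function() rep(list(memo_tree()), 50)
memo_corpus <- function() rep(list(tree_yield(memo_tree())), 50)

# small trained models on the memorization fixture
memo_rnng <- function(strategy) cached_fixture(
  paste0("memo_rnng_", strategy),
  train_rnng(memo_treebank(), strategy,
             rnng_config(width = 16, epochs = 12, lr = 8e-3),
             seed = 5, min_count = 1))

memo_lstm <- function() cached_fixture(
  "memo_lstm",
  train_sequence_lm(memo_corpus(), seqlm_config(width = 16, epochs = 8),
                    seed = 5, min_count = 1))

# RNNGs trained on the tiny ambiguous grammar (for beam-vs-oracle tests)
ambig_treebank <- function() cached_fixture(
  "ambig_treebank",
  sample_treebank(fixture_ambiguous(), 200, max_len = 2, seed = 21))

ambig_rnng <- function(strategy) cached_fixture(
  paste0("ambig_rnng_", strategy),
  train_rnng(ambig_treebank(), strategy,
             rnng_config(width = 8, epochs = 3, lr = 5e-3,
                         nt_budget = 2L, open_cap = 2L),
             seed = 13, min_count = 1))

# canonical synthetic study: treebank -> schedule -> metrics -> design
study_schedule <- function() cached_fixture("study_schedule", {
  tb <- sample_treebank(fixture_headfinal(), 120, max_len = 10, seed = 11)
  make_stimulus_schedule(tb, blocks = 4, seed = 2)
})

study_metrics <- function() cached_fixture("study_metrics", {
  sch <- study_schedule()
  sents <- schedule_sentences(sch)
  kn <- fit_kn5(unname(sents), build_vocab(unname(sents), min_count = 1))
  lstm <- cached_fixture("study_lstm",
    train_sequence_lm(unname(sents), seqlm_config(width = 16, epochs = 3),
                      seed = 7, min_count = 1))
  tb <- sample_treebank(fixture_headfinal(), 120, max_len = 10, seed = 11)
  td <- cached_fixture("study_rnng_td",
    train_rnng(tb, "top_down", rnng_config(width = 16, epochs = 2, lr = 5e-3),
               seed = 7, min_count = 1))
  lc <- cached_fixture("study_rnng_lc",
    train_rnng(tb, "left_corner", rnng_config(width = 16, epochs = 2, lr = 5e-3),
               seed = 7, min_count = 1))
  segment_metric_table(sch, ngram = kn, lstm = lstm, rnng_td = td,
                       rnng_lc = lc, cfg = beam_config(k = 20))
})

study_design <- function() cached_fixture(
  "study_design",
  build_design(study_schedule(), study_metrics(), seed = 3))

# ground truth used by the ROI recovery experiments: a left-corner surprisal
# effect of 0.2 sd in the effect-bearing ROIs, none elsewhere
study_truth <- function(with_lc_effect = TRUE, n_subjects = 34L) {
  beta <- c(word_rate = 0.5, word_length = 0.2, word_freq = -0.2,
            sentpos = 0.1)
  if (with_lc_effect) beta <- c(beta, surp_RNNG_LC = 0.6)
  effect_spec(beta, sigma_subject = 0.3, sigma_noise = 1, ar1_rho = 0.3,
              n_subjects = n_subjects)
}

EFFECT_ROIS <- c("IFGoperc", "IFGtriang", "IPL", "AG", "STG")
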