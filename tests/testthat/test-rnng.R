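rand_rnng <- function(strategy, seed = 3, width = 8, ...) {
  g <- toy_grammar("ambiguous")
  rnng_model(g$terminals, g$nonterminals, strategy,
             rnng_config(width = width, ...), seed = seed)
}

test_that("initial legal actions differ by strategy", {
  td <- rand_rnng("top_down")
  lc <- rand_rnng("left_corner")
  m_td <- legal_actions(rnng_init_state(td), td, 5)
  m_lc <- legal_actions(rnng_init_state(lc), lc, 5)
  expect_false(m_td[1])            # no open constituent to GEN into
  expect_true(all(m_td[3:4]))      # only NT legal
  expect_false(m_td[2])
  expect_true(m_lc[1])             # nothing yet to be a left corner: GEN only
  expect_false(any(m_lc[2:4]))
})

test_that("a completed top-down root is terminal", {
  m <- rand_rnng("top_down")
  s <- rnng_init_state(m)
  for (a in list(c(3, NA), c(1, 1), c(2, NA))) {
    s <- rnng_step(m, s, a[1], token = if (!is.na(a[2])) "a")
  }
  expect_false(any(legal_actions(s, m, 1)))
})

test_that("REDUCE shrinks the stack by the number of children", {
  m <- rand_rnng("top_down")
  s <- rnng_init_state(m)
  s <- rnng_step(m, s, 3)                      # NT(S)
  s <- rnng_step(m, s, 1, token = "a")
  s <- rnng_step(m, s, 1, token = "b")
  s <- rnng_step(m, s, 1, token = "a")
  expect_equal(length(s$stack), 4L)
  s2 <- rnng_step(m, s, 2)                     # REDUCE over c = 3 children
  expect_equal(length(s$stack) - length(s2$stack), 3L)
  expect_equal(length(s2$stack[[1]]$vec), m$config$width)
  expect_identical(write_bracketed(s2$stack[[1]]$tree), "(S a b a)")
})

test_that("illegal actions are contract violations", {
  m <- rand_rnng("top_down")
  expect_error(rnng_step(m, rnng_init_state(m), 1, token = "a"),
               "contract violation")
  expect_error(rnng_step(m, rnng_init_state(m), 2), "contract violation")
})

test_that("composition is order-sensitive for generic parameters", {
  m <- rand_rnng("top_down")
  kids <- list(stats::runif(8, -1, 1), stats::runif(8, -1, 1),
               stats::runif(8, -1, 1))
  v1 <- rnngbold:::rnng_compose(m, 1L, kids)
  v2 <- rnngbold:::rnng_compose(m, 1L, rev(kids))
  expect_equal(length(v1), 8L)
  expect_gt(max(abs(v1 - v2)), 1e-6)
})

test_that("gold derivations score identically via training and stepping", {
  for (strat in c("top_down", "left_corner")) {
    m <- rand_rnng(strat, seed = 8)
    tree <- read_bracketed("(S (X a) b)")
    nll <- rnngbold:::ad_val(rnng_tree_nll(m, tree)$nll)
    # independent accumulation through scoring + stepping
    seqa <- derivation_oracle(tree, strat)$actions
    s <- rnng_init_state(m)
    tot <- 0
    for (a in seqa) {
      aid <- switch(a$type, GEN = 1L, REDUCE = 2L,
                    NT = 2L + match(a$arg, m$nts))
      mask <- legal_actions(s, m, 2)
      sc <- rnngbold:::rnng_state_scores(m, s, mask)
      lp <- sc$alp[aid]
      if (a$type == "GEN")
        lp <- lp + rnngbold:::rnng_word_logprobs(m, sc$h)[
          rnngbold:::word_id(m, a$arg)]
      tot <- tot - lp
      s <- rnng_step(m, s, aid, token = if (a$type == "GEN") a$arg,
                     lp_add = lp, check = FALSE)
    }
    expect_equal(tot, nll, tolerance = 1e-10)
    expect_equal(-s$logp, nll, tolerance = 1e-10)
    expect_identical(write_bracketed(s$stack[[1]]$tree),
                     write_bracketed(tree))
  }
})

test_that("epoch-0 loss matches the analytic near-uniform bound", {
  g <- toy_grammar("ambiguous")
  tree <- read_bracketed("(S (X a) b)")
  for (strat in c("top_down", "left_corner")) {
    m <- rnng_model(g$terminals, g$nonterminals, strat,
                    rnng_config(width = 8), seed = 1)
    # shrink init so logits are near zero => softmax near uniform over legal
    for (nm in names(m$params$val))
      m$params$val[[nm]] <- m$params$val[[nm]] * 1e-3
    expected <- 0
    seqa <- derivation_oracle(tree, strat)$actions
    s <- rnng_init_state(m)
    for (a in seqa) {
      aid <- switch(a$type, GEN = 1L, REDUCE = 2L,
                    NT = 2L + match(a$arg, m$nts))
      mask <- legal_actions(s, m, 2)
      expected <- expected + log(sum(mask)) +
        if (a$type == "GEN") log(length(m$words)) else 0
      s <- rnng_step(m, s, aid, token = if (a$type == "GEN") a$arg,
                     check = FALSE)
    }
    nll <- rnngbold:::ad_val(rnng_tree_nll(m, tree)$nll)
    expect_equal(nll, expected, tolerance = 1e-3)
  }
})

test_that("single-tree training memorizes the gold derivation", {
  for (strat in c("top_down", "left_corner")) {
    m <- memo_rnng(strat)
    expect_lt(m$history[length(m$history)], m$history[1])
    expect_gt(exp(rnng_tree_logprob(m, memo_tree())), 0.9)
    # both strategies have the capacity: gold-derivation perplexity < 1.5
    expect_lt(exp(m$history[length(m$history)]), 1.5)
    expect_identical(m$strategy, strat)
  }
})

test_that("training rejects trees with unknown nonterminals cleanly", {
  m <- rand_rnng("top_down")
  expect_error(rnng_tree_nll(m, read_bracketed("(Q a)")),
               "data error.*Q")
})

test_that("rnng checkpoints round-trip through JSON", {
  m <- ambig_rnng("top_down")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  tree <- read_bracketed("(S (X a) b)")
  expect_equal(rnng_tree_logprob(m2, tree), rnng_tree_logprob(m, tree))
  expect_identical(m2$strategy, "top_down")
})
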