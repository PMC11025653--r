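test_that("zero subject variance reduces to the OLS Gaussian likelihood", {
  set.seed(3)
  n <- 400
  X <- cbind(x = rnorm(n))
  e <- rnorm(n)
  subj <- rep(1:4, each = 100)
  # remove empirical between-group noise so the no-group-effect boundary is
  # the ML optimum, making the OLS identity exact rather than approximate
  e <- e - stats::ave(e, subj) + mean(e)
  y <- 0.4 * X[, 1] + e
  fit <- fit_lmm_ml(y, X, subj)
  ols <- lm(y ~ X)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-4)
  expect_lt(fit$sigma_u, 1e-3)
  # ML can never do worse than OLS, whatever the grouping
  y2 <- 0.4 * X[, 1] + rnorm(n)
  expect_gte(fit_lmm_ml(y2, X, subj)$logLik,
             as.numeric(logLik(lm(y2 ~ X))) - 1e-8)
})

test_that("balanced one-way ML estimates match direct ML maximization", {
  set.seed(9)
  G <- 6; m <- 30
  y <- rep(rnorm(G, 0, 0.8), each = m) + rnorm(G * m, 2, 1)
  subj <- rep(1:G, each = m)
  fit <- fit_lmm_ml(y, matrix(numeric(0), G * m, 0), subj)
  # independent oracle: direct 3-parameter ML with the marginal likelihood
  negll <- function(par) {
    mu <- par[1]; su2 <- exp(par[2]); se2 <- exp(par[3])
    tot <- 0
    for (g in 1:G) {
      yg <- y[subj == g] - mu
      V <- diag(se2, m) + su2
      tot <- tot + 0.5 * (determinant(V)$modulus +
                            sum(yg * solve(V, yg)) + m * log(2 * pi))
    }
    tot
  }
  opt <- optim(c(mean(y), log(0.5), log(1)), negll, method = "BFGS")
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-6)
  expect_equal(unname(fit$beta[1]), opt$par[1], tolerance = 1e-4)
})

test_that("the profiled fitter reproduces lme4's ML log-likelihood", {
  set.seed(21)
  n <- 150; G <- 7
  X <- cbind(a = rnorm(n * G), b = rnorm(n * G))
  subj <- rep(seq_len(G), each = n)
  y <- 0.5 + 0.3 * X[, 1] + rep(rnorm(G, 0, 0.6), each = n) + rnorm(n * G)
  fit <- fit_lmm_ml(y, X, subj)
  df <- data.frame(y = y, a = X[, 1], b = X[, 2], s = factor(subj))
  lf <- lme4::lmer(y ~ a + b + (1 | s), data = df, REML = FALSE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
})

test_that("parameter recovery: estimates within 3 SE in >= 95% of reps", {
  set.seed(5)
  n <- 40; G <- 6
  X <- cbind(x1 = rnorm(n * G), x2 = rnorm(n * G))
  subj <- rep(1:G, each = n)
  truth <- c(x1 = 0.5, x2 = -0.3)
  hits <- replicate(200, {
    y <- X %*% truth + rep(rnorm(G, 0, 0.5), each = n) + rnorm(n * G)
    fit <- fit_lmm_ml(as.vector(y), X, subj)
    all(abs(fit$beta[names(truth)] - truth) <= 3 * fit$se[names(truth)])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("likelihood never decreases when adding a column", {
  set.seed(31)
  n <- 200
  subj <- rep(1:4, each = 50)
  y <- rnorm(n) + rep(rnorm(4, 0, 0.5), each = 50)
  X1 <- cbind(a = rnorm(n))
  for (r in 1:5) {
    X2 <- cbind(X1, b = rnorm(n))
    f1 <- fit_lmm_ml(y, X1, subj)
    f2 <- fit_lmm_ml(y, X2, subj)
    expect_gte(f2$logLik, f1$logLik - 1e-6)
  }
})

test_that("LRT mechanics: identical models, nesting checks, chisq identity", {
  set.seed(13)
  n <- 120
  X <- cbind(a = rnorm(n))
  subj <- rep(1:4, each = 30)
  y <- rnorm(n)
  f1 <- fit_lmm_ml(y, X, subj)
  same <- lrt(f1, f1)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  f2 <- fit_lmm_ml(y, cbind(X, b = rnorm(n)), subj)
  tst <- lrt(f1, f2)
  expect_equal(tst$chisq, 2 * (f2$logLik - f1$logLik))
  expect_equal(tst$df, 1)
  expect_error(lrt(f2, f1), "not nested")
  fr <- f1; fr$reml <- TRUE
  expect_error(lrt(fr, f2), "contract error.*REML")
})

test_that("LRT type-I error is calibrated at alpha = 0.05", {
  set.seed(77)
  n <- 40; G <- 5
  subj <- rep(1:G, each = n)
  Xb <- cbind(a = rnorm(n * G))
  pvals <- replicate(1000, {
    u <- rep(rnorm(G, 0, 0.5), each = n)
    eps <- unlist(lapply(1:G, function(g)
      rnngbold:::ar1_noise(n, 0.3, 1)))
    y <- 0.2 * Xb[, 1] + u + eps
    xnew <- rnorm(n * G)          # white-noise predictor: the null is true
    f0 <- fit_lmm_ml(y, Xb, subj)
    f1 <- fit_lmm_ml(y, cbind(Xb, z = xnew), subj)
    lrt(f0, f1)$p
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("the Bonferroni gate uses alpha / m", {
  expect_true(bonferroni_gate(0.004, m = 8))    # 0.004 < 0.00625
  expect_false(bonferroni_gate(0.007, m = 8))
  expect_false(bonferroni_gate(1, m = 1))
  expect_false(bonferroni_gate(1, m = 100))
  expect_error(bonferroni_gate(0.01, m = 0), "positive")
})

test_that("a four-step ladder over eight ROIs yields exactly 32 rows", {
  d <- study_design()
  truth <- study_truth(with_lc_effect = FALSE, n_subjects = 6L)
  responses <- lapply(setNames(ROI_NAMES, ROI_NAMES), function(r)
    simulate_roi_bold(d, truth, seed = rnngbold:::sub_seed(1, r)))
  tab <- run_ladder(d, responses, ladder_spec("surp_td_first"))
  expect_equal(nrow(tab), 32L)
  expect_equal(sort(unique(tab$roi)), sort(ROI_NAMES))
  expect_true(all(tab$df == 1))
  expect_true(all(tab$chisq >= -1e-6))
  expect_error(run_ladder(d, responses,
                          ladder_spec("custom", steps = "nonexistent")),
               "schema error")
})

test_that("orthogonalization isolates word_rate from the LM columns", {
  # with no true LM effect, adding the (orthogonalized) LM columns leaves
  # the word_rate coefficient essentially unchanged
  d <- study_design()
  truth <- study_truth(with_lc_effect = FALSE, n_subjects = 8L)
  Y <- simulate_roi_bold(d, truth, seed = 33)
  pooled <- rnngbold:::pool_roi(d, Y, 3)
  base <- fit_lmm_ml(pooled$y, pooled$X[, rnngbold:::BASELINE_COLS],
                     pooled$subject)
  full <- fit_lmm_ml(pooled$y,
                     pooled$X[, c(rnngbold:::BASELINE_COLS, "ngram", "lstm",
                                  "surp_RNNG_TD", "surp_RNNG_LC")],
                     pooled$subject)
  shift <- abs(base$beta["word_rate"] - full$beta["word_rate"])
  expect_lt(shift, 3 * base$se["word_rate"])
})

test_that("all four study ladders are available with the right steps", {
  expect_equal(ladder_spec("surp_td_first")$steps,
               c("ngram", "lstm", "surp_RNNG_TD", "surp_RNNG_LC"))
  expect_equal(ladder_spec("surp_lc_first")$steps,
               c("ngram", "lstm", "surp_RNNG_LC", "surp_RNNG_TD"))
  expect_equal(ladder_spec("dis_td_first")$steps,
               c("ngram", "lstm", "dis_RNNG_TD", "dis_RNNG_LC"))
  expect_equal(ladder_spec("dis_lc_first")$steps,
               c("ngram", "lstm", "dis_RNNG_LC", "dis_RNNG_TD"))
})
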