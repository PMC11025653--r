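test_that("the canonical HRF is causal, peaks at 4-6 s, undershoots at 16 s", {
  expect_equal(canonical_hrf(0), 0)
  expect_equal(canonical_hrf(-3), 0)
  grid <- seq(0, 30, by = 0.01)
  h <- canonical_hrf(grid)
  tpeak <- grid[which.max(h)]
  expect_gte(tpeak, 4); expect_lte(tpeak, 6)
  expect_equal(max(h), 1)                 # peak-normalized
  expect_lt(canonical_hrf(16), 0)         # late undershoot
})

test_that("event convolution is linear and superposes single events", {
  ft <- seq(0, 60, by = 2)
  one <- convolve_events(data.frame(time = 0, amplitude = 1), ft)
  expect_equal(one, canonical_hrf(ft), tolerance = 1e-9)
  a <- convolve_events(data.frame(time = 10, amplitude = 2), ft)
  b <- convolve_events(data.frame(time = 24, amplitude = -1), ft)
  both <- convolve_events(data.frame(time = c(10, 24), amplitude = c(2, -1)),
                          ft)
  expect_equal(both, a + b, tolerance = 1e-12)
  expect_equal(convolve_events(data.frame(time = c(5, 9),
                                          amplitude = c(0, 0)), ft),
               numeric(length(ft)))
})

test_that("convolution is time-invariant on the oversampled grid", {
  ft <- seq(0, 80, by = 2)
  x <- convolve_events(data.frame(time = 20, amplitude = 1), ft)
  y <- convolve_events(data.frame(time = 22, amplitude = 1), ft)
  # shifting the event by one TR shifts the sampled column by one frame
  expect_equal(y[-1], x[-length(x)], tolerance = 1e-9)
})

test_that("events after the last frame warn and are truncated", {
  ft <- seq(0, 20, by = 2)
  expect_warning(
    col <- convolve_events(data.frame(time = c(5, 99), amplitude = c(1, 1)),
                           ft),
    "truncated")
  expect_equal(col,
               convolve_events(data.frame(time = 5, amplitude = 1), ft))
})

test_that("orthogonalization matches the normal-equations oracle", {
  set.seed(7)
  n <- 120
  base <- cbind(b1 = rnorm(n), b2 = rnorm(n))
  target <- rnorm(n) + 0.6 * base[, 1]
  res <- orthogonalize(target, base)
  # independent projector: beta = (B'B)^-1 B'y with explicit intercept
  B <- cbind(1, base)
  beta <- solve(t(B) %*% B, t(B) %*% target)
  expect_equal(res, as.vector(target - B %*% beta), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(scale(base), res))), 1e-8)
  # already-orthogonal target is unchanged; base column maps to zero
  t2 <- res
  expect_equal(orthogonalize(t2, base), t2, tolerance = 1e-10)
  expect_equal(orthogonalize(base[, 1], base), numeric(n), tolerance = 1e-10)
  expect_error(orthogonalize(target, cbind(base, b1dup = base[, 1])),
               "collinear")
})

test_that("the built design is standardized, orthogonalized, at 0.5 Hz", {
  d <- study_design()
  expect_equal(unique(round(diff(d$frames$time[d$frames$block == 1]), 9)), 2)
  expect_true(all(d$frames$time >= study_schedule()$discard_lead_s))
  expect_lt(max(abs(colMeans(d$X))), 1e-8)
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, ncol(d$X)), tolerance = 1e-8)
  for (cn in c("ngram", "lstm", "surp_RNNG_TD", "surp_RNNG_LC",
               "dis_RNNG_TD", "dis_RNNG_LC"))
    expect_lt(abs(cor(d$X[, cn], d$X[, "word_rate"])), 1e-6)
  expect_identical(unname(d$provenance$orthogonalized["surp_RNNG_LC"]),
                   "word_rate")
  expect_error(build_design(study_schedule(),
                            data.frame(segment_id = 1)), "schema error")
})

test_that("predictor correlations are symmetric with unit diagonal", {
  d <- study_design()
  cc <- predictor_correlations(d)
  expect_equal(cc, t(cc), tolerance = 1e-12)
  expect_equal(unname(diag(cc)), rep(1, ncol(d$X)))
  X2 <- cbind(d$X[, 1:3], dup = d$X[, 1])
  expect_equal(predictor_correlations(X2)[1, 4], 1)
  expect_error(predictor_correlations(cbind(d$X[, 1:2], z = rep(1, nrow(d$X)))),
               "zero-variance")
})

test_that("outlier censoring follows the normal tail mass", {
  set.seed(11)
  fracs <- replicate(40, mean(censor_outliers(rnorm(2000), 3)))
  p <- 2 * pnorm(-3)
  se <- sqrt(p * (1 - p) / 2000) / sqrt(40)
  expect_lt(abs(mean(fracs) - p), 3 * se)
  expect_equal(censor_outliers(rep(2.5, 50)), rep(FALSE, 50))
  x <- rnorm(500); x[100] <- 10 * sd(x)
  expect_equal(which(censor_outliers(x, 3)), 100L)
})

test_that("stimulus schedule arithmetic matches the presentation protocol", {
  tb <- sample_treebank(toy_grammar("headfinal"), 6, max_len = 6, seed = 2)
  sch <- make_stimulus_schedule(tb, blocks = 2, soa_s = 1, seed = 5)
  seg <- sch$segments
  b1 <- seg[seg$block == 1, ]
  expect_equal(b1$onset, 20 + seq_len(nrow(b1)) - 1)
  expect_equal(seg$offset - seg$onset, rep(0.5, nrow(seg)))
  # sentence position restarts at 1 at each sentence boundary
  for (k in unique(seg$sentence_key))
    expect_equal(seg$sentpos[seg$sentence_key == k],
                 seq_len(sum(seg$sentence_key == k)))
  expect_error(make_stimulus_schedule(tb, soa_s = 0), "invalid parameter")
})
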