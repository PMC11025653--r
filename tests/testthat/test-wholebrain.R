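test_that("Gaussian smoothing: constants, kernel mass, and the sigma formula", {
  shape <- c(10, 10, 8)
  const <- array(3.7, shape)
  expect_equal(gaussian_smooth(const, 8), const, tolerance = 1e-10)
  imp <- array(0, shape); imp[5, 5, 4] <- 1
  sm <- gaussian_smooth(imp, 8)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(8 / (2 * sqrt(2 * log(2))), 3.39728, tolerance = 1e-5)
  expect_error(gaussian_smooth(const, -1), "fwhm")
  expect_identical(gaussian_smooth(const, 0), const)
})

test_that("first-level GLM recovers noise-free betas exactly", {
  d <- study_design()
  shape <- c(6, 6, 4)
  eff <- array(TRUE, shape)
  truth <- effect_spec(c(word_rate = 0.7, lstm = -0.4),
                       sigma_subject = 0, sigma_noise = 1e-9, ar1_rho = 0,
                       n_subjects = 1L)
  vols <- simulate_volume_bold(shape, eff, d, truth, seed = 2)
  maps <- first_level_glm(vols[[1]], d)
  expect_equal(as.vector(maps[["word_rate"]]), rep(0.7, prod(shape)),
               tolerance = 1e-6)
  expect_equal(as.vector(maps[["lstm"]]), rep(-0.4, prod(shape)),
               tolerance = 1e-6)
  # residual orthogonality at one voxel
  Xn <- cbind(1, d$X[, setdiff(colnames(d$X),
                               c("dx", "dy", "dz", "rx", "ry", "rz"))])
  y <- vols[[1]]$data[1, 1, 1, ]
  res <- y - Xn %*% qr.coef(qr(Xn), y)
  expect_lt(max(abs(crossprod(Xn, res))), 1e-6)
})

test_that("named beta maps are invariant to predictor order", {
  d <- study_design()
  shape <- c(5, 5, 3)
  truth <- effect_spec(c(word_rate = 0.5), sigma_subject = 0,
                       sigma_noise = 0.5, ar1_rho = 0, n_subjects = 1L)
  vols <- simulate_volume_bold(shape, array(TRUE, shape), d, truth, seed = 8)
  m1 <- first_level_glm(vols[[1]], d, predictors = c("word_rate", "lstm"))
  m2 <- first_level_glm(vols[[1]], d, predictors = c("lstm", "word_rate"))
  expect_equal(m1[["word_rate"]], m2[["word_rate"]])
  expect_equal(m1[["lstm"]], m2[["lstm"]])
})

test_that("second-level z maps are calibrated under the null", {
  set.seed(4)
  shape <- c(12, 12, 8)
  nsub <- 8
  zs <- replicate(30, {
    maps <- lapply(seq_len(nsub), function(i) array(rnorm(prod(shape)), shape))
    zm <- second_level_z(maps, fwhm_mm = 0)
    c(mean(zm$z), var(as.vector(zm$z)))
  })
  nv <- prod(shape) * 30
  expect_lt(abs(mean(zs[1, ])), 3 / sqrt(nv) * 2)
  expect_equal(mean(zs[2, ]), 1, tolerance = 0.05)
  # positive effect: all z positive; monotone t -> z mapping
  maps <- lapply(seq_len(nsub), function(i)
    array(1 + 0.2 * rnorm(prod(shape)), shape))
  zm <- second_level_z(maps, fwhm_mm = 0)
  expect_true(all(zm$z > 0))
  expect_error(second_level_z(maps[1:2]), "at least 3")
})

test_that("t-to-z preserves voxel ordering", {
  set.seed(6)
  shape <- c(6, 6, 4)
  maps <- lapply(1:5, function(i) array(rnorm(prod(shape), 0.3), shape))
  B <- sapply(maps, as.vector)
  tstat <- rowMeans(B) / (apply(B, 1, sd) / sqrt(5))
  zm <- second_level_z(maps, fwhm_mm = 0)
  expect_equal(order(tstat), order(as.vector(zm$z)))
})

test_that("FDR + extent thresholding keeps a 150-voxel blob, drops a 99-voxel one", {
  d <- study_design()
  run_blob <- function(nx, ny, nz, seed) {
    shape <- c(14, 14, 10)
    eff <- array(FALSE, shape)
    eff[seq_len(nx) + 3, seq_len(ny) + 3, seq_len(nz) + 2] <- TRUE
    truth <- effect_spec(c(surp_RNNG_LC = 2.5), sigma_subject = 0,
                         sigma_noise = 1, ar1_rho = 0.2, n_subjects = 6L)
    vols <- simulate_volume_bold(shape, eff, d, truth, seed = seed)
    maps <- lapply(vols, function(v)
      first_level_glm(v, d, predictors = "surp_RNNG_LC")[["surp_RNNG_LC"]])
    zm <- second_level_z(maps, fwhm_mm = 0)
    list(res = fdr_cluster_threshold(zm, 0.05, 100), n = sum(eff))
  }
  big <- run_blob(6, 5, 5, seed = 9)       # 150 voxels
  expect_equal(big$n, 150L)
  expect_equal(nrow(big$res$clusters), 1L)
  expect_gte(big$res$clusters$size_voxels[1], 100)
  small <- run_blob(9, 11, 1, seed = 10)   # 99 voxels
  expect_equal(small$n, 99L)
  expect_equal(nrow(small$res$clusters), 0L)
})

test_that("null maps almost never yield surviving clusters", {
  set.seed(12)
  shape <- c(12, 12, 8)
  hits <- replicate(200, {
    maps <- lapply(1:8, function(i) array(rnorm(prod(shape)), shape))
    zm <- second_level_z(maps, fwhm_mm = 0)
    nrow(fdr_cluster_threshold(zm, 0.05, 100)$clusters)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("FDR is monotone in q and cluster sizes convert exactly to mm3", {
  set.seed(14)
  shape <- c(10, 10, 8)
  maps <- lapply(1:6, function(i)
    array(rnorm(prod(shape)) + as.vector(outer(1:10, 1:10) > 60) * 2, shape))
  zm <- second_level_z(maps, fwhm_mm = 0)
  surv <- vapply(c(0.2, 0.05, 0.01), function(q)
    sum(!is.na(fdr_cluster_threshold(zm, q, 1)$thresholded)), integer(1))
  expect_true(all(diff(surv) <= 0))
  res <- fdr_cluster_threshold(zm, 0.2, 1)
  expect_equal(res$clusters$size_mm3, res$clusters$size_voxels * prod(c(3, 3, 4)))
})

test_that("pipeline is equivariant under lattice translation of the volumes", {
  d <- study_design()
  shape <- c(12, 12, 8)
  eff <- array(FALSE, shape)
  eff[3:7, 3:7, 3:6] <- TRUE
  truth <- effect_spec(c(surp_RNNG_LC = 3), sigma_subject = 0,
                       sigma_noise = 0.8, ar1_rho = 0, n_subjects = 5L)
  vols <- simulate_volume_bold(shape, eff, d, truth, seed = 77)
  roll_x <- function(a, s) a[c((shape[1] - s + 1):shape[1],
                               1:(shape[1] - s)), , , , drop = FALSE]
  run <- function(vs) {
    maps <- lapply(vs, function(v)
      first_level_glm(v, d, predictors = "surp_RNNG_LC")[["surp_RNNG_LC"]])
    zm <- second_level_z(maps, fwhm_mm = 0)
    fdr_cluster_threshold(zm, 0.05, 50)$clusters
  }
  vols2 <- lapply(vols, function(v) { v$data <- roll_x(v$data, 2); v })
  c0 <- run(vols); c2 <- run(vols2)
  expect_equal(nrow(c0), 1L)
  expect_equal(nrow(c2), 1L)
  expect_equal(c2$peak_x, c0$peak_x + 2)
  expect_equal(c2$peak_y, c0$peak_y)
  expect_equal(c2$peak_stat, c0$peak_stat)
  expect_equal(c2$size_voxels, c0$size_voxels)
})

test_that("cluster connectivity options label as expected", {
  keep <- array(FALSE, c(4, 4, 1))
  keep[1, 1, 1] <- TRUE; keep[2, 2, 1] <- TRUE  # diagonal touch
  lab6 <- rnngbold:::label_clusters(keep, 6)
  lab26 <- rnngbold:::label_clusters(keep, 26)
  expect_equal(max(lab6), 2L)
  expect_equal(max(lab26), 1L)
})
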