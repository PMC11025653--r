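#' Simulated 4-D BOLD volumes with a known effect mask
#'
#' Per subject, every voxel carries stationary AR(1) noise; voxels inside
#' `effect_voxels` additionally carry the design effect `X %*% beta` from
#' `truth$beta`. Frame spacing is TR = 2 s.
#'
#' @param shape Integer grid shape `c(x, y, z)`.
#' @param effect_voxels Logical 3-D array (same shape): voxels carrying the
#'   effect; `NULL` = none.
#' @param design A `design_matrix`.
#' @param truth An [effect_spec()].
#' @param voxel_size_mm Numeric length-3 voxel dimensions (default
#'   `c(3, 3, 4)` mm).
#' @param seed Integer seed.
#' @return List of class `volume_series`, one entry per subject:
#'   `data` (4-D array x,y,z,t), `frame_times`, `voxel_size_mm`, `mask`
#'   (all-TRUE analysis mask).
#' @export
simulate_volume_bold <- function(shape, effect_voxels = NULL, design, truth,
                                 voxel_size_mm = c(3, 3, 4), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("invalid parameter: shape must be 3 positive integers")
  nv <- prod(shape)
  if (is.null(effect_voxels)) effect_voxels <- array(FALSE, shape)
  if (!all(dim(effect_voxels) == shape))
    stop("effect mask shape must equal grid shape")
  X <- design$X
  n <- nrow(X)
  mu <- as.vector(X[, names(truth$beta), drop = FALSE] %*% truth$beta)
  rng <- local_rng(sub_seed(seed, "vol-bold"))
  ev <- as.vector(effect_voxels)
  out <- vector("list", truth$n_subjects)
  for (s in seq_len(truth$n_subjects)) {
    eps <- matrix(stats::rnorm(n * nv), n, nv)
    if (abs(truth$ar1_rho) > 0) {
      sfac <- sqrt(1 - truth$ar1_rho^2)
      for (t in 2:n) eps[t, ] <- truth$ar1_rho * eps[t - 1, ] +
          sfac * eps[t, ]
    }
    eps <- eps * truth$sigma_noise
    Y <- eps
    Y[, ev] <- Y[, ev] + mu
    out[[s]] <- list(data = array(t(Y), dim = c(shape, n)),
                     frame_times = seq(0, by = 2, length.out = n),
                     voxel_size_mm = voxel_size_mm,
                     mask = array(TRUE, shape))
  }
  class(out) <- "volume_series_set"
  out
}

#' Separable Gaussian smoothing of a volume
#'
#' `sigma = FWHM / (2 sqrt(2 log 2))` per axis in mm, converted to voxel
#' units; boundaries are handled by reflection, so a constant volume is
#' unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param vol 3-D array (or 4-D; smoothing applied per volume).
#' @param fwhm_mm Full width at half maximum in mm (> 0, or 0 = identity).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return Smoothed array, same shape.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, voxel_size_mm = c(3, 3, 4)) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  if (length(dim(vol)) == 4L) {
    for (t in seq_len(dim(vol)[4]))
      vol[, , , t] <- gaussian_smooth(vol[, , , t], fwhm_mm, voxel_size_mm)
    return(vol)
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(vol)
  for (ax in 1:3) {
    sig <- sigma_mm / voxel_size_mm[ax]
    r <- max(1L, ceiling(3 * sig))
    k <- stats::dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    L <- d[ax]
    # banded operator with reflecting boundaries (preserves constants)
    W <- matrix(0, L, L)
    for (i in seq_len(L)) for (o in -r:r) {
      j <- i + o
      if (j < 1L) j <- 1L - j
      if (j > L) j <- 2L * L + 1L - j
      j <- max(1L, min(L, j))
      W[i, j] <- W[i, j] + k[o + r + 1L]
    }
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dim(v) <- c(d[ax], prod(d[-ax]))
    v <- W %*% v
    dim(v) <- d[perm]
    vol <- aperm(v, order(perm))
  }
  vol
}

#' First-level (per-subject) voxelwise GLM
#'
#' Ordinary least squares of every voxel's time series on the design
#' (motion columns excluded, matching the first-level convention); returns
#' one beta map per named predictor.
#'
#' @param volume One element of [simulate_volume_bold()] output.
#' @param design A `design_matrix`.
#' @param predictors Columns to return maps for (default: all non-motion).
#' @return Named list of 3-D beta arrays (class `stat_map_set`), with
#'   attributes `voxel_size_mm` and `mask`.
#' @export
first_level_glm <- function(volume, design,
                            predictors = setdiff(colnames(design$X),
                                                 c("dx", "dy", "dz",
                                                   "rx", "ry", "rz"))) {
  X <- cbind(`(Intercept)` = 1,
             design$X[, setdiff(colnames(design$X),
                                c("dx", "dy", "dz", "rx", "ry", "rz")),
                      drop = FALSE])
  d <- dim(volume$data)
  n <- d[4]
  if (n != nrow(X)) stop("frame counts of volume and design differ")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient design")
  Y <- matrix(volume$data, prod(d[1:3]), n)  # voxels x time
  B <- qr.coef(qrx, t(Y))                    # p x voxels
  out <- lapply(predictors, function(cn)
    array(B[cn, ], dim = d[1:3]))
  names(out) <- predictors
  attr(out, "voxel_size_mm") <- volume$voxel_size_mm
  attr(out, "mask") <- volume$mask
  class(out) <- "stat_map_set"
  out
}

#' Second-level one-sample z map
#'
#' Voxelwise one-sample t test of subject beta maps against zero, mapped to
#' z by matching tail probabilities (monotone in t). Voxels with zero
#' across-subject variance are capped at `z_cap` and flagged.
#'
#' @param beta_maps List (one per subject) of 3-D beta arrays for one
#'   predictor.
#' @param mask Logical 3-D array; voxels outside are `NA`.
#' @param fwhm_mm Smoothing applied to each subject map first (default 8).
#' @param voxel_size_mm Voxel size for smoothing.
#' @param z_cap Cap for infinite z (default 40).
#' @return List of class `stat_map`: `z` (3-D array, `NA` outside mask),
#'   `n_subjects`, `capped` (logical array).
#' @export
second_level_z <- function(beta_maps, mask = NULL, fwhm_mm = 8,
                           voxel_size_mm = c(3, 3, 4), z_cap = 40) {
  ns <- length(beta_maps)
  if (ns < 3L) stop("need at least 3 subjects")
  d <- dim(beta_maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  if (fwhm_mm > 0)
    beta_maps <- lapply(beta_maps, gaussian_smooth, fwhm_mm = fwhm_mm,
                        voxel_size_mm = voxel_size_mm)
  B <- vapply(beta_maps, as.vector, numeric(prod(d)))
  mean_b <- rowMeans(B)
  sd_b <- apply(B, 1, stats::sd)
  tstat <- mean_b / (sd_b / sqrt(ns))
  capped <- !is.finite(tstat) | sd_b == 0
  tstat[capped] <- sign(mean_b[capped]) * Inf
  df <- ns - 1
  z <- ifelse(tstat >= 0,
              stats::qnorm(stats::pt(tstat, df, lower.tail = FALSE,
                                     log.p = TRUE),
                           lower.tail = FALSE, log.p = TRUE),
              stats::qnorm(stats::pt(tstat, df, log.p = TRUE), log.p = TRUE))
  z <- pmin(pmax(z, -z_cap), z_cap)
  z[!as.vector(mask)] <- NA
  structure(list(z = array(z, d), n_subjects = ns,
                 capped = array(capped & as.vector(mask), d),
                 voxel_size_mm = voxel_size_mm, mask = mask),
            class = "stat_map")
}

# connected components of a logical 3-D array (6/18/26-connectivity)
label_clusters <- function(keep, connectivity = 6L) {
  d <- dim(keep)
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
    "18" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o[rowSums(abs(o)) %in% c(1, 2), , drop = FALSE]
    },
    "26" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o[rowSums(abs(o)) > 0, , drop = FALSE]
    },
    stop("connectivity must be 6, 18 or 26"))
  lab <- array(0L, d)
  nextlab <- 0L
  idx <- which(keep)
  for (v in idx) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    lab[v] <- nextlab
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        ni <- ci + offs[r, ]
        if (any(ni < 1L) || any(ni > d)) next
        nl <- ni[1] + (ni[2] - 1L) * d[1] + (ni[3] - 1L) * d[1] * d[2]
        if (keep[nl] && lab[nl] == 0L) {
          lab[nl] <- nextlab
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

#' FDR + cluster-extent thresholding of a z map
#'
#' Two-sided voxelwise p-values within the mask are corrected by
#' Benjamini-Hochberg at rate `q`; surviving voxels are grouped into
#' connected clusters (6-connectivity by default; 18/26 by config) and
#' clusters smaller than `min_extent` voxels are removed. The study's
#' settings are `q = 0.05` and `min_extent = 100`.
#'
#' @param zmap A `stat_map` from [second_level_z()].
#' @param q FDR rate (default 0.05).
#' @param min_extent Minimum cluster size in voxels (default 100).
#' @param connectivity 6, 18, or 26.
#' @return List: `thresholded` (z array, `NA` where not surviving) and
#'   `clusters` (data frame: `cluster`, `peak_x`, `peak_y`, `peak_z`,
#'   `peak_stat`, `size_voxels`, `size_mm3`).
#' @export
fdr_cluster_threshold <- function(zmap, q = 0.05, min_extent = 100L,
                                  connectivity = 6L) {
  z <- zmap$z
  inmask <- !is.na(z)
  if (!any(inmask)) stop("empty mask")
  p <- 2 * stats::pnorm(-abs(z[inmask]))
  sig <- stats::p.adjust(p, method = "BH") <= q
  keep <- array(FALSE, dim(z))
  keep[inmask] <- sig
  lab <- label_clusters(keep, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  ok <- which(sizes >= min_extent)
  thr <- array(NA_real_, dim(z))
  rows <- list()
  vox_mm3 <- prod(zmap$voxel_size_mm)
  for (ci in seq_along(ok)) {
    cl <- ok[ci]
    vox <- which(lab == cl)
    thr[vox] <- z[vox]
    peak <- vox[which.max(abs(z[vox]))]
    pc <- arrayInd(peak, dim(z))
    rows[[ci]] <- data.frame(cluster = ci, peak_x = pc[1], peak_y = pc[2],
                             peak_z = pc[3], peak_stat = z[peak],
                             size_voxels = sizes[cl],
                             size_mm3 = sizes[cl] * vox_mm3)
  }
  clusters <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster = integer(0), peak_x = integer(0), peak_y = integer(0),
               peak_z = integer(0), peak_stat = numeric(0),
               size_voxels = integer(0), size_mm3 = numeric(0))
  list(thresholded = thr, clusters = clusters)
}

#' Write a 3-D/4-D array as NIfTI (requires the RNifti package)
#' @param vol Numeric array.
#' @param path Output `.nii` path.
#' @param voxel_size_mm Voxel dimensions.
#' @export
write_volume_nifti <- function(vol, path, voxel_size_mm = c(3, 3, 4)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cluster table as TSV
#' @param clusters Cluster data frame from [fdr_cluster_threshold()].
#' @param path Output path.
#' @export
write_cluster_tsv <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
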