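#' Canonical hemodynamic response function
#'
#' Double-gamma HRF: a gamma-density peak (delay 6 s, dispersion 1 s) minus
#' a gamma-density undershoot (delay 16 s, dispersion 1 s) scaled by 1/6,
#' peak-normalized to 1. Zero for `t <= 0` (causality); the response peaks
#' between 4 and 6 s and is negative around 16 s (late undershoot).
#'
#' @param t Time in seconds (vectorized).
#' @param peak_delay,under_delay Gamma shape parameters (s).
#' @param peak_disp,under_disp Gamma scale parameters (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF amplitude(s), peak-normalized.
#' @export
canonical_hrf <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 6) {
  raw <- function(x) {
    v <- numeric(length(x))
    pos <- x > 0
    v[pos] <- stats::dgamma(x[pos], shape = peak_delay / peak_disp,
                            scale = peak_disp) -
      stats::dgamma(x[pos], shape = under_delay / under_disp,
                    scale = under_disp) / ratio
    v
  }
  grid <- seq(0, 32, by = 0.01)
  peak <- max(raw(grid))
  raw(t) / peak
}

#' Convolve event amplitudes with the HRF onto fMRI frame times
#'
#' Places an amplitude-weighted copy of the HRF at each event time on a
#' finely oversampled grid (`TR / oversample`), sums them (linear
#' superposition), and samples the result at the frame times. Events later
#' than the last frame contribute nothing (with a warning).
#'
#' @param events Data frame with columns `time` (s) and `amplitude`.
#' @param frame_times Uniformly spaced frame times (s); spacing defines TR.
#' @param oversample Oversampling factor for the internal grid (default 50;
#'   sub-TR event timing, 1 s SOA vs 2 s TR, demands a fine grid).
#' @param hrf HRF function (default [canonical_hrf()]).
#' @return Numeric column, one value per frame time.
#' @export
convolve_events <- function(events, frame_times, oversample = 50L,
                            hrf = canonical_hrf) {
  stopifnot(all(c("time", "amplitude") %in% names(events)))
  if (nrow(events) == 0L) return(numeric(length(frame_times)))
  if (is.unsorted(events$time)) events <- events[order(events$time), ]
  tr <- if (length(frame_times) > 1L) diff(frame_times)[1] else 2
  if (length(frame_times) > 2L &&
      max(abs(diff(diff(frame_times)))) > 1e-9)
    stop("frame times must be uniformly spaced")
  dt <- tr / oversample
  t0 <- min(frame_times[1], events$time[1], 0)
  t1 <- frame_times[length(frame_times)]
  late <- events$time > t1
  if (any(late)) {
    warning(sprintf("%d event(s) after the last frame: contribution truncated",
                    sum(late)))
    events <- events[!late, , drop = FALSE]
    if (nrow(events) == 0L) return(numeric(length(frame_times)))
  }
  grid <- seq(t0, t1, by = dt)
  x <- numeric(length(grid))
  idx <- round((events$time - t0) / dt) + 1L
  for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + events$amplitude[i]
  kern <- hrf(seq(0, max(48, t1 - t0), by = dt))
  y <- stats::convolve(x, rev(kern), type = "open")[seq_along(grid)]
  fidx <- round((frame_times - t0) / dt) + 1L
  y[fidx]
}

#' Orthogonalize a column against a set of base columns
#'
#' Returns `target` minus its least-squares projection onto
#' `span(base, constant)`; the residual has (numerically) zero inner product
#' with every base column and with the intercept.
#'
#' @param target Numeric vector.
#' @param base Numeric matrix (columns are the base).
#' @return Residual vector.
#' @export
orthogonalize <- function(target, base) {
  base <- cbind(`(intercept)` = 1, as.matrix(base))
  qrb <- qr(base)
  if (qrb$rank < ncol(base)) {
    bad <- colnames(base)[qrb$pivot[(qrb$rank + 1L):ncol(base)]]
    stop("rank-deficient base; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  as.vector(stats::resid(stats::lm.fit(base, target)))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance column cannot be standardized")
  (x - mean(x)) / s
}

#' Build the fMRI design matrix from a schedule and complexity metrics
#'
#' The full pipeline from per-segment predictors to analysis-ready
#' regressors, per block:
#' \enumerate{
#'   \item event series at segment offsets: `word_rate` (amplitude 1),
#'     `word_length` (characters per segment), `word_freq` (log mean
#'     within-corpus relative word frequency), `sentid`, `sentpos`, and the
#'     language-model metrics (`ngram`, `lstm`, `surp_RNNG_TD`,
#'     `surp_RNNG_LC`, `dis_RNNG_TD`, `dis_RNNG_LC`);
#'   \item HRF convolution of every event series, sampled at 0.5 Hz
#'     (TR = 2 s);
#'   \item the LM-metric columns are each orthogonalized against the
#'     convolved `word_rate` (plus constant);
#'   \item motion columns (`dx, dy, dz, rx, ry, rz`) appended unconvolved;
#'   \item frames in the first `discard_lead_s` seconds of each block
#'     dropped; all columns standardized (mean 0, sd 1).
#' }
#'
#' @param schedule A `stimulus_schedule`.
#' @param metrics Data frame keyed like `schedule$segments` with one column
#'   per LM metric (see [segment_metric_table()]).
#' @param motion Optional frames x 6 matrix/data frame of head-motion
#'   parameters (frame-aligned across all blocks, post-discard rows are
#'   taken by position); `NULL` simulates none (zeros are not allowed by
#'   standardization, so `NULL` draws smooth random motion with `seed`).
#' @param tr Repetition time (s), default 2 (0.5 Hz).
#' @param oversample Oversampling for [convolve_events()].
#' @param seed Seed for simulated motion when `motion` is `NULL`.
#' @return Object of class `design_matrix`: `X` (standardized matrix),
#'   `frames` (data frame `block`, `time`), `provenance` (orthogonalization
#'   graph and parameters).
#' @export
build_design <- function(schedule, metrics, motion = NULL, tr = 2,
                         oversample = 50L, seed = 1L) {
  seg <- schedule$segments
  lm_cols <- c("ngram", "lstm", "surp_RNNG_TD", "surp_RNNG_LC",
               "dis_RNNG_TD", "dis_RNNG_LC")
  have_lm <- intersect(lm_cols, names(metrics))
  if (length(have_lm) == 0L)
    stop("schema error: metrics has none of the LM predictor columns")
  if (!all(seg$segment_id %in% metrics$segment_id))
    stop("schema error: metrics missing segments")
  metrics <- metrics[match(seg$segment_id, metrics$segment_id), , drop = FALSE]
  # corpus word frequencies for word_freq (relative frequency in stimuli)
  all_toks <- unlist(strsplit(seg$tokens, " ", fixed = TRUE))
  ftab <- table(all_toks) / length(all_toks)
  seg_vals <- data.frame(
    word_rate = rep(1, nrow(seg)),
    word_length = nchar(gsub(" ", "", seg$tokens, fixed = TRUE)),
    word_freq = vapply(strsplit(seg$tokens, " ", fixed = TRUE), function(tk)
      log(mean(as.numeric(ftab[tk]))), numeric(1)))
  for (cn in have_lm) seg_vals[[cn]] <- metrics[[cn]]
  seg_vals$sentid <- seg$sentid
  seg_vals$sentpos <- seg$sentpos
  ord_cols <- c("word_rate", "word_length", "word_freq", "sentid", "sentpos",
                have_lm)
  blocks <- sort(unique(seg$block))
  Xb <- list(); frames <- list()
  for (b in seq_along(blocks)) {
    bi <- blocks[b]
    sb <- seg$block == bi
    ft <- seq(0, schedule$block_duration_s[b], by = tr)
    cols <- vapply(ord_cols, function(cn)
      convolve_events(data.frame(time = seg$offset[sb],
                                 amplitude = seg_vals[[cn]][sb]),
                      ft, oversample = oversample),
      numeric(length(ft)))
    keep <- ft >= schedule$discard_lead_s
    Xb[[b]] <- cols[keep, , drop = FALSE]
    frames[[b]] <- data.frame(block = bi, time = ft[keep])
  }
  X <- do.call(rbind, Xb)
  frames <- do.call(rbind, frames)
  # orthogonalize each LM column independently against {constant, word_rate}
  for (cn in have_lm)
    X[, cn] <- orthogonalize(X[, cn], X[, "word_rate", drop = FALSE])
  # motion: frame-aligned, never convolved
  mot_names <- c("dx", "dy", "dz", "rx", "ry", "rz")
  if (is.null(motion)) {
    rng <- local_rng(sub_seed(seed, "motion"))
    motion <- vapply(mot_names, function(cn) {
      raw <- stats::rnorm(nrow(X))
      as.vector(stats::filter(raw, rep(1 / 8, 8), sides = 1,
                              method = "convolution")) -> sm
      sm[is.na(sm)] <- raw[is.na(sm)]
      sm
    }, numeric(nrow(X)))
  } else {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(X))
      stop("schema error: motion rows must match retained frames")
    colnames(motion) <- mot_names
  }
  X <- cbind(X, motion)
  X <- apply(X, 2, standardize)
  structure(list(
    X = X, frames = frames,
    provenance = list(
      orthogonalized = stats::setNames(rep("word_rate", length(have_lm)),
                                       have_lm),
      hrf = "double-gamma 6/16/1/1/6 peak-normalized",
      tr = tr, oversample = oversample,
      discard_lead_s = schedule$discard_lead_s, seed = seed)),
    class = "design_matrix")
}

#' Pearson correlations among design columns
#'
#' @param design A `design_matrix` (or plain matrix).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
predictor_correlations <- function(design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(X) < 2L) stop("need at least two columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  stats::cor(X)
}

#' Frame censoring by z-score
#'
#' Marks frames whose absolute z-score exceeds `z_thresh` (default 3); the
#' mask is consumed by the fitting stage, which drops masked rows. A
#' constant series yields an empty mask; masking every frame is an error.
#'
#' @param values Numeric vector (one ROI time series).
#' @param z_thresh Threshold (default 3.0).
#' @return Logical vector, `TRUE` = censored.
#' @export
censor_outliers <- function(values, z_thresh = 3) {
  stopifnot(all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  mask <- abs((values - mean(values)) / s) > z_thresh
  if (all(mask)) stop("all frames censored")
  mask
}

#' Write a design matrix as TSV with a JSON provenance sidecar
#' @param design A `design_matrix`.
#' @param path Output TSV path; the sidecar is `paste0(path, ".json")`.
#' @export
write_design_tsv <- function(design, path) {
  df <- cbind(design$frames, as.data.frame(design$X))
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(design$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
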