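#' Build a stimulus presentation schedule from a treebank
#'
#' Emulates rapid serial visual presentation of phrasal segments: each
#' sentence's tokens are chunked into segments of 1-3 tokens, sentences are
#' dealt into `blocks` blocks in order, and within a block segment onsets
#' fall at `lead_s + k * soa_s` (k = 0, 1, ...). Each segment is displayed
#' for `display_s` seconds followed by a blank, so `offset = onset +
#' display_s`; the default 1 s stimulus-onset asynchrony reflects a 500 ms
#' display plus 500 ms blank. The first `discard_lead_s` seconds of each
#' block carry no stimuli and are excluded from analysis downstream.
#'
#' @param treebank List of `syntax_tree` (one per sentence).
#' @param blocks Number of presentation blocks.
#' @param soa_s Stimulus-onset asynchrony in seconds (> 0; default 1.0).
#' @param display_s Display duration in seconds (default 0.5).
#' @param discard_lead_s Lead-in per block with no stimuli (default 20).
#' @param max_tokens_per_segment Segment length cap (default 3).
#' @param tail_s Rest appended after the last segment of a block (default 10).
#' @param seed Seed for the random segmentation.
#' @return Object of class `stimulus_schedule`: list with `segments` (data
#'   frame: `segment_id`, `tokens`, `onset`, `offset`, `block`, `sentid`,
#'   `sentpos`, `sentence_key`), `soa_s`, `display_s`, `discard_lead_s`,
#'   `block_duration_s`.
#' @export
make_stimulus_schedule <- function(treebank, blocks = 4L, soa_s = 1.0,
                                   display_s = 0.5, discard_lead_s = 20,
                                   max_tokens_per_segment = 3L, tail_s = 10,
                                   seed = 1L) {
  if (length(treebank) == 0L) stop("treebank is empty")
  if (soa_s <= 0) stop("invalid parameter: soa_s must be > 0")
  if (display_s > soa_s) stop("invalid parameter: display_s exceeds soa_s")
  rng <- local_rng(sub_seed(seed, "schedule"))
  yields <- lapply(treebank, tree_yield)
  # deal sentences into blocks in order, balanced sizes
  nb <- min(as.integer(blocks), length(yields))
  sizes <- rep(length(yields) %/% nb, nb) +
    (seq_len(nb) <= length(yields) %% nb)
  block_of <- rep(seq_len(nb), sizes)
  rows <- list()
  seg_id <- 0L
  for (b in seq_len(nb)) {
    k <- 0L
    sent_in_block <- 0L
    for (si in which(block_of == b)) {
      sent_in_block <- sent_in_block + 1L
      toks <- yields[[si]]
      segs <- list()
      i <- 1L
      while (i <= length(toks)) {
        take <- min(sample.int(max_tokens_per_segment, 1L),
                    length(toks) - i + 1L)
        segs[[length(segs) + 1L]] <- toks[i:(i + take - 1L)]
        i <- i + take
      }
      for (sp in seq_along(segs)) {
        seg_id <- seg_id + 1L
        onset <- discard_lead_s + k * soa_s
        rows[[seg_id]] <- data.frame(
          segment_id = seg_id,
          tokens = paste(segs[[sp]], collapse = " "),
          onset = onset, offset = onset + display_s,
          block = b, sentid = sent_in_block, sentpos = sp,
          sentence_key = sprintf("b%d_s%d", b, sent_in_block),
          stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  segments <- do.call(rbind, rows)
  dur <- vapply(seq_len(nb), function(b)
    max(segments$offset[segments$block == b]) + tail_s, numeric(1))
  structure(list(segments = segments, soa_s = soa_s, display_s = display_s,
                 discard_lead_s = discard_lead_s,
                 block_duration_s = dur),
            class = "stimulus_schedule")
}

#' Write / read a stimulus schedule as TSV
#' @param schedule A `stimulus_schedule`.
#' @param path File path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sentences of a schedule as token lists
#'
#' Reassembles the tokenized sentences (in presentation order) from the
#' segments; names are the `sentence_key`s.
#' @param schedule A `stimulus_schedule`.
#' @return Named list of character vectors.
#' @export
schedule_sentences <- function(schedule) {
  seg <- schedule$segments
  keys <- unique(seg$sentence_key)
  out <- lapply(keys, function(k) {
    s <- seg[seg$sentence_key == k, , drop = FALSE]
    s <- s[order(s$sentpos), , drop = FALSE]
    unlist(strsplit(s$tokens, " ", fixed = TRUE), use.names = FALSE)
  })
  names(out) <- keys
  out
}

#' Ground-truth effect specification for BOLD simulation
#'
#' Houses the generative truth that parameter-recovery tests re-estimate.
#'
#' @param beta Named numeric vector: true coefficient per design column.
#' @param sigma_subject Random-intercept standard deviation (>= 0).
#' @param sigma_noise Residual standard deviation (> 0).
#' @param ar1_rho Lag-1 autocorrelation of the residual noise (|rho| < 1).
#' @param n_subjects Number of subjects.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(beta, sigma_subject = 0.3, sigma_noise = 1,
                        ar1_rho = 0.3, n_subjects = 34L) {
  stopifnot(is.numeric(beta), !is.null(names(beta)),
            sigma_subject >= 0, sigma_noise > 0, abs(ar1_rho) < 1,
            n_subjects >= 1)
  structure(list(beta = beta, sigma_subject = sigma_subject,
                 sigma_noise = sigma_noise, ar1_rho = ar1_rho,
                 n_subjects = as.integer(n_subjects)),
            class = "effect_spec")
}

# stationary AR(1) noise: x_1 ~ N(0, sd^2), innovations scaled so the
# marginal variance is sd^2 at every lag (no burn-in needed)
ar1_noise <- function(n, rho, sd) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  if (n > 1) {
    s <- sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + s * e[t]
  }
  x * sd
}

#' Simulate ROI BOLD time series with known ground truth
#'
#' `y_s = X beta + u_s + eps_s` per subject `s`, with `u_s ~ N(0,
#' sigma_subject^2)` and `eps_s` stationary AR(1) noise with the given rho
#' and marginal sd, simulated independently per block. Deterministic under
#' `seed`.
#'
#' @param design A `design_matrix` (see [build_design()]).
#' @param truth An [effect_spec()]; every name of `truth$beta` must be a
#'   design column.
#' @param seed Integer seed.
#' @return Matrix (frames x subjects) with class `roi_timeseries`; subject
#'   ids as column names.
#' @export
simulate_roi_bold <- function(design, truth, seed = 1L) {
  X <- design$X
  missing <- setdiff(names(truth$beta), colnames(X))
  if (length(missing) > 0L)
    stop("schema error: predictors absent from design: ",
         paste(missing, collapse = ", "))
  rng <- local_rng(sub_seed(seed, "roi-bold"))
  mu <- as.vector(X[, names(truth$beta), drop = FALSE] %*% truth$beta)
  n <- nrow(X)
  blocks <- design$frames$block
  Y <- matrix(0, n, truth$n_subjects)
  for (s in seq_len(truth$n_subjects)) {
    u <- stats::rnorm(1, 0, truth$sigma_subject)
    eps <- unlist(lapply(split(seq_len(n), blocks), function(ix)
      ar1_noise(length(ix), truth$ar1_rho, truth$sigma_noise)),
      use.names = FALSE)
    Y[, s] <- mu + u + eps
  }
  colnames(Y) <- sprintf("sub%02d", seq_len(truth$n_subjects))
  structure(Y, class = c("roi_timeseries", "matrix"), frames = design$frames)
}
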