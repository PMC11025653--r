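#' Per-segment complexity metrics for every model family
#'
#' Computes the six language-model predictors for each segment of a
#' stimulus schedule: `ngram` and `lstm` segment surprisal (sum of member
#' tokens' negative log probabilities), and beam-search `surp_RNNG_TD`,
#' `surp_RNNG_LC`, `dis_RNNG_TD`, `dis_RNNG_LC`.
#'
#' @param schedule A `stimulus_schedule`.
#' @param ngram A `kn_ngram` (or `NULL` to skip).
#' @param lstm A `sequence_lm` (or `NULL`).
#' @param rnng_td,rnng_lc `rnng_model`s (or `NULL`).
#' @param cfg A [beam_config()] for the RNNGs.
#' @return Data frame: `segment_id` plus one column per available metric.
#' @export
segment_metric_table <- function(schedule, ngram = NULL, lstm = NULL,
                                 rnng_td = NULL, rnng_lc = NULL,
                                 cfg = beam_config(k = 20)) {
  seg <- schedule$segments
  sentences <- schedule_sentences(schedule)
  out <- data.frame(segment_id = seg$segment_id)
  seq_surprisal <- function(model) {
    recs <- do.call(rbind, lapply(names(sentences), function(k) {
      lp <- lm_sentence_logprobs(model, sentences[[k]], eos = FALSE)
      data.frame(sentence = k, token_index = seq_along(lp),
                 surprisal = -lp, distance = 1)
    }))
    aggregate_segments(recs, schedule)$surprisal
  }
  if (!is.null(ngram)) out$ngram <- seq_surprisal(ngram)
  if (!is.null(lstm)) out$lstm <- seq_surprisal(lstm)
  rnng_metrics <- function(model) {
    recs <- do.call(rbind, lapply(names(sentences), function(k) {
      prof <- complexity_profile(model, sentences[[k]], cfg)
      data.frame(sentence = k, token_index = prof$token_index,
                 surprisal = prof$surprisal, distance = prof$distance)
    }))
    agg <- aggregate_segments(recs, schedule)
    list(surp = agg$surprisal, dis = agg$distance)
  }
  if (!is.null(rnng_td)) {
    m <- rnng_metrics(rnng_td)
    out$surp_RNNG_TD <- m$surp
    out$dis_RNNG_TD <- m$dis
  }
  if (!is.null(rnng_lc)) {
    m <- rnng_metrics(rnng_lc)
    out$surp_RNNG_LC <- m$surp
    out$dis_RNNG_LC <- m$dis
  }
  out
}

#' Write per-segment metrics as TSV
#' @param metrics Data frame from [segment_metric_table()].
#' @param path Output path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(format(metrics, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' A documented JSON container holding the model class, configuration,
#' vocabulary and all parameter arrays, so checkpoints are plain text and
#' portable.
#'
#' @param model A `sequence_lm`, `rnng_model`, or `kn_ngram`.
#' @param path Output `.json` path.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "kn_ngram")) {
    payload <- list(kind = "kn_ngram", order = model$order,
                    vocab = model$vocab$tokens,
                    support = model$support,
                    used = lapply(model$used, function(tb)
                      list(keys = names(tb), counts = as.integer(tb))),
                    discounts = model$discounts)
  } else {
    kind <- if (inherits(model, "rnng_model")) "rnng" else "sequence_lm"
    params <- lapply(model$params$val, function(v)
      list(dim = dim(v) %||% length(v), data = as.vector(v)))
    payload <- list(kind = kind, config = unclass(model$config),
                    params = params)
    if (kind == "rnng") {
      payload$words <- model$words
      payload$nts <- model$nts
      payload$strategy <- model$strategy
    } else {
      payload$vocab <- model$vocab$tokens
    }
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  restore_params <- function(params) {
    s <- new.env(parent = emptyenv())
    s$val <- lapply(params, function(p) {
      d <- unlist(p$dim)
      v <- unlist(p$data)
      if (length(d) > 1L) array(v, dim = d) else v
    })
    s$m <- lapply(s$val, function(v) v * 0)
    s$v <- lapply(s$val, function(v) v * 0)
    s$t <- 0L
    s
  }
  if (x$kind == "kn_ngram") {
    used <- lapply(x$used, function(u) {
      tb <- as.integer(unlist(u$counts))
      names(tb) <- unlist(u$keys)
      as.table(tb)
    })
    vocab <- structure(list(tokens = unlist(x$vocab), unk = "<unk>",
                            bos = "<s>", eos = "</s>"), class = "vocabulary")
    return(structure(list(vocab = vocab, order = x$order, used = used,
                          discounts = lapply(x$discounts, unlist),
                          support = unlist(x$support)),
                     class = "kn_ngram"))
  }
  if (x$kind == "rnng") {
    cfg <- structure(x$config, class = "rnng_config")
    return(structure(list(words = unlist(x$words), nts = unlist(x$nts),
                          strategy = x$strategy, config = cfg,
                          params = restore_params(x$params)),
                     class = "rnng_model"))
  }
  cfg <- structure(x$config, class = "seqlm_config")
  vocab <- structure(list(tokens = unlist(x$vocab), unk = "<unk>",
                          bos = "<s>", eos = "</s>"), class = "vocabulary")
  structure(list(vocab = vocab, config = cfg,
                 params = restore_params(x$params)),
            class = "sequence_lm")
}

#' Write / read ROI time series as TSV
#'
#' Long format: `roi`, `subject`, `block`, `time`, `value`.
#' @param responses Named list of frames x subjects matrices (per ROI).
#' @param frames Frame data frame (`block`, `time`) matching the rows.
#' @param path Output path.
#' @export
write_roi_tsv <- function(responses, frames, path) {
  rows <- lapply(names(responses), function(roi) {
    Y <- responses[[roi]]
    do.call(rbind, lapply(seq_len(ncol(Y)), function(s)
      data.frame(roi = roi, subject = colnames(Y)[s] %||% s,
                 block = frames$block, time = frames$time, value = Y[, s])))
  })
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
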