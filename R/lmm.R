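#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits `y = X beta + u[subject] + eps`, `u ~ N(0, sigma_u^2)`,
#' `eps ~ N(0, sigma_e^2)`, by maximum likelihood (never REML: fits feed
#' likelihood-ratio tests on fixed effects). The fixed effects and residual
#' variance are profiled out analytically; the single variance ratio
#' `lambda = sigma_u^2 / sigma_e^2` is optimized on a log scale. With a
#' single grouping factor the covariance inverse has the closed
#' Sherman-Morrison block form, so each likelihood evaluation costs only a
#' few p x p operations after one pass over the data.
#'
#' @param y Response vector (pooled subjects x frames).
#' @param X Fixed-effects design matrix (a column of ones is added for the
#'   intercept unless one is already present).
#' @param subject Grouping factor/vector, same length as `y`.
#' @return Object of class `lmm_fit`: `beta`, `se`, `sigma_u`, `sigma_e`,
#'   `logLik`, `n`, `ngroups`, `fixed` (column names), `reml = FALSE`.
#' @export
fit_lmm_ml <- function(y, X, subject) {
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(subject) == n)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("singular design; collinear column(s): ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]],
               collapse = ", "))
  g <- as.integer(factor(subject))
  G <- max(g)
  m_g <- tabulate(g, G)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  S <- rowsum(X, g)                 # G x p group column sums
  tvec <- as.vector(rowsum(y, g))   # group response sums
  prof <- function(loglam) {
    lam <- exp(loglam)
    cg <- lam / (1 + m_g * lam)
    A <- XtX - crossprod(S, S * cg)
    b <- Xty - crossprod(S, tvec * cg)
    q <- yty - sum(cg * tvec^2)
    beta <- solve(A, b)
    rss <- q - sum(b * beta)
    sig2 <- rss / n
    m2ll <- n * log(2 * pi * sig2) + sum(log1p(m_g * lam)) + n
    list(m2ll = m2ll, beta = beta, A = A, sig2 = sig2, lam = lam)
  }
  obj <- function(ll) prof(ll)$m2ll
  opt <- stats::optimize(obj, interval = c(-14, 12), tol = 1e-9)
  # compare with the boundary sigma_u = 0 (lambda -> 0)
  cand <- c(opt$minimum, -30)
  vals <- vapply(cand, obj, numeric(1))
  best <- prof(cand[which.min(vals)])
  if (!is.finite(best$m2ll)) stop("non-convergence in LMM optimizer")
  sig2 <- best$sig2
  se <- sqrt(diag(solve(best$A)) * sig2)
  structure(list(beta = stats::setNames(as.vector(best$beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 sigma_u = sqrt(best$lam * sig2), sigma_e = sqrt(sig2),
                 logLik = -best$m2ll / 2, n = n, ngroups = G,
                 fixed = colnames(X), reml = FALSE),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML): n = %d, groups = %d, logLik = %.4f\n",
              x$n, x$ngroups, x$logLik))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  cat(sprintf("sigma_subject = %.4f, sigma_resid = %.4f\n",
              x$sigma_u, x$sigma_e))
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chisq = 2 (logLik_full - logLik_reduced)`, compared against a
#' chi-square with df = difference in fixed-effect count. Both fits must be
#' maximum likelihood (REML-based comparison of fixed effects is a contract
#' error), on the same observations, with nested fixed effects.
#'
#' @param reduced,full `lmm_fit` objects.
#' @return One-row data frame: `ll_reduced`, `ll_full`, `chisq`, `df`, `p`.
#' @export
lrt <- function(reduced, full) {
  stopifnot(inherits(reduced, "lmm_fit"), inherits(full, "lmm_fit"))
  if (isTRUE(reduced$reml) || isTRUE(full$reml))
    stop("contract error: LRT on fixed effects requires ML fits, not REML")
  if (reduced$n != full$n)
    stop("mismatched observation sets (n differs)")
  if (!all(reduced$fixed %in% full$fixed))
    stop("models are not nested (reduced fixed effects not a subset)")
  df <- length(full$fixed) - length(reduced$fixed)
  if (df <= 0L) df <- 0L
  chisq <- 2 * (full$logLik - reduced$logLik)
  p <- if (df == 0L) 1 else stats::pchisq(max(chisq, 0), df,
                                          lower.tail = FALSE)
  data.frame(ll_reduced = reduced$logLik, ll_full = full$logLik,
             chisq = chisq, df = df, p = p)
}

#' Bonferroni significance gate
#'
#' Significant iff `p < alpha / m`; the study's gate is `alpha = 0.05` over
#' `m = 8` regions of interest, i.e. 0.00625.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m Number of comparisons (default 8).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector.
#' @export
bonferroni_gate <- function(p, m = 8L, alpha = 0.05) {
  if (m <= 0) stop("m must be positive")
  stopifnot(all(p >= 0 & p <= 1))
  p < alpha / m
}

#' The eight left-hemisphere regions of interest
#' @export
ROI_NAMES <- c("IFGoperc", "IFGtriang", "IFGorb", "IPL", "AG", "STG",
               "sATL", "mATL")

#' Nested model-comparison ladders
#'
#' Each ladder starts from the baseline fixed effects (`word_rate`,
#' `word_length`, `word_freq`, `sentid`, `sentpos`, six motion parameters)
#' plus a by-subject random intercept, and adds one predictor per step:
#' \describe{
#'   \item{`surp_td_first`}{+ngram, +lstm, +surp_RNNG_TD, +surp_RNNG_LC}
#'   \item{`surp_lc_first`}{+ngram, +lstm, +surp_RNNG_LC, +surp_RNNG_TD}
#'   \item{`dis_td_first`}{+ngram, +lstm, +dis_RNNG_TD, +dis_RNNG_LC}
#'   \item{`dis_lc_first`}{+ngram, +lstm, +dis_RNNG_LC, +dis_RNNG_TD}
#' }
#'
#' @param name Ladder name (above) or `"custom"`.
#' @param steps For `"custom"`: character vector of predictors to add.
#' @return Object of class `ladder_spec`.
#' @export
ladder_spec <- function(name = c("surp_td_first", "surp_lc_first",
                                 "dis_td_first", "dis_lc_first", "custom"),
                        steps = NULL) {
  name <- match.arg(name)
  steps <- switch(name,
    surp_td_first = c("ngram", "lstm", "surp_RNNG_TD", "surp_RNNG_LC"),
    surp_lc_first = c("ngram", "lstm", "surp_RNNG_LC", "surp_RNNG_TD"),
    dis_td_first = c("ngram", "lstm", "dis_RNNG_TD", "dis_RNNG_LC"),
    dis_lc_first = c("ngram", "lstm", "dis_RNNG_LC", "dis_RNNG_TD"),
    custom = steps)
  if (is.null(steps)) stop("custom ladder needs steps")
  structure(list(name = name, steps = steps), class = "ladder_spec")
}

BASELINE_COLS <- c("word_rate", "word_length", "word_freq", "sentid",
                   "sentpos", "dx", "dy", "dz", "rx", "ry", "rz")

# pool one ROI's subject series into (y, X, subject), applying censoring
pool_roi <- function(design, Y, z_thresh = 3) {
  n <- nrow(design$X)
  stopifnot(nrow(Y) == n)
  ys <- list(); Xs <- list(); subj <- list()
  for (s in seq_len(ncol(Y))) {
    mask <- censor_outliers(Y[, s], z_thresh)
    ys[[s]] <- Y[!mask, s]
    Xs[[s]] <- design$X[!mask, , drop = FALSE]
    subj[[s]] <- rep(colnames(Y)[s] %||% s, sum(!mask))
  }
  list(y = unlist(ys, use.names = FALSE), X = do.call(rbind, Xs),
       subject = unlist(subj, use.names = FALSE))
}

#' Run a model-comparison ladder over ROIs
#'
#' For each ROI: pools subjects' (censored) frames, fits the baseline model
#' and each ladder step by ML, and tests each added predictor with a
#' likelihood-ratio test; p-values are reported unadjusted with a separate
#' Bonferroni flag (`alpha / #ROIs`).
#'
#' @param design A `design_matrix` containing every ladder predictor.
#' @param responses Named list (one entry per ROI) of frames x subjects
#'   matrices, e.g. from [simulate_roi_bold()].
#' @param ladder A [ladder_spec()].
#' @param z_thresh Outlier-censoring threshold (default 3).
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return Data frame (one row per ROI x step): `roi`, `reduced`, `full`,
#'   `ll_full`, `chisq`, `df`, `p`, `significant`.
#' @export
run_ladder <- function(design, responses, ladder, z_thresh = 3,
                       alpha = 0.05) {
  stopifnot(inherits(ladder, "ladder_spec"))
  missing <- setdiff(c(BASELINE_COLS, ladder$steps), colnames(design$X))
  if (length(missing) > 0L)
    stop("schema error: design lacks predictor(s): ",
         paste(missing, collapse = ", "))
  m <- length(responses)
  rows <- list()
  for (roi in names(responses)) {
    pooled <- pool_roi(design, responses[[roi]], z_thresh)
    cols <- BASELINE_COLS
    fit0 <- fit_lmm_ml(pooled$y, pooled$X[, cols, drop = FALSE],
                       pooled$subject)
    label0 <- "baseline"
    for (step in ladder$steps) {
      cols <- c(cols, step)
      fit1 <- fit_lmm_ml(pooled$y, pooled$X[, cols, drop = FALSE],
                         pooled$subject)
      tst <- lrt(fit0, fit1)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, reduced = label0, full = paste0("+", step),
        ll_full = tst$ll_full, chisq = tst$chisq, df = tst$df, p = tst$p,
        significant = bonferroni_gate(tst$p, m = m, alpha = alpha),
        stringsAsFactors = FALSE)
      fit0 <- fit1
      label0 <- paste0("+", step)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a comparison table as text (shaped like the study tables)
#' @param comparisons Output of [run_ladder()].
#' @return Character vector of lines (invisibly printed).
#' @export
format_comparison_table <- function(comparisons) {
  lines <- sprintf("%-10s %-16s -> %-16s  logLik %10.2f  chisq %8.3f  df %d  p %s%s",
                   comparisons$roi, comparisons$reduced, comparisons$full,
                   comparisons$ll_full, comparisons$chisq, comparisons$df,
                   format.pval(comparisons$p, digits = 3),
                   ifelse(comparisons$significant, " *", ""))
  lines
}
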