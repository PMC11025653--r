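# Minimal tape-based reverse-mode automatic differentiation over numeric
# vectors/matrices. Every op takes the tape as first argument; with
# `tape = NULL` the same code path computes plain (gradient-free) numerics,
# which is what beam search and other inference-only callers use. This keeps
# a single forward implementation for training and inference.
#
# A node is list(val, parents = integer ids, bp = function(g) list of parent
# gradients). Backward sweeps the tape in reverse construction order.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t$pid <- list()   # param name -> leaf node id (one leaf per tape)
  t
}

ad_is_node <- function(x) inherits(x, "adnode")

ad_val <- function(x) if (ad_is_node(x)) x$val else x

ad_record <- function(tape, val, parents, bp) {
  i <- tape$n + 1L
  if (i > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[i]] <- list(parents = parents, bp = bp)
  tape$n <- i
  structure(list(id = i, val = val), class = "adnode")
}

# generic op builder: ins is the list of inputs (nodes or raw), bps the
# per-input gradient functions g -> grad contribution (same shape as input)
ad_op <- function(tape, val, ins, bps) {
  if (is.null(tape)) return(val)
  keep <- vapply(ins, ad_is_node, logical(1))
  if (!any(keep)) return(val)  # constant w.r.t. parameters
  parents <- vapply(ins[keep], function(x) x$id, integer(1))
  bpk <- bps[keep]
  ad_record(tape, val, parents, function(g) lapply(bpk, function(f) f(g)))
}

# parameter leaf: one node per parameter name per tape, so gradients from
# repeated uses accumulate onto the same leaf
ad_param <- function(tape, store, name) {
  v <- store$val[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  if (is.null(tape)) return(v)
  id <- tape$pid[[name]]
  if (!is.null(id)) return(structure(list(id = id, val = v), class = "adnode"))
  nd <- ad_record(tape, v, integer(0), NULL)
  tape$pid[[name]] <- nd$id
  nd
}

ad_const <- function(tape, val) val  # constants are raw

ad_matvec <- function(tape, W, x) {
  Wv <- ad_val(W); xv <- ad_val(x)
  val <- as.vector(Wv %*% xv)
  ad_op(tape, val, list(W, x),
        list(function(g) outer(g, xv),
             function(g) as.vector(crossprod(Wv, g))))
}

ad_add <- function(tape, a, b) {
  val <- ad_val(a) + ad_val(b)
  ad_op(tape, val, list(a, b), list(identity, identity))
}

ad_sub <- function(tape, a, b) {
  val <- ad_val(a) - ad_val(b)
  ad_op(tape, val, list(a, b), list(identity, function(g) -g))
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(tape, av * bv, list(a, b),
        list(function(g) g * bv, function(g) g * av))
}

ad_scale <- function(tape, a, k) {  # k plain scalar
  ad_op(tape, ad_val(a) * k, list(a), list(function(g) g * k))
}

ad_tanh <- function(tape, a) {
  val <- tanh(ad_val(a))
  ad_op(tape, val, list(a), list(function(g) g * (1 - val^2)))
}

ad_sigmoid <- function(tape, a) {
  val <- 1 / (1 + exp(-ad_val(a)))
  ad_op(tape, val, list(a), list(function(g) g * val * (1 - val)))
}

ad_slice <- function(tape, a, idx) {
  av <- ad_val(a)
  n <- length(av)
  ad_op(tape, av[idx], list(a),
        list(function(g) { z <- numeric(n); z[idx] <- g; z }))
}

ad_concat <- function(tape, xs) {
  vals <- lapply(xs, ad_val)
  lens <- lengths(vals)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  bps <- lapply(seq_along(xs), function(k) {
    s <- starts[k]; e <- ends[k]
    function(g) g[s:e]
  })
  ad_op(tape, unlist(vals, use.names = FALSE), xs, bps)
}

# row lookup in an embedding matrix; gradient scatters into the full matrix
ad_embed <- function(tape, E, row) {
  Ev <- ad_val(E)
  ad_op(tape, Ev[row, ], list(E),
        list(function(g) {
          Z <- array(0, dim = dim(Ev)); Z[row, ] <- g; Z
        }))
}

# negative log softmax probability of component `idx` of `logits`, with an
# optional logical mask of admissible components (others get zero probability)
ad_pick_nll <- function(tape, logits, idx, mask = NULL) {
  z <- ad_val(logits)
  if (!is.null(mask)) z[!mask] <- -Inf
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  val <- lse - z[idx]
  p <- exp(z - lse)
  p[!is.finite(p)] <- 0
  ad_op(tape, val, list(logits),
        list(function(g) { d <- p; d[idx] <- d[idx] - 1; g * d }))
}

# masked log-softmax as plain numeric vector (inference helper)
masked_log_softmax <- function(z, mask = NULL) {
  if (!is.null(mask)) z[!mask] <- -Inf
  z - logsumexp(z)
}

ad_backward <- function(tape, loss) {
  stopifnot(ad_is_node(loss))
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq.int(tape$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$bp)) next
    pg <- nd$bp(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# gather parameter gradients (named list; missing -> zero array)
ad_param_grads <- function(tape, grads, store) {
  out <- list()
  for (name in names(tape$pid)) {
    g <- grads[[tape$pid[[name]]]]
    if (is.null(g)) g <- array(0, dim = dim(store$val[[name]]) %||%
                                 length(store$val[[name]]))
    out[[name]] <- g
  }
  out
}

# ---- fused ops (hot path) ----
# One tape node per LSTM cell with hand-derived backward; the cell returns
# the concatenation [h2; c2] which callers slice. Cuts tape length ~5x.

ad_lstm_cell_fused <- function(tape, W, b, x, h, c, H) {
  Wv <- ad_val(W); bv <- ad_val(b)
  xv <- ad_val(x); hv <- ad_val(h); cv <- ad_val(c)
  xh <- c(xv, hv)
  z <- as.vector(Wv %*% xh) + bv
  i <- 1 / (1 + exp(-z[1:H]))
  f <- 1 / (1 + exp(-z[(H + 1):(2 * H)]))
  o <- 1 / (1 + exp(-z[(2 * H + 1):(3 * H)]))
  g <- tanh(z[(3 * H + 1):(4 * H)])
  c2 <- f * cv + i * g
  tc <- tanh(c2)
  h2 <- o * tc
  val <- c(h2, c2)
  nx <- length(xv)
  ad_op(tape, val, list(W, b, x, h, c), local({
    bp_core <- function(gr) {
      gh <- gr[1:H]; gc <- gr[(H + 1):(2 * H)]
      go <- gh * tc
      gc2 <- gc + gh * o * (1 - tc^2)
      gz <- c(gc2 * g * i * (1 - i),
              gc2 * cv * f * (1 - f),
              go * o * (1 - o),
              gc2 * i * (1 - g^2))
      list(gz = gz, gxh = as.vector(crossprod(Wv, gz)), gcprev = gc2 * f)
    }
    memo <- new.env(parent = emptyenv())
    core <- function(gr) {
      k <- "last"
      if (!is.null(memo$g) && identical(memo$g, gr)) return(memo$res)
      res <- bp_core(gr)
      memo$g <- gr; memo$res <- res
      res
    }
    list(
      function(gr) outer(core(gr)$gz, xh),
      function(gr) core(gr)$gz,
      function(gr) core(gr)$gxh[seq_len(nx)],
      function(gr) core(gr)$gxh[(nx + 1L):(nx + H)],
      function(gr) core(gr)$gcprev)
  }))
}

ad_affine_tanh <- function(tape, W, b, x) {
  Wv <- ad_val(W); bv <- ad_val(b); xv <- ad_val(x)
  val <- tanh(as.vector(Wv %*% xv) + bv)
  ad_op(tape, val, list(W, b, x), list(
    function(g) outer(g * (1 - val^2), xv),
    function(g) g * (1 - val^2),
    function(g) as.vector(crossprod(Wv, g * (1 - val^2)))))
}

# NLL of component idx of softmax(W x + b) with optional legality mask,
# in a single node
ad_affine_pick_nll <- function(tape, W, b, x, idx, mask = NULL) {
  Wv <- ad_val(W); bv <- ad_val(b); xv <- ad_val(x)
  z <- as.vector(Wv %*% xv) + bv
  if (!is.null(mask)) z[!mask] <- -Inf
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  val <- lse - z[idx]
  p <- exp(z - lse)
  p[!is.finite(p)] <- 0
  d <- p; d[idx] <- d[idx] - 1
  ad_op(tape, val, list(W, b, x), list(
    function(g) outer(g * d, xv),
    function(g) g * d,
    function(g) as.vector(crossprod(Wv, g * d))))
}

# ---- parameter store and Adam optimizer ----

param_store <- function(shapes, seed, init_scale = 0.1) {
  rng <- local_rng(seed)
  s <- new.env(parent = emptyenv())
  s$val <- lapply(shapes, function(d) {
    n <- prod(d)
    v <- stats::runif(n, -init_scale, init_scale)
    if (length(d) > 1L) array(v, dim = d) else v
  })
  names(s$val) <- names(shapes)
  s$m <- lapply(s$val, function(v) v * 0)
  s$v <- lapply(s$val, function(v) v * 0)
  s$t <- 0L
  s
}

adam_step <- function(store, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  store$t <- store$t + 1L
  t <- store$t
  for (name in names(grads)) {
    g <- grads[[name]]
    store$m[[name]] <- beta1 * store$m[[name]] + (1 - beta1) * g
    store$v[[name]] <- beta2 * store$v[[name]] + (1 - beta2) * g^2
    mhat <- store$m[[name]] / (1 - beta1^t)
    vhat <- store$v[[name]] / (1 - beta2^t)
    store$val[[name]] <- store$val[[name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(store)
}

# ---- LSTM cell usable on tape or raw numerics ----
# params: <prefix>_W (4H x (Din+H)), <prefix>_b (4H); forget-gate slice gets
# a +1 bias at init time (see lstm_param_shapes / lstm_init_bias)
lstm_cell <- function(tape, store, prefix, x, h, c, H) {
  W <- ad_param(tape, store, paste0(prefix, "_W"))
  b <- ad_param(tape, store, paste0(prefix, "_b"))
  hc <- ad_lstm_cell_fused(tape, W, b, x, h, c, H)
  list(h = ad_slice(tape, hc, 1:H),
       c = ad_slice(tape, hc, (H + 1):(2 * H)))
}

lstm_param_shapes <- function(prefix, Din, H) {
  stats::setNames(list(c(4L * H, Din + H), 4L * H),
                  paste0(prefix, c("_W", "_b")))
}

lstm_init_forget_bias <- function(store, prefix, H, value = 1) {
  b <- store$val[[paste0(prefix, "_b")]]
  b[(H + 1):(2 * H)] <- b[(H + 1):(2 * H)] + value
  store$val[[paste0(prefix, "_b")]] <- b
  invisible(store)
}

# run a (possibly multi-layer) LSTM stack one step; states is a list of
# per-layer list(h, c)
lstm_stack_step <- function(tape, store, prefix, x, states, H) {
  out <- vector("list", length(states))
  inp <- x
  for (l in seq_along(states)) {
    st <- lstm_cell(tape, store, paste0(prefix, l), inp, states[[l]]$h,
                    states[[l]]$c, H)
    out[[l]] <- st
    inp <- st$h
  }
  list(states = out, h = inp)
}

lstm_zero_states <- function(layers, H) {
  replicate(layers, list(h = numeric(H), c = numeric(H)), simplify = FALSE)
}
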