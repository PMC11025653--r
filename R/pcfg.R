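#' Probabilistic context-free grammar specification
#'
#' Defines and validates a proper PCFG. Rule probabilities must sum to 1 per
#' left-hand side (tolerance 1e-12), every right-hand-side symbol must be a
#' declared nonterminal or terminal, and every symbol must be reachable from
#' the start symbol and productive (able to derive a terminal string).
#'
#' @param nonterminals Character vector of nonterminal labels.
#' @param terminals Character vector of terminal tokens.
#' @param rules List of rules, each `list(lhs =, rhs = character vector, prob =)`.
#' @param start Start symbol (must be a nonterminal).
#' @return An object of class `pcfg_spec`.
#' @examples
#' g <- pcfg_spec("S", c("a", "b"),
#'                list(list(lhs = "S", rhs = "a", prob = 0.3),
#'                     list(lhs = "S", rhs = "b", prob = 0.7)), "S")
#' @export
pcfg_spec <- function(nonterminals, terminals, rules, start) {
  stopifnot(is.character(nonterminals), is.character(terminals),
            is.list(rules), start %in% nonterminals)
  if (length(intersect(nonterminals, terminals)) > 0L)
    stop("symbols cannot be both nonterminal and terminal: ",
         paste(intersect(nonterminals, terminals), collapse = ", "))
  lhs <- vapply(rules, `[[`, character(1), "lhs")
  prob <- vapply(rules, `[[`, numeric(1), "prob")
  if (any(!lhs %in% nonterminals))
    stop("rule lhs not a declared nonterminal: ",
         paste(unique(lhs[!lhs %in% nonterminals]), collapse = ", "))
  if (any(prob < 0)) stop("negative rule probability")
  for (r in rules) {
    bad <- setdiff(r$rhs, c(nonterminals, terminals))
    if (length(bad) > 0L)
      stop("undeclared rhs symbol(s): ", paste(bad, collapse = ", "))
    if (length(r$rhs) == 0L) stop("empty rhs not allowed")
  }
  sums <- tapply(prob, lhs, sum)
  if (any(abs(sums - 1) > 1e-12))
    stop("rule probabilities do not sum to 1 for lhs: ",
         paste(names(sums)[abs(sums - 1) > 1e-12], collapse = ", "))
  if (!all(nonterminals %in% lhs))
    stop("nonterminal(s) without rules (unproductive): ",
         paste(setdiff(nonterminals, lhs), collapse = ", "))
  # productivity: iterate "can derive a terminal string"
  productive <- character(0)
  repeat {
    new <- unique(lhs[vapply(rules, function(r)
      all(r$rhs %in% c(terminals, productive)), logical(1))])
    if (setequal(new, productive)) break
    productive <- new
  }
  if (!all(nonterminals %in% productive))
    stop("unproductive nonterminal(s): ",
         paste(setdiff(nonterminals, productive), collapse = ", "))
  # reachability from start
  reach <- start
  repeat {
    new <- unique(c(reach, unlist(lapply(rules[lhs %in% reach], `[[`, "rhs"))))
    new <- intersect(new, nonterminals)
    if (setequal(new, reach)) break
    reach <- new
  }
  if (!all(nonterminals %in% reach))
    stop("unreachable nonterminal(s): ",
         paste(setdiff(nonterminals, reach), collapse = ", "))
  structure(list(nonterminals = nonterminals, terminals = terminals,
                 rules = rules, start = start),
            class = "pcfg_spec")
}

rules_for <- function(grammar, sym) {
  grammar$rules[vapply(grammar$rules, function(r) r$lhs == sym, logical(1))]
}

#' Sample a treebank from a PCFG
#'
#' Ancestral sampling with rejection on yield length: each tree is redrawn
#' (up to `max_attempts` times) until its terminal yield has length
#' `<= max_len`. Fully deterministic given `seed`.
#'
#' @param grammar A `pcfg_spec`.
#' @param n Number of trees (>= 1).
#' @param max_len Maximum terminal yield length.
#' @param seed Integer seed.
#' @param max_attempts Rejection budget per tree (default 100).
#' @return List of `syntax_tree` of length `n`.
#' @export
sample_treebank <- function(grammar, n, max_len = 20L, seed = 1L,
                            max_attempts = 100L) {
  stopifnot(inherits(grammar, "pcfg_spec"), n >= 1L)
  rng <- local_rng(seed)
  expand <- function(sym, depth) {
    if (sym %in% grammar$terminals) return(sym)
    if (depth > 200L) stop("sampling-budget error: derivation depth exceeded")
    rs <- rules_for(grammar, sym)
    p <- vapply(rs, `[[`, numeric(1), "prob")
    r <- rs[[sample.int(length(rs), 1L, prob = p)]]
    syntax_tree(sym, lapply(r$rhs, expand, depth = depth + 1L))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      t <- tryCatch(expand(grammar$start, 0L), error = function(e) NULL)
      if (!is.null(t) && length(tree_yield(t)) <= max_len) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(
        "sampling-budget error: no tree with yield <= %d in %d attempts",
        max_len, max_attempts))
    out[[i]] <- t
  }
  out
}

#' Exhaustively enumerate all trees of a PCFG up to a yield length
#'
#' Returns every complete derivation whose terminal yield has length
#' `<= max_len`, with its exact probability (product of rule probabilities).
#' Used as the brute-force oracle for sampler frequencies and beam-search
#' marginals. Probabilities over the enumerated set sum to at most 1.
#'
#' @param grammar A `pcfg_spec`.
#' @param max_len Maximum yield length.
#' @param node_budget Abort (budget error) after this many partial
#'   expansions (default 1e6).
#' @return List of `list(tree =, prob =)`.
#' @export
enumerate_trees <- function(grammar, max_len, node_budget = 1e6) {
  stopifnot(inherits(grammar, "pcfg_spec"))
  count <- 0L
  # derive(sym, budget): list of (tree, prob, len) with len <= budget
  derive <- function(sym, budget) {
    if (budget <= 0L) return(list())
    count <<- count + 1L
    if (count > node_budget)
      stop("enumeration budget error: node budget exceeded")
    if (sym %in% grammar$terminals)
      return(list(list(tree = sym, prob = 1, len = 1L)))
    out <- list()
    for (r in rules_for(grammar, sym)) {
      partial <- list(list(children = list(), prob = r$prob, len = 0L))
      for (s in r$rhs) {
        nxt <- list()
        for (p in partial) {
          for (d in derive(s, budget - p$len)) {
            nxt[[length(nxt) + 1L]] <- list(
              children = c(p$children, list(d$tree)),
              prob = p$prob * d$prob,
              len = p$len + d$len)
          }
        }
        partial <- nxt
        if (length(partial) == 0L) break
      }
      for (p in partial)
        out[[length(out) + 1L]] <- list(
          tree = syntax_tree(sym, p$children), prob = p$prob, len = p$len)
    }
    out
  }
  res <- derive(grammar$start, as.integer(max_len))
  lapply(res, function(x) list(tree = x$tree, prob = x$prob))
}

#' Built-in toy grammars
#'
#' * `"headfinal"`: a small head-final grammar (postpositional noun phrases,
#'   verb-final clauses, left-branching relative clauses) emulating the
#'   derivation geometry of a head-final/left-branching language such as
#'   Japanese, where top-down and left-corner strategies differ most.
#' * `"ambiguous"`: a 2-nonterminal grammar under which the string `"a b"`
#'   has exactly two parses; used for exhaustive beam-search oracles.
#' * `"chain"`: deterministic single-derivation grammar `(S (N w))`.
#'
#' @param kind One of `"headfinal"`, `"ambiguous"`, `"chain"`.
#' @return A `pcfg_spec`.
#' @export
toy_grammar <- function(kind = c("headfinal", "ambiguous", "chain")) {
  kind <- match.arg(kind)
  if (kind == "chain") {
    return(pcfg_spec(c("S", "N"), "w",
                     list(list(lhs = "S", rhs = "N", prob = 1),
                          list(lhs = "N", rhs = "w", prob = 1)),
                     start = "S"))
  }
  if (kind == "ambiguous") {
    return(pcfg_spec(
      nonterminals = c("S", "X"),
      terminals = c("a", "b"),
      rules = list(
        list(lhs = "S", rhs = c("X", "b"), prob = 0.5),
        list(lhs = "S", rhs = c("a", "b"), prob = 0.5),
        list(lhs = "X", rhs = "a", prob = 0.6),
        list(lhs = "X", rhs = "b", prob = 0.4)),
      start = "S"))
  }
  # head-final fixture: NP -> N P, relative clauses branch left, verb final
  nouns <- c("inu", "neko", "hon", "sensei", "kodomo", "tori")
  parts <- c("ga", "wo", "ni")
  verbs <- c("mita", "yonda", "oikaketa", "aruita")
  rules <- list(
    list(lhs = "S", rhs = c("NP", "VP"), prob = 1),
    list(lhs = "NP", rhs = c("N", "P"), prob = 0.75),
    list(lhs = "NP", rhs = c("S", "N", "P"), prob = 0.25),
    list(lhs = "VP", rhs = c("V"), prob = 0.55),
    list(lhs = "VP", rhs = c("NP", "V"), prob = 0.45))
  for (w in nouns) rules[[length(rules) + 1L]] <-
    list(lhs = "N", rhs = w, prob = 1 / length(nouns))
  for (w in parts) rules[[length(rules) + 1L]] <-
    list(lhs = "P", rhs = w, prob = 1 / length(parts))
  for (w in verbs) rules[[length(rules) + 1L]] <-
    list(lhs = "V", rhs = w, prob = 1 / length(verbs))
  pcfg_spec(c("S", "NP", "VP", "N", "P", "V"),
            c(nouns, parts, verbs), rules, "S")
}

#' Read/write a PCFG as JSON
#' @param grammar A `pcfg_spec`.
#' @param path File path.
#' @export
write_pcfg_json <- function(grammar, path) {
  jsonlite::write_json(unclass(grammar), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pcfg_json
#' @export
read_pcfg_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rules <- lapply(x$rules, function(r)
    list(lhs = r$lhs, rhs = unlist(r$rhs), prob = r$prob))
  pcfg_spec(unlist(x$nonterminals), unlist(x$terminals), rules, x$start)
}
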