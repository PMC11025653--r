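#' Derivation actions and action sequences
#'
#' A generative derivation is a sequence of three action types:
#' `GEN(token)` generates a terminal, `NT(label)` opens a nonterminal, and
#' `REDUCE` closes the innermost open nonterminal. The two strategies differ
#' only in *when* a nonterminal is announced: top-down opens it before any of
#' its children; left-corner opens it immediately after its first child (the
#' left corner) has been completed, attaching that child on the spot.
#'
#' @param type One of `"GEN"`, `"NT"`, `"REDUCE"`.
#' @param arg Token for `GEN`, label for `NT`, ignored for `REDUCE`.
#' @return `action()` returns a list with `type` and `arg`.
#' @name actions
NULL

#' @rdname actions
#' @export
action <- function(type, arg = NA_character_) {
  stopifnot(type %in% c("GEN", "NT", "REDUCE"))
  list(type = type, arg = arg)
}

#' @param strategy `"top_down"` or `"left_corner"`.
#' @param actions List of actions from [action()].
#' @rdname actions
#' @export
action_sequence <- function(strategy, actions) {
  strategy <- match.arg(strategy, c("top_down", "left_corner"))
  structure(list(strategy = strategy, actions = actions),
            class = "action_sequence")
}

#' @export
format.action_sequence <- function(x, ...) {
  fmt1 <- function(a) switch(a$type,
    GEN = paste0("GEN(", a$arg, ")"),
    NT = paste0("NT(", a$arg, ")"),
    REDUCE = "REDUCE")
  paste0("[", x$strategy, "] ",
         paste(vapply(x$actions, fmt1, character(1)), collapse = " "))
}

#' @export
print.action_sequence <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Top-down derivation oracle
#'
#' Converts a tree to its unique top-down action sequence: `NT(label)`, then
#' each child's actions in order, then `REDUCE`; `GEN` at terminals.
#'
#' @param tree A `syntax_tree`.
#' @return An `action_sequence` with strategy `"top_down"`.
#' @export
topdown_oracle <- function(tree) {
  rec <- function(t) {
    if (is_terminal(t)) return(list(action("GEN", t)))
    c(list(action("NT", t$label)),
      unlist(lapply(t$children, rec), recursive = FALSE),
      list(action("REDUCE")))
  }
  action_sequence("top_down", rec(tree))
}

#' Left-corner derivation oracle
#'
#' Converts a tree to its unique left-corner action sequence: the first
#' child's actions, then `NT(label)` (which attaches the completed first
#' child as the left corner), then the remaining children's actions, then
#' `REDUCE`.
#'
#' @param tree A `syntax_tree`.
#' @return An `action_sequence` with strategy `"left_corner"`.
#' @export
leftcorner_oracle <- function(tree) {
  rec <- function(t) {
    if (is_terminal(t)) return(list(action("GEN", t)))
    rest <- if (length(t$children) > 1L)
      unlist(lapply(t$children[-1L], rec), recursive = FALSE) else list()
    c(rec(t$children[[1L]]),
      list(action("NT", t$label)),
      rest,
      list(action("REDUCE")))
  }
  action_sequence("left_corner", rec(tree))
}

#' Oracle for a named strategy
#' @inheritParams topdown_oracle
#' @param strategy `"top_down"` or `"left_corner"`.
#' @export
derivation_oracle <- function(tree, strategy) {
  strategy <- match.arg(strategy, c("top_down", "left_corner"))
  if (strategy == "top_down") topdown_oracle(tree) else leftcorner_oracle(tree)
}

#' Replay an action sequence back into a tree
#'
#' Inverse of the oracles: `replay_actions(topdown_oracle(t))` and
#' `replay_actions(leftcorner_oracle(t))` both return `t`. The replay stack
#' holds completed items and open-constituent markers; under the left-corner
#' strategy `NT` pops the completed item on top of the stack and stores it as
#' the new constituent's left corner.
#'
#' @param seq An `action_sequence`.
#' @return A `syntax_tree`.
#' @export
replay_actions <- function(seq) {
  stopifnot(inherits(seq, "action_sequence"))
  lc <- seq$strategy == "left_corner"
  stack <- list()  # elements: terminals, syntax_tree, or list(open=label, corner=list)
  is_open <- function(e) is.list(e) && !inherits(e, "syntax_tree") &&
    !is.null(e$open)
  bad <- function(i, msg)
    stop(sprintf("malformed derivation at index %d: %s", i, msg), call. = FALSE)
  for (i in seq_along(seq$actions)) {
    a <- seq$actions[[i]]
    if (a$type == "GEN") {
      stack[[length(stack) + 1L]] <- a$arg
    } else if (a$type == "NT") {
      if (lc) {
        n <- length(stack)
        if (n == 0L || is_open(stack[[n]]))
          bad(i, "left-corner NT requires a completed item on top of the stack")
        corner <- stack[[n]]
        stack[[n]] <- list(open = a$arg, corner = list(corner))
      } else {
        stack[[length(stack) + 1L]] <- list(open = a$arg, corner = list())
      }
    } else { # REDUCE
      n <- length(stack)
      j <- n
      while (j >= 1L && !is_open(stack[[j]])) j <- j - 1L
      if (j == 0L) bad(i, "REDUCE with no open constituent")
      marker <- stack[[j]]
      kids <- c(marker$corner, if (j < n) stack[(j + 1L):n] else list())
      if (length(kids) == 0L) bad(i, "REDUCE would close an empty constituent")
      stack <- stack[seq_len(j - 1L)]
      stack[[j]] <- syntax_tree(marker$open, kids)
    }
  }
  if (length(stack) != 1L || is_open(stack[[1L]]))
    bad(length(seq$actions),
        sprintf("derivation leaves %d item(s)/open constituent(s) on the stack",
                length(stack)))
  if (is_terminal(stack[[1L]]))
    bad(length(seq$actions), "derivation yields a bare terminal, not a tree")
  stack[[1L]]
}

#' Tabulate action counts of a sequence
#' @param seq An `action_sequence`.
#' @return Named integer vector over `GEN`, `NT`, `REDUCE`.
#' @export
action_counts <- function(seq) {
  tp <- vapply(seq$actions, `[[`, character(1), "type")
  c(GEN = sum(tp == "GEN"), NT = sum(tp == "NT"), REDUCE = sum(tp == "REDUCE"))
}

#' Serialize / read an action sequence as TSV
#'
#' Columns: `index`, `type`, `arg` (empty for REDUCE).
#' @param seq An `action_sequence`.
#' @param path File path.
#' @export
write_actions_tsv <- function(seq, path) {
  df <- data.frame(
    index = seq_along(seq$actions),
    type = vapply(seq$actions, `[[`, character(1), "type"),
    arg = vapply(seq$actions, function(a)
      if (a$type == "REDUCE") "" else a$arg, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param strategy Strategy tag to attach on read.
#' @rdname write_actions_tsv
#' @export
read_actions_tsv <- function(path, strategy) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character"))
  acts <- lapply(seq_len(nrow(df)), function(i)
    action(df$type[i], if (df$type[i] == "REDUCE") NA_character_ else df$arg[i]))
  action_sequence(strategy, acts)
}
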