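#' Syntax trees
#'
#' A syntax tree is a labeled ordered constituency tree: an internal node is a
#' list with a `label` (nonterminal symbol) and `children` (a list whose
#' elements are either further trees or bare character terminals). Terminals
#' occur only at leaves; every internal node has at least one child.
#'
#' @param label Nonterminal label (single character string).
#' @param children List of child trees and/or terminal tokens (character).
#' @return An object of class `syntax_tree`.
#' @examples
#' t <- syntax_tree("S", list(syntax_tree("N", list("dogs")), "bark"))
#' write_bracketed(t)
#' @export
syntax_tree <- function(label, children) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.list(children) || length(children) == 0L)
    stop("internal node must have at least one child")
  structure(list(label = label, children = children), class = "syntax_tree")
}

#' @export
print.syntax_tree <- function(x, ...) {
  cat(write_bracketed(x), "\n")
  invisible(x)
}

is_terminal <- function(x) is.character(x)

#' Count terminals and internal nodes of a tree
#'
#' @param tree A `syntax_tree`.
#' @return Named integer vector with elements `terminals` and `internal`.
#' @export
tree_counts <- function(tree) {
  if (is_terminal(tree)) return(c(terminals = 1L, internal = 0L))
  acc <- c(terminals = 0L, internal = 1L)
  for (ch in tree$children) acc <- acc + tree_counts(ch)
  acc
}

#' Terminal yield of a tree
#'
#' @param tree A `syntax_tree` (or a bare terminal).
#' @return Character vector of terminals in left-to-right order.
#' @export
tree_yield <- function(tree) {
  if (is_terminal(tree)) return(tree)
  unlist(lapply(tree$children, tree_yield), use.names = FALSE)
}

#' Serialize a tree to Penn-style bracketed text
#'
#' @param tree A `syntax_tree`.
#' @return A single character string such as `"(S (N dogs) bark)"`.
#' @seealso [read_bracketed()]
#' @export
write_bracketed <- function(tree) {
  if (is_terminal(tree)) return(tree)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, write_bracketed, character(1)),
               collapse = " "),
         ")")
}

#' Parse Penn-style bracketed text into a tree
#'
#' Accepts a single balanced s-expression, e.g.
#' `"(S (NP (N dogs)) (VP (V bark)))"`. `write_bracketed(read_bracketed(x))`
#' is the identity on whitespace-normalized input.
#'
#' @param text Character scalar holding one bracketed tree.
#' @return A `syntax_tree`.
#' @export
read_bracketed <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # tokenize: parens and maximal runs of non-space non-paren characters
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) stop("parse error: empty input")
  toks <- regmatches(text, list(m))[[1]]
  pos <- as.integer(m)
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else NULL
  take <- function() { i <<- i + 1L; toks[i] }
  err <- function(msg, at = if (i < length(toks)) pos[i + 1L] else nchar(text) + 1L)
    stop(sprintf("parse error at position %d: %s", at, msg), call. = FALSE)
  parse_node <- function() {
    tk <- take()
    if (tk != "(") err("expected '('", pos[i])
    if (is.null(peek())) err("unexpected end-of-input, expected label")
    lab <- take()
    if (lab %in% c("(", ")")) err("expected constituent label", pos[i])
    children <- list()
    repeat {
      nx <- peek()
      if (is.null(nx)) err("unexpected end-of-input, unbalanced parentheses")
      if (nx == ")") { take(); break }
      if (nx == "(") children[[length(children) + 1L]] <- parse_node()
      else children[[length(children) + 1L]] <- take()
    }
    if (length(children) == 0L) err("empty constituent", pos[i])
    syntax_tree(lab, children)
  }
  tree <- parse_node()
  if (!is.null(peek())) err("trailing content after tree")
  tree
}

#' Read / write one-tree-per-line treebank files
#'
#' @param path File path.
#' @return `read_treebank()` returns a list of `syntax_tree`;
#'   `write_treebank()` returns `path` invisibly.
#' @export
read_treebank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_bracketed)
}

#' @param trees List of `syntax_tree`.
#' @rdname read_treebank
#' @export
write_treebank <- function(trees, path) {
  writeLines(vapply(trees, write_bracketed, character(1)), path)
  invisible(path)
}
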