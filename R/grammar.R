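# Context-free grammar of protein topology (Taylor fold strings).
#
# A topology string is an ordered list of secondary-structure elements,
# each written <orientation><layer><position>: an orientation sign relative
# to the first strand of the sheet, a layer letter A-D, and a signed
# position within the layer ('+0' allowed, '-0' not). The grammar
# G = {N, Sigma, P, S} has five nonterminals and 22 productions:
#
#   idx  production
#    0   <topology>    -> <element> <topology>
#    1   <topology>    -> <element>
#    2   <element>     -> <orientation> <layer> <position>
#    3   <orientation> -> '+'
#    4   <orientation> -> '-'
#    5-8 <layer>       -> 'A' | 'B' | 'C' | 'D'
#   9-21 <position>    -> '+0' | '+1' ... '+6' | '-1' ... '-6'
#
# Rule indices are 0-based and frozen in the order above; the canonical
# leftmost derivation of an n-element topology applies exactly 5 rules per
# element, so derivations of up to 11 elements fit the 55-rule encoding.

.POSITIONS <- c(paste0("+", 0:6), paste0("-", 1:6))
.LAYERS <- c("A", "B", "C", "D")
.N_RULES <- 22L
.MAX_RULES <- 55L
.RULE_BLOCK <- 23L   # 22 rules + padding rule

#' The topology grammar
#'
#' Returns the fixed context-free grammar describing protein topology
#' strings: 5 nonterminals, the terminal set, and 22 productions in their
#' canonical (0-based) index order. The grammar object is informational;
#' parsing and derivation use the frozen rule order internally.
#'
#' @return An object of class \code{"topology_grammar"}: a list with
#'   \code{nonterminals}, \code{terminals}, \code{productions} (a
#'   data.frame with columns \code{index}, \code{lhs}, \code{rhs}) and
#'   \code{start}.
#' @examples
#' topology_grammar()
#' @export
topology_grammar <- function() {
  prods <- data.frame(
    index = 0:21,
    lhs = c("<topology>", "<topology>", "<element>",
            rep("<orientation>", 2), rep("<layer>", 4),
            rep("<position>", 13)),
    rhs = c("<element> <topology>", "<element>",
            "<orientation> <layer> <position>",
            "+", "-", .LAYERS, .POSITIONS),
    stringsAsFactors = FALSE
  )
  structure(
    list(nonterminals = c("<topology>", "<element>", "<orientation>",
                          "<layer>", "<position>"),
         terminals = c("+", "-", .LAYERS, .POSITIONS),
         productions = prods,
         start = "<topology>"),
    class = "topology_grammar")
}

#' @export
print.topology_grammar <- function(x, ...) {
  cat("Context-free grammar of protein topology\n")
  cat("  start symbol:", x$start, "\n")
  cat("  nonterminals:", paste(x$nonterminals, collapse = " "), "\n")
  cat("  productions (", nrow(x$productions), "):\n", sep = "")
  with(x$productions,
       cat(sprintf("   [%2d] %-14s -> %s\n", index, lhs, rhs), sep = ""))
  invisible(x)
}

#' @keywords internal
.normalise_topology_chars <- function(s) {
  # accept Unicode minus / hyphen variants, emit ASCII; drop whitespace
  s <- gsub("[−‐‑–—]", "-", s)
  gsub("[[:space:]]+", "", s)
}

#' Parse a topology string
#'
#' Tokenizes a fold string such as \code{"-C+0+B+0-B-1+C-1-B-2"} into its
#' secondary-structure elements. Whitespace is ignored and Unicode minus
#' signs are accepted, so strings copied from typeset text parse directly.
#'
#' @param s Character scalar topology string.
#' @return An object of class \code{"topology"}: a data.frame with one row
#'   per element and columns \code{orientation} (\code{"+"}/\code{"-"}),
#'   \code{layer} (\code{"A"}-\code{"D"}) and \code{position} (a signed
#'   token, \code{"+0"} through \code{"-6"}).
#' @examples
#' t <- parse_topology("-C + 0 + B + 0-B-1 + C-1-B-2")
#' nrow(t)              # 5 elements
#' unparse_topology(t)
#' @export
parse_topology <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  s <- .normalise_topology_chars(s)
  if (!nzchar(s)) stop("empty topology string", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  ori <- layer <- pos <- character(0)
  i <- 1L
  while (i <= n) {
    o <- chars[i]
    if (!o %in% c("+", "-"))
      stop("expected orientation sign at position ", i, ", got '", o, "'",
           call. = FALSE)
    if (i + 3L > n)
      stop("trailing partial element at position ", i, " of '", s, "'",
           call. = FALSE)
    l <- chars[i + 1L]; ps <- chars[i + 2L]; pd <- chars[i + 3L]
    if (!l %in% .LAYERS)
      stop("unknown layer letter '", l, "' at position ", i + 1L, call. = FALSE)
    tok <- paste0(ps, pd)
    if (!tok %in% .POSITIONS)
      stop("invalid position token '", tok, "' at position ", i + 2L,
           " (positions run +0..+6 and -1..-6)", call. = FALSE)
    ori <- c(ori, o); layer <- c(layer, l); pos <- c(pos, tok)
    i <- i + 4L
  }
  structure(
    data.frame(orientation = ori, layer = layer, position = pos,
               stringsAsFactors = FALSE),
    class = c("topology", "data.frame"))
}

#' Render a topology back to its canonical string
#'
#' Inverse of [parse_topology()]: emits the compact ASCII form with no
#' whitespace, so \code{parse_topology(unparse_topology(t))} is the
#' identity.
#'
#' @param t A \code{"topology"} object (or a data.frame with the same
#'   columns).
#' @return Character scalar.
#' @export
unparse_topology <- function(t) {
  if (nrow(t) == 0L) stop("topology must have at least one element", call. = FALSE)
  paste0(t$orientation, t$layer, t$position, collapse = "")
}

#' @export
format.topology <- function(x, ...) unparse_topology(x)

#' @export
print.topology <- function(x, ...) {
  cat("Topology with", nrow(x), "elements:", unparse_topology(x), "\n")
  invisible(x)
}

#' @export
as.character.topology <- function(x, ...) unparse_topology(x)

#' Canonical rule derivation of a topology
#'
#' Computes the leftmost derivation of a topology under the fixed grammar:
#' for each element in order, the recursive topology rule (or, for the last
#' element, the terminating rule), then the element rule, orientation rule,
#' layer rule and position rule — exactly 5 rule applications per element.
#' Topologies with more than 11 elements would need more than the 55 rule
#' slots the one-hot encoding provides and are rejected.
#'
#' @param t A \code{"topology"} object.
#' @return Integer vector of 0-based rule indices in \code{[0, 21]}, of
#'   length \code{5 * nrow(t)}.
#' @seealso [replay_rules()], [encode_rules()]
#' @examples
#' derive_rules(parse_topology("+B+0"))  # length 5
#' @export
derive_rules <- function(t) {
  n <- nrow(t)
  if (n < 1L) stop("topology must have at least one element", call. = FALSE)
  if (5L * n > .MAX_RULES)
    stop("topology has ", n, " elements; derivations longer than ",
         .MAX_RULES, " rules (11 elements) are not encodable", call. = FALSE)
  per_elem <- function(i) {
    c(if (i < n) 0L else 1L,                       # topology rule
      2L,                                          # element rule
      if (t$orientation[i] == "+") 3L else 4L,     # orientation
      4L + match(t$layer[i], .LAYERS),             # layer: 5..8
      8L + match(t$position[i], .POSITIONS))       # position: 9..21
  }
  unlist(lapply(seq_len(n), per_elem))
}

#' Replay a rule sequence into the topology it derives
#'
#' Validates that \code{rules} is a canonical leftmost derivation (the
#' exact 5-rules-per-element pattern produced by [derive_rules()]) and
#' reconstructs the topology.
#'
#' @param rules Integer vector of 0-based rule indices.
#' @return A \code{"topology"} object.
#' @export
replay_rules <- function(rules) {
  rules <- as.integer(rules)
  if (length(rules) == 0L || length(rules) %% 5L != 0L)
    stop("rule sequence length must be a positive multiple of 5", call. = FALSE)
  if (any(rules < 0L | rules > 21L))
    stop("rule indices must lie in [0, 21]", call. = FALSE)
  n <- length(rules) %/% 5L
  ori <- layer <- pos <- character(n)
  for (i in seq_len(n)) {
    r <- rules[(i - 1L) * 5L + 1:5]
    top_rule <- if (i < n) 0L else 1L
    if (r[1L] != top_rule)
      stop("element ", i, ": expected topology rule ", top_rule,
           ", got ", r[1L], call. = FALSE)
    if (r[2L] != 2L)
      stop("element ", i, ": expected element rule 2, got ", r[2L],
           call. = FALSE)
    if (!r[3L] %in% 3:4)
      stop("element ", i, ": invalid orientation rule ", r[3L], call. = FALSE)
    if (!r[4L] %in% 5:8)
      stop("element ", i, ": invalid layer rule ", r[4L], call. = FALSE)
    if (!r[5L] %in% 9:21)
      stop("element ", i, ": invalid position rule ", r[5L], call. = FALSE)
    ori[i] <- if (r[3L] == 3L) "+" else "-"
    layer[i] <- .LAYERS[r[4L] - 4L]
    pos[i] <- .POSITIONS[r[5L] - 8L]
  }
  structure(
    data.frame(orientation = ori, layer = layer, position = pos,
               stringsAsFactors = FALSE),
    class = c("topology", "data.frame"))
}

#' One-hot encode a rule derivation
#'
#' Encodes a rule sequence as the flat conditioning tensor used by the
#' structure-task model: 55 blocks of 23 entries (the 22 grammar rules plus
#' a padding rule), flattened to a length-1265 binary vector. Blocks past
#' the end of the derivation one-hot the padding rule.
#'
#' @param rules Integer vector of 0-based rule indices, length \code{<= 55}.
#' @return Numeric 0/1 vector of length 1265 whose entries sum to 55.
#' @export
encode_rules <- function(rules) {
  rules <- as.integer(rules)
  if (length(rules) > .MAX_RULES)
    stop("rule sequence longer than ", .MAX_RULES, " rules", call. = FALSE)
  if (any(rules < 0L | rules > 21L))
    stop("rule indices must lie in [0, 21]", call. = FALSE)
  slot <- c(rules, rep(.N_RULES, .MAX_RULES - length(rules)))  # padding = 22
  out <- numeric(.MAX_RULES * .RULE_BLOCK)
  out[(seq_len(.MAX_RULES) - 1L) * .RULE_BLOCK + slot + 1L] <- 1
  out
}

#' Decode a rule-encoding tensor back to a rule sequence
#'
#' Per-block argmax; decoding stops at the first padding-rule block and the
#' result is validated as a replayable canonical derivation.
#'
#' @param x Numeric vector of length 1265.
#' @return Integer vector of 0-based rule indices.
#' @export
decode_rules <- function(x) {
  if (length(x) != .MAX_RULES * .RULE_BLOCK)
    stop("encoding has length ", length(x), ", expected ",
         .MAX_RULES * .RULE_BLOCK, call. = FALSE)
  m <- matrix(x, nrow = .RULE_BLOCK)
  slot <- apply(m, 2L, which.max) - 1L
  pad_at <- which(slot == .N_RULES)
  rules <- if (length(pad_at)) slot[seq_len(min(pad_at) - 1L)] else slot
  replay_rules(rules)        # validates derivation structure
  as.integer(rules)
}

#' Sample a random topology
#'
#' Draws a random derivation from the grammar: at each expansion of the
#' topology nonterminal the recursive and terminating rules are chosen
#' uniformly (the terminating rule is forced once \code{max_elements} is
#' reached), and orientation, layer and position rules are chosen uniformly
#' among their alternatives.
#'
#' @param max_elements Maximum number of elements, in \code{[1, 11]}.
#' @param seed Optional integer seed; if supplied the draw is a pure
#'   function of it (the caller's RNG state is left untouched).
#' @return A \code{"topology"} object.
#' @export
sample_topology <- function(max_elements = 11L, seed = NULL) {
  stopifnot(max_elements >= 1L, max_elements <= 11L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- 1L
  while (n < max_elements && sample(c(TRUE, FALSE), 1L)) n <- n + 1L
  structure(
    data.frame(
      orientation = sample(c("+", "-"), n, replace = TRUE),
      layer = sample(.LAYERS, n, replace = TRUE),
      position = sample(.POSITIONS, n, replace = TRUE),
      stringsAsFactors = FALSE),
    class = c("topology", "data.frame"))
}
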