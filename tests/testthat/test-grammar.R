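# Independent oracle: enumerate every leftmost derivation of a target
# string by recursive expansion of the grammar, pruning on string prefix.
# Returns a list of rule-index sequences (0-based, in the canonical rule
# order) that derive exactly the target.
enumerate_derivations <- function(target, max_rules = 60L) {
  positions <- c(paste0("+", 0:6), paste0("-", 1:6))
  prods <- list(
    list(lhs = "T", rhs = c("E", "T")), list(lhs = "T", rhs = "E"),
    list(lhs = "E", rhs = c("O", "L", "P")),
    list(lhs = "O", rhs = "+"), list(lhs = "O", rhs = "-"))
  for (l in c("A", "B", "C", "D")) prods <- c(prods, list(list(lhs = "L", rhs = l)))
  for (p in positions) prods <- c(prods, list(list(lhs = "P", rhs = p)))
  is_nt <- function(s) s %in% c("T", "E", "O", "L", "P")
  out <- list()
  recurse <- function(form, rules) {
    if (length(rules) > max_rules) return()
    nt <- which(vapply(form, is_nt, logical(1)))
    if (length(nt) == 0L) {
      if (identical(paste(form, collapse = ""), target))
        out[[length(out) + 1L]] <<- rules
      return()
    }
    i <- nt[1L]
    prefix <- paste(form[seq_len(i - 1L)], collapse = "")
    if (!startsWith(target, prefix)) return()
    for (k in seq_along(prods)) {
      if (prods[[k]]$lhs != form[[i]]) next
      nf <- append(form[-i], as.list(prods[[k]]$rhs), after = i - 1L)
      recurse(nf, c(rules, k - 1L))
    }
  }
  recurse(list("T"), integer(0))
  out
}

test_that("the grammar has the canonical production inventory", {
  g <- topology_grammar()
  expect_length(g$nonterminals, 5L)
  expect_equal(nrow(g$productions), 22L)
  counts <- table(g$productions$lhs)
  expect_equal(unname(counts[c("<topology>", "<element>", "<orientation>",
                               "<layer>", "<position>")]),
               c(2L, 1L, 2L, 4L, 13L), ignore_attr = TRUE)
  expect_setequal(g$terminals,
                  c("+", "-", "A", "B", "C", "D",
                    paste0("+", 0:6), paste0("-", 1:6)))
})

test_that("reference topology strings parse to the expected elements", {
  # an alpha-beta-alpha layer fold of a small bacterial protein
  t1 <- parse_topology("-C + 0 + B + 0-B-1 + C-1-B-2")
  expect_equal(nrow(t1), 5L)
  expect_identical(unlist(t1[1L, ], use.names = FALSE), c("-", "C", "+0"))
  expect_identical(unparse_topology(t1), "-C+0+B+0-B-1+C-1-B-2")
  # minimal one-element string
  t2 <- parse_topology("+B+0")
  expect_equal(nrow(t2), 1L)
  expect_identical(unlist(t2[1L, ], use.names = FALSE), c("+", "B", "+0"))
  # the two-layer sandwich (three strands, one helix)
  t3 <- parse_topology("+B + 0−C + 0 + B + 2−B + 1")
  expect_equal(nrow(t3), 4L)
  # a designed novel-topology string parses and differs from the first fold
  t4 <- parse_topology("−C+0+B+0−B−2+C−1−B−1")
  expect_equal(nrow(t4), 5L)
  expect_false(identical(unparse_topology(t4), unparse_topology(t1)))
})

test_that("malformed topology strings are rejected with positions", {
  expect_error(parse_topology("+E+0"), "layer")
  expect_error(parse_topology("+B-0"), "position")
  expect_error(parse_topology("+B+7"), "position")
  expect_error(parse_topology("+B+0-C"), "partial")
  expect_error(parse_topology("B+0"), "orientation")
  expect_error(parse_topology(""), "empty")
  expect_error(unparse_topology(parse_topology("+B+0")[0, ]), "at least one")
})

test_that("canonical derivation matches exhaustive enumeration", {
  # one-element strings admit exactly one leftmost derivation, of length 5
  for (s in c("+B+0", "-D-6", "+A+6")) {
    oracle <- enumerate_derivations(s)
    expect_length(oracle, 1L)
    expect_length(oracle[[1L]], 5L)
    expect_identical(derive_rules(parse_topology(s)), as.integer(oracle[[1L]]))
  }
  # a two-element string: still a unique leftmost derivation
  oracle2 <- enumerate_derivations("+B+0-C-1")
  expect_length(oracle2, 1L)
  expect_identical(derive_rules(parse_topology("+B+0-C-1")),
                   as.integer(oracle2[[1L]]))
})

test_that("derivation length is 5 rules per element with an 11-element cap", {
  for (i in 1:50) {
    t <- sample_topology(max_elements = 11L, seed = i)
    expect_length(derive_rules(t), 5L * nrow(t))
  }
  eleven <- parse_topology(strrep("+B+0", 11L))
  expect_length(derive_rules(eleven), 55L)
  twelve <- parse_topology(strrep("+B+0", 12L))
  expect_error(derive_rules(twelve), "55")
})

test_that("rule encoding is one-hot over 55 blocks of 23", {
  # empty derivation: all padding
  e <- encode_rules(integer(0))
  expect_length(e, 1265L)
  expect_equal(sum(e), 55)
  expect_true(all(matrix(e, nrow = 23L)[23L, ] == 1))
  # a one-element derivation has exactly 5 non-padding blocks
  r <- derive_rules(parse_topology("+B+0"))
  g <- encode_rules(r)
  expect_equal(sum(matrix(g, nrow = 23L)[23L, ] == 0), 5L)
  expect_identical(decode_rules(g), as.integer(r))
  expect_error(encode_rules(c(0L, 22L)), "\\[0, 21\\]")
})

test_that("decoding validates that the rule order is a real derivation", {
  r <- derive_rules(parse_topology("+B+0"))
  bad <- encode_rules(rev(r))
  expect_error(decode_rules(bad), "expected")
  expect_error(decode_rules(numeric(100)), "length")
})

test_that("topology sampling is seeded, closed under the grammar, and capped", {
  expect_identical(unparse_topology(sample_topology(seed = 99)),
                   unparse_topology(sample_topology(seed = 99)))
  for (i in 1:200) {
    t <- sample_topology(max_elements = 11L, seed = i)
    s <- unparse_topology(t)
    expect_identical(unparse_topology(parse_topology(s)), s)
    expect_identical(unparse_topology(replay_rules(derive_rules(t))), s)
  }
  for (i in 1:20)
    expect_equal(nrow(sample_topology(max_elements = 1L, seed = i)), 1L)
})
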