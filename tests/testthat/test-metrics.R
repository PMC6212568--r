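# brute-force motif oracle: test every index pair directly
brute_hx3h <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  out <- NULL
  for (i in seq_along(chars)) for (j in seq_along(chars))
    if (j == i + 4L && chars[i] == "H" && chars[j] == "H")
      out <- rbind(out, c(i, j))
  if (is.null(out)) cbind(first = integer(0), second = integer(0))
  else cbind(first = out[, 1L], second = out[, 2L])
}

# direct-summation JSD oracle, written independently of the implementation
brute_jsd <- function(p, q) {
  m <- 0.5 * (p + q)
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * (log(p[i]) - log(m[i])) / log(2)
    if (q[i] > 0) s <- s + 0.5 * q[i] * (log(q[i]) - log(m[i])) / log(2)
  }
  s
}

test_that("His-x3-His scan matches brute-force pair enumeration", {
  expect_equal(find_hx3h("HAAAH"), cbind(first = 1L, second = 5L))
  expect_equal(nrow(find_hx3h("HAAH")), 0L)
  expect_equal(find_hx3h("HAAAHAAAH"),
               cbind(first = c(1L, 5L), second = c(5L, 9L)))
  set.seed(20)
  for (i in 1:50) {
    s <- paste(sample(c("H", "A", "G"), 60, replace = TRUE, prob = c(.3, .4, .3)),
               collapse = "")
    expect_equal(find_hx3h(s), brute_hx3h(s))
  }
})

test_that("the helix annotation restricts motif hits", {
  seq <- "HAAAHAAAH"
  ss_all <- "HHHHHHHHH"
  ss_part <- "HHHHHCCCC"   # only the first pair is fully helical
  expect_equal(nrow(find_hx3h(seq, ss_all)), 2L)
  expect_equal(find_hx3h(seq, ss_part), cbind(first = 1L, second = 5L))
  expect_error(find_hx3h(seq, "HH"), "length")
})

test_that("spatially close histidines are found on a coordinate frame", {
  coords <- data.frame(index = 1:10, residue = "X",
                       x = c(0, 10, 0.5, 20, 30, 40, 50, 60, 70, 1),
                       y = 0, z = 0)
  seq <- "HAHAAAAAAH"   # His at 1, 3, 10
  hits <- close_histidines(seq, coords, cutoff = 7)
  # all three pairs lie within 1 A of each other along x
  expect_equal(hits, cbind(first = c(1L, 1L, 3L), second = c(3L, 10L, 10L)))
  # far pair not reported at a 7 A cutoff
  far <- close_histidines("HAAAAAAAAH", coords, cutoff = 7)
  expect_equal(nrow(far), 1L)  # positions 1 and 10 are 1 A apart here
  expect_equal(nrow(close_histidines("HAAAAAAAH",
                                     transform(coords, x = (1:10) * 50))), 0L)
  # coincident positions always report
  same <- data.frame(index = 1:5, residue = "X", x = 1, y = 1, z = 1)
  expect_equal(nrow(close_histidines("HAHAH", same, cutoff = 0.1)), 3L)
  # adjacent histidines (separation < 2) are not pairs
  expect_equal(nrow(close_histidines("HH", same[1:2, ], cutoff = 10)), 0L)
  # residues without coordinates are skipped with a warning
  expect_warning(h <- close_histidines("HAHAAAAAAH", coords[-1L, ], 7),
                 "skipped")
  expect_equal(h, cbind(first = 3L, second = 10L))
})

test_that("PDB residue coordinates pick coordinating side-chain atoms", {
  pdb_lines <- c(
    "ATOM      1  N   HIS A   1      0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  HIS A   1      1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  NE2 HIS A   1      2.500   1.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2      4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA A   3      8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CB  ALA A   3      8.500   1.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  co <- residue_coordinates(f)
  expect_equal(nrow(co), 3L)
  expect_equal(co$residue, c("H", "G", "A"))
  expect_equal(co$x, c(2.5, 4, 8.5))   # NE2, CA fallback, CB fallback
  unlink(f)
})

test_that("JSD conservation matches the direct-summation oracle", {
  aas <- aa_alphabet()[1:20]
  # column identical to the background scores zero
  bg <- setNames(c(0.5, 0.5, rep(0, 18)), aas)   # A and C only
  aln <- c("AC", "CA")                            # both columns are 50/50 A/C
  expect_equal(unname(jsd_conservation(aln, bg)), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # fully conserved column vs uniform background, against the oracle
  p <- c(1, rep(0, 19)); q <- rep(1 / 20, 20)
  aln2 <- c("AA", "AA", "AA")
  expect_equal(unname(jsd_conservation(aln2)[1L]), brute_jsd(p, q),
               tolerance = 1e-10)
  # random columns agree with the oracle to 1e-10
  set.seed(21)
  for (i in 1:25) {
    col <- sample(aas, 12, replace = TRUE)
    aln3 <- vapply(col, function(ch) paste0(ch, "A"), character(1))
    pc <- as.numeric(table(factor(col, levels = aas))) / 12
    expect_equal(unname(jsd_conservation(aln3)[1L]), brute_jsd(pc, q),
                 tolerance = 1e-10)
  }
  # symmetry of the divergence: swap column distribution and background
  p2 <- setNames(c(0.75, 0.25, rep(0, 18)), aas)
  a_pq <- jsd_conservation(c("A", "A", "A", "C"), bg)[1L]   # p2 vs bg
  a_qp <- jsd_conservation(c("A", "C", "A", "C"), p2)[1L]   # bg vs p2
  expect_equal(unname(a_pq), unname(a_qp), tolerance = 1e-10)
  expect_true(all(jsd_conservation(c("ACDE", "KLMN"))
                  >= 0 - 1e-12))
})

test_that("gap handling excludes gaps and flags gappy columns", {
  aln <- c("A-A", "A-C", "A-G", "-AT")
  out <- jsd_conservation(aln)
  expect_true(attr(out, "gappy")[2L])
  expect_false(attr(out, "gappy")[1L])
  expect_error(jsd_conservation(c("AA", "AAA")), "ragged")
})

test_that("sequence identity covers equal, divergent and gapped pairs", {
  expect_equal(sequence_identity("ACDEF", "ACDEF"), 100)
  expect_equal(sequence_identity("AAAA", "AAAT"), 75)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0)
  # unequal lengths go through a global alignment
  expect_equal(sequence_identity("ACDEFG", "ACDFG"), 100 * 5 / 6,
               tolerance = 1e-9)
  expect_error(sequence_identity("", "AAA"), "empty")
})

test_that("residue enrichment counts strict exceedance", {
  expect_equal(residue_enrichment(c("AD", "AD"), "AD", "D"), 0)
  expect_equal(residue_enrichment(c("ADD", "DDA"), "AD", "D"), 1)
  expect_equal(residue_enrichment(c("ADD", "AD", "AD", "AA"), "AD", "D"), 0.25)
})
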