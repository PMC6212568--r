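# Sequence- and structure-level evaluation of generated sequences:
# copper-motif scans, spatial histidine proximity on a template structure,
# per-column Jensen-Shannon conservation, sequence identity and residue
# enrichment.

#' Scan a sequence for His-x3-His motifs
#'
#' Finds all position pairs \code{(i, i+4)} where both residues are
#' histidine — the classic linear copper-coordination pattern of two
#' histidines separated by three arbitrary residues. If a per-residue
#' secondary-structure string is supplied, only pairs with both positions
#' helix-annotated (\code{"H"} in \code{ss}) are kept.
#'
#' @param seq Amino-acid string.
#' @param ss Optional secondary-structure string of the same length
#'   (\code{"H"} marks helix).
#' @return Two-column integer matrix of 1-based position pairs (zero rows
#'   if none).
#' @examples
#' find_hx3h("HAAAHAAAH")
#' @export
find_hx3h <- function(seq, ss = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (!is.null(ss)) {
    if (nchar(ss) != n)
      stop("secondary-structure string length differs from sequence",
           call. = FALSE)
    helix <- strsplit(toupper(ss), "", fixed = TRUE)[[1L]] == "H"
  }
  i <- which(chars == "H")
  i <- i[i + 4L <= n & chars[pmin(i + 4L, n)] == "H"]
  if (!is.null(ss)) i <- i[helix[i] & helix[i + 4L]]
  cbind(first = i, second = i + 4L)
}

#' Extract representative residue coordinates from a PDB structure
#'
#' Reads the first model of a (single) chain and returns one
#' representative 3-D point per residue: a typical metal-coordinating
#' side-chain atom where the residue type has one (His NE2, Cys SG,
#' Asp OD2, Glu OE2, Met SD, Ser OG, Thr OG1, Tyr OH, Asn OD1, Gln OE1),
#' else the beta-carbon, falling back to the alpha-carbon.
#'
#' @param pdb Path to a PDB file, or a \code{bio3d} \code{pdb} object.
#' @param chain Optional chain identifier; default takes the first chain.
#' @return data.frame with columns \code{index} (1-based position along
#'   the chain), \code{residue} (one-letter code), \code{x}, \code{y},
#'   \code{z} (Angstrom).
#' @export
residue_coordinates <- function(pdb, chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, call. = FALSE)
  rep_atom <- c(HIS = "NE2", CYS = "SG", ASP = "OD2", GLU = "OE2",
                MET = "SD", SER = "OG", THR = "OG1", TYR = "OH",
                ASN = "OD1", GLN = "OE1")
  resnos <- unique(at$resno)
  rows <- lapply(seq_along(resnos), function(i) {
    res <- at[at$resno == resnos[i], , drop = FALSE]
    resn <- res$resid[1L]
    pref <- c(unname(rep_atom[resn]), "CB", "CA")
    pick <- res[match(pref, res$elety), , drop = FALSE]
    pick <- pick[!is.na(pick$elety), , drop = FALSE][1L, , drop = FALSE]
    if (is.na(pick$elety)) return(NULL)
    aa1 <- bio3d::aa321(resn)
    data.frame(index = i, residue = ifelse(is.na(aa1), "X", aa1),
               x = pick$x, y = pick$y, z = pick$z)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find spatially close histidine pairs
#'
#' Threads a sequence onto a residue coordinate frame (e.g. a template
#' structure read with [residue_coordinates()]) and reports every pair of
#' histidines whose representative atoms lie within \code{cutoff}
#' Angstrom, requiring at least two intervening residues so trivially
#' adjacent pairs are not counted. Residues without coordinates are
#' skipped with a warning.
#'
#' @param seq Amino-acid string (positions index into \code{coords}).
#' @param coords data.frame from [residue_coordinates()] (columns
#'   \code{index}, \code{x}, \code{y}, \code{z}).
#' @param cutoff Distance cutoff in Angstrom; default 7, a typical
#'   metal-site screening distance (configurable, not hard-coded).
#' @return Two-column integer matrix of 1-based histidine position pairs
#'   with \code{first < second}.
#' @export
close_histidines <- function(seq, coords, cutoff = 7) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  his <- which(chars == "H")
  if (length(his) < 2L) return(cbind(first = integer(0), second = integer(0)))
  have <- his %in% coords$index
  if (any(!have)) {
    warning("no coordinates for histidine position(s) ",
            paste(his[!have], collapse = ", "), "; skipped", call. = FALSE)
    his <- his[have]
  }
  xyz <- as.matrix(coords[match(his, coords$index), c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("first", "second")))
  for (i in seq_along(his)) for (j in seq_along(his)) {
    if (j <= i) next
    if (his[j] - his[i] < 2L) next   # sequence separation >= 2
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(his[i], his[j]))
  }
  out
}

#' Per-column Jensen-Shannon conservation of an alignment
#'
#' For each column of an equal-length alignment, the Jensen-Shannon
#' divergence (half-mixture definition, log base 2, hence bounded in
#' \code{[0, 1]}) between the column's amino-acid distribution and a
#' background distribution. Gap characters (\code{"-"} and \code{"."})
#' are excluded from the column distribution; columns with more than 50%
#' gaps are flagged.
#'
#' @param alignment Character vector of two or more equal-length aligned
#'   sequences.
#' @param background Named 20-vector of background frequencies (default
#'   uniform); see [aa_frequencies()] to use training-set frequencies.
#' @return Numeric vector of JSD values, one per column, with attribute
#'   \code{"gappy"} — a logical vector flagging columns with over 50%
#'   gaps (columns that are all gaps score \code{NA}).
#' @export
jsd_conservation <- function(alignment, background = NULL) {
  stopifnot(length(alignment) >= 2L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("alignment is ragged: sequence lengths differ", call. = FALSE)
  aas <- aa_alphabet()[1:20]
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), aas)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must be normalised", call. = FALSE)
  background <- background[aas]
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  apply_col <- function(col) {
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0L) return(NA_real_)
    p <- as.numeric(table(factor(col, levels = aas)))
    if (sum(p) == 0L) return(NA_real_)   # column entirely non-standard
    p <- p / sum(p)
    .jsd(p, background)
  }
  out <- apply(m, 2L, apply_col)
  gaps <- colMeans(matrix(m %in% c("-", "."), nrow(m)))
  attr(out, "gappy") <- gaps > 0.5
  out
}

# Jensen-Shannon divergence, half-mixture, log2; 0*log0 := 0
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Percentage sequence identity
#'
#' Equal-length sequences are compared position-wise. Unequal lengths are
#' globally aligned first (Needleman-Wunsch via Biostrings: match +1,
#' mismatch -1, gap open -2, gap extension -1) and identity is matches
#' over alignment length.
#'
#' @param a,b Nonempty amino-acid strings.
#' @return Identity as a percentage in \code{[0, 100]}.
#' @examples
#' sequence_identity("AAAA", "AAAT")  # 75
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    return(100 * sum(ca == cb) / length(ca))
  }
  letters22 <- aa_alphabet()
  mat <- matrix(-1, 22L, 22L, dimnames = list(letters22, letters22))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1L]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Fraction of generated sequences enriched in a residue
#'
#' The fraction of generated sequences whose count of \code{residue}
#' strictly exceeds the native sequence's count — e.g. aspartate
#' enrichment when calcium binding was requested.
#'
#' @param generated Character vector of generated sequences.
#' @param native Native sequence.
#' @param residue Single residue character.
#' @return Fraction in \code{[0, 1]}.
#' @export
residue_enrichment <- function(generated, native, residue) {
  stopifnot(length(generated) >= 1L, nchar(residue) == 1L)
  count <- function(s) lengths(regmatches(s, gregexpr(residue, s, fixed = TRUE)))
  mean(count(toupper(generated)) > count(toupper(native))[1L])
}
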