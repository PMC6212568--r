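# Dataset construction: sequence records, attribute vectors, negative
# metal-binding examples, homologue filtering, and the FASTA/TSV record
# interchange format.
#
# A "records" data.frame has one protein per row with columns:
#   id, sequence, fe zn ca na cu mg cd ni (0/1 flags in the canonical
#   metal order), binding_positions (comma-separated 1-based residue
#   indices, "" if none), topology (fold string or NA), family, provenance
#   ("native", "homologue" or "negative").
# Residue indices are 1-based throughout the package.

#' Canonical metal order
#'
#' The fixed order of the eight metal-binding flags: Fe, Zn, Ca, Na, Cu,
#' Mg, Cd, Ni. Attribute vectors, discriminator outputs and manifest
#' columns all use this order.
#'
#' @return Character vector of length 8.
#' @export
metal_order <- function() c("Fe", "Zn", "Ca", "Na", "Cu", "Mg", "Cd", "Ni")

.metal_cols <- function() tolower(metal_order())

#' @keywords internal
.parse_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' @keywords internal
.format_positions <- function(p) paste(p, collapse = ",")

#' Make a negative metal-binding training example
#'
#' Copies a metal-binding record, resampling each annotated binding
#' residue independently from the training-set amino-acid frequency
#' distribution, and zeroing all metal flags. Because the replacement is a
#' plain draw from the background distribution, a site may redraw its
#' original residue; the negative differs from the source only at binding
#' positions (possibly a subset of them).
#'
#' @param rec A single-row records data.frame with at least one binding
#'   position.
#' @param aa_freqs Named numeric vector of background frequencies over the
#'   20 standard amino acids, summing to 1 (within 1e-9); see
#'   [aa_frequencies()].
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return The mutated single-row records data.frame with provenance
#'   \code{"negative"}, id suffixed \code{"_neg"}, and all flags 0.
#' @export
make_negative_example <- function(rec, aa_freqs, seed = NULL) {
  stopifnot(is.data.frame(rec), nrow(rec) == 1L)
  pos <- .parse_positions(rec$binding_positions)
  if (length(pos) == 0L)
    stop("record '", rec$id, "' has no binding positions to mutate",
         call. = FALSE)
  if (abs(sum(aa_freqs) - 1) > 1e-9)
    stop("aa_freqs must sum to 1", call. = FALSE)
  aas <- names(aa_freqs)
  if (is.null(aas) || length(aas) != 20L)
    stop("aa_freqs must be a named 20-vector of amino-acid frequencies",
         call. = FALSE)
  chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1L]]
  if (any(pos < 1L | pos > length(chars)))
    stop("binding position outside sequence for '", rec$id, "'", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chars[pos] <- sample(aas, length(pos), replace = TRUE, prob = aa_freqs)
  out <- rec
  out$id <- paste0(rec$id, "_neg")
  out$sequence <- paste(chars, collapse = "")
  out[.metal_cols()] <- 0L
  out$provenance <- "negative"
  out
}

#' Propagate binding-site mutations from a native chain to a homologue
#'
#' When a native structure's binding residues are mutated to build a
#' negative example, homologous sequences receive the same replacements at
#' the corresponding alignment columns — but only where the homologue
#' carries the same amino acid as the native chain at that column;
#' positions that already diverged are left untouched.
#'
#' @param native Single-row records data.frame of the native chain (used
#'   for the identity check).
#' @param homologue Single-row records data.frame to mutate.
#' @param column_map Named integer vector mapping native residue index
#'   (names, 1-based) to homologue residue index (values); must be
#'   injective.
#' @param mutations Named character vector: native position (1-based) to
#'   replacement residue, as applied to the native chain.
#' @return The homologue record, mutated where the rule applies, with all
#'   metal flags zeroed and provenance \code{"negative"}.
#' @export
propagate_mutations <- function(native, homologue, column_map, mutations) {
  stopifnot(is.data.frame(native), nrow(native) == 1L,
            is.data.frame(homologue), nrow(homologue) == 1L)
  if (anyDuplicated(column_map))
    stop("column_map must be injective", call. = FALSE)
  nat <- strsplit(native$sequence, "", fixed = TRUE)[[1L]]
  hom <- strsplit(homologue$sequence, "", fixed = TRUE)[[1L]]
  out <- homologue
  if (length(mutations)) {
    for (k in seq_along(mutations)) {
      ni <- as.integer(names(mutations)[k])
      if (is.na(ni) || ni < 1L || ni > length(nat))
        stop("mutated native position ", names(mutations)[k],
             " outside native sequence", call. = FALSE)
      hi <- column_map[as.character(ni)]
      if (is.na(hi)) next  # native column not aligned in this homologue
      hi <- as.integer(hi)
      if (hi < 1L || hi > length(hom))
        stop("column_map points outside homologue at native position ", ni,
             call. = FALSE)
      if (hom[hi] == nat[ni]) hom[hi] <- mutations[[k]]
    }
  }
  out$id <- paste0(homologue$id, "_neg")
  out$sequence <- paste(hom, collapse = "")
  out[.metal_cols()] <- 0L
  out$provenance <- "negative"
  out
}

#' Homologue length filter
#'
#' Keep a homology hit only if its length lies within 80--120% of the
#' query length, and never above 140 residues.
#'
#' @param query_len,hit_len Positive integer vectors (recycled).
#' @return Logical vector.
#' @examples
#' filter_homologue(100, c(75, 80, 120, 125))
#' filter_homologue(120, 141)
#' @export
filter_homologue <- function(query_len, hit_len) {
  stopifnot(all(query_len > 0), all(hit_len > 0))
  hit_len >= 0.8 * query_len & hit_len <= pmin(1.2 * query_len, 140)
}

#' Amino-acid frequencies of a sequence set
#'
#' Pooled frequencies of the 20 standard amino acids across all sequences
#' (non-standard residues are ignored); used as the background for
#' negative-example resampling and conservation scoring.
#'
#' @param seqs Character vector of sequences.
#' @return Named numeric 20-vector summing to 1.
#' @export
aa_frequencies <- function(seqs) {
  aas <- aa_alphabet()[1:20]
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE))
  counts <- table(factor(chars, levels = aas))
  n <- sum(counts)
  if (n == 0L) stop("no standard residues found", call. = FALSE)
  out <- as.numeric(counts) / n
  names(out) <- aas
  out
}

#' Build the conditioning attribute for one record
#'
#' Metal mode returns the 8 flags in canonical order; grammar mode parses
#' the record's topology string, derives its canonical rule sequence and
#' one-hot encodes it to the 1265-long tensor.
#'
#' @param rec Single-row records data.frame.
#' @param mode \code{"metal"} or \code{"grammar"}.
#' @return Numeric vector of length 8 or 1265.
#' @export
build_attribute <- function(rec, mode = c("metal", "grammar")) {
  mode <- match.arg(mode)
  if (mode == "metal") {
    as.numeric(unlist(rec[.metal_cols()]))
  } else {
    if (is.na(rec$topology) || !nzchar(rec$topology))
      stop("record '", rec$id, "' has no topology string", call. = FALSE)
    encode_rules(derive_rules(parse_topology(rec$topology)))
  }
}

#' Build the attribute matrix for a records table
#'
#' @param records Records data.frame.
#' @inheritParams build_attribute
#' @return Numeric matrix, one attribute row per record.
#' @export
build_attributes <- function(records, mode = c("metal", "grammar")) {
  mode <- match.arg(mode)
  if (mode == "metal") {
    m <- as.matrix(records[, .metal_cols(), drop = FALSE]) * 1.0
    dimnames(m) <- NULL
    m
  } else {
    # encode each distinct topology once
    tops <- unique(records$topology)
    enc <- lapply(tops, function(s)
      encode_rules(derive_rules(parse_topology(s))))
    names(enc) <- tops
    do.call(rbind, enc[records$topology])
  }
}

# ---- record I/O ------------------------------------------------------------

#' Read/write sequence records as FASTA + TSV manifest
#'
#' Sequences travel as FASTA; everything else (flags, binding positions,
#' topology, family, provenance) as a tab-separated manifest keyed by
#' \code{id}. `write_records` emits both files; `read_records` joins them
#' back into a records data.frame.
#'
#' @param records Records data.frame.
#' @param fasta,manifest File paths.
#' @return \code{read_records}: the records data.frame.
#'   \code{write_records}: invisibly, the two paths.
#' @export
write_records <- function(records, fasta, manifest) {
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- records$id
  Biostrings::writeXStringSet(seqs, fasta)
  man <- records[, c("id", .metal_cols(), "binding_positions", "topology",
                     "family", "provenance")]
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(fasta = fasta, manifest = manifest))
}

#' @rdname write_records
#' @export
read_records <- function(fasta, manifest) {
  seqs <- Biostrings::readAAStringSet(fasta)
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  idx <- match(man$id, names(seqs))
  if (anyNA(idx))
    stop("manifest ids missing from FASTA: ",
         paste(man$id[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- data.frame(id = man$id,
                    sequence = as.character(seqs[idx]),
                    stringsAsFactors = FALSE)
  for (m in .metal_cols()) out[[m]] <- as.integer(man[[m]])
  out$binding_positions <- man$binding_positions
  out$topology <- ifelse(nzchar(man$topology), man$topology, NA_character_)
  out$family <- man$family
  out$provenance <- man$provenance
  out
}
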