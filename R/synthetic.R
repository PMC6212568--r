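# Synthetic protein-family generator.
#
# Emulates the statistical structure the models are trained on: families
# of related sequences (a native chain plus up to 50 homologues), planted
# per-position conservation, metal-binding motifs tied to attribute flags,
# per-family topology labels, and matched negative twins in which the
# binding residues are resampled from background frequencies. Mutations
# are i.i.d. per position — deliberately, since residue covariation is a
# known blind spot of this model family and is not emulated.

# Metal-specific planted binding motifs (tripeptides of typical
# coordinating residues). Families binding the same metal carry the motif
# at the same, metal-specific site — the synthetic analogue of binding
# sites at structurally equivalent positions of a shared fold.
.METAL_MOTIFS <- c(Fe = "HEH", Zn = "CHC", Ca = "DND", Na = "DGD",
                   Cu = "HMH", Mg = "DED", Cd = "CCC", Ni = "HTH")

#' Specify a synthetic protein family
#'
#' @param id Family label.
#' @param length Consensus length (residues), at most 140.
#' @param n_homologues Number of homologues besides the native chain (at
#'   most 50, mirroring the per-structure cap used when harvesting real
#'   homologues).
#' @param conservation Per-position probability, in \code{[0,1]}, that a
#'   homologue retains the consensus residue; scalar or length
#'   \code{length}.
#' @param metal Metal name from [metal_order()], or \code{NULL} for a
#'   non-binding family.
#' @param motif Residues planted at the binding site (character scalar);
#'   defaults to the metal's canonical tripeptide.
#' @param motif_start 1-based start of the motif; required when
#'   \code{metal} is set.
#' @param topology Topology string for the family, or \code{NULL}.
#' @return An object of class \code{"family_spec"}.
#' @export
family_spec <- function(id, length, n_homologues = 50L, conservation = 0.9,
                        metal = NULL, motif = NULL, motif_start = NULL,
                        topology = NULL) {
  stopifnot(length >= 10L, length <= 140L,
            n_homologues >= 0L, n_homologues <= 50L)
  conservation <- rep_len(conservation, length)
  if (any(conservation < 0 | conservation > 1))
    stop("conservation probabilities must lie in [0,1]", call. = FALSE)
  if (!is.null(metal)) {
    metal <- match.arg(metal, metal_order())
    if (is.null(motif)) motif <- .METAL_MOTIFS[[metal]]
    if (is.null(motif_start))
      stop("motif_start is required for a metal-binding family", call. = FALSE)
    if (motif_start < 1L || motif_start + nchar(motif) - 1L > length)
      stop("motif does not fit inside the consensus length", call. = FALSE)
  }
  structure(list(id = id, length = as.integer(length),
                 n_homologues = as.integer(n_homologues),
                 conservation = conservation, metal = metal, motif = motif,
                 motif_start = as.integer(motif_start %||% NA_integer_),
                 topology = topology),
            class = "family_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the sequence records of one synthetic family
#'
#' Draws a consensus uniformly over the 20 standard amino acids, plants
#' the motif (if the family binds a metal; motif positions are then held
#' perfectly conserved), and mutates each homologue independently: every
#' position is retained with its conservation probability, otherwise
#' redrawn uniformly (so a redraw can coincide with the consensus
#' residue).
#'
#' @param spec A [family_spec()].
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return Records data.frame with \code{n_homologues + 1} rows: the
#'   native chain plus homologues.
#' @export
generate_family <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  aas <- aa_alphabet()[1:20]
  L <- spec$length
  cons <- sample(aas, L, replace = TRUE)
  keep_p <- spec$conservation
  pos <- integer(0)
  if (!is.null(spec$metal)) {
    mot <- strsplit(spec$motif, "", fixed = TRUE)[[1L]]
    pos <- spec$motif_start + seq_along(mot) - 1L
    cons[pos] <- mot
    keep_p[pos] <- 1     # binding site fixed while the flag is on
  }
  n <- spec$n_homologues
  member <- function(i) {
    s <- cons
    if (i > 0L) {
      mut <- stats::runif(L) > keep_p
      if (any(mut)) s[mut] <- sample(aas, sum(mut), replace = TRUE)
    }
    paste(s, collapse = "")
  }
  seqs <- vapply(0:n, member, character(1))
  out <- data.frame(
    id = paste0(spec$id, "_", 0:n),
    sequence = seqs,
    stringsAsFactors = FALSE)
  for (m in .metal_cols())
    out[[m]] <- as.integer(!is.null(spec$metal) && tolower(spec$metal) == m)
  out$binding_positions <- .format_positions(pos)
  out$topology <- spec$topology %||% NA_character_
  out$family <- spec$id
  out$provenance <- c("native", rep("homologue", n))
  out
}

#' Generate a full synthetic dataset
#'
#' Builds \code{n_families} families: the first \code{2 * 8} (by default)
#' are metal binders, two families per metal in canonical order, the rest
#' bind nothing. Each metal's planted motif sits at a metal-specific site
#' drawn once; family lengths, topologies and per-position conservation
#' levels vary per family. For every member of a flagged family a
#' matched negative twin is added via [make_negative_example()]:
#' identical except that the binding residues are resampled from the
#' pooled amino-acid frequencies of the positive set and all flags are
#' zeroed. The result streams through [build_attributes()],
#' [cvae()] and [discriminator()] unchanged.
#'
#' @param n_families Number of families (at least 2; default 24, of which
#'   16 bind metals).
#' @param n_binding Number of metal-binding families (cycled over the 8
#'   metals; default \code{min(16, n_families)}).
#' @param n_homologues Homologues per family (default 50).
#' @param max_len Maximum sequence length; family lengths are drawn
#'   uniformly between half of \code{max_len} and \code{max_len - 2}.
#' @param conservation_range Range the per-position conservation
#'   probabilities are drawn from (default \code{c(0.6, 0.98)}).
#' @param n_topologies Size of the topology pool families draw from;
#'   topologies are shared between families (as folds are in real
#'   structure collections). Default one topology per three families.
#' @param seed Integer seed; the whole dataset, including file output, is
#'   a pure function of it.
#' @param dir Optional directory: if given, \code{sequences.fasta} and
#'   \code{manifest.tsv} are written there.
#' @return Records data.frame of all members plus negative twins.
#' @examples
#' recs <- generate_dataset(n_families = 4, n_homologues = 5, seed = 1)
#' table(recs$provenance)
#' @export
generate_dataset <- function(n_families = 24L, n_binding = min(16L, n_families),
                             n_homologues = 50L, max_len = 60L,
                             conservation_range = c(0.6, 0.98),
                             n_topologies = max(2L, n_families %/% 3L),
                             seed = 1L, dir = NULL) {
  stopifnot(n_families >= 2L, n_binding <= n_families, max_len >= 20L,
            max_len <= 140L)
  set.seed(seed)
  metals <- rep_len(metal_order(), n_binding)
  len_min <- max(10L, max_len %/% 2L)
  # one binding site per metal, common to its families
  site <- stats::setNames(sample(5:(len_min - 8L), 8L, replace = TRUE),
                          metal_order())
  topo_pool <- replicate(n_topologies,
                         unparse_topology(sample_topology(max_elements = 5L)))
  fams <- lapply(seq_len(n_families), function(i) {
    L <- sample(len_min:(max_len - 2L), 1L)
    metal <- if (i <= n_binding) metals[i] else NULL
    family_spec(
      id = sprintf("fam%02d", i), length = L, n_homologues = n_homologues,
      conservation = stats::runif(L, conservation_range[1], conservation_range[2]),
      metal = metal,
      motif_start = if (!is.null(metal)) site[[metal]] else NULL,
      topology = sample(topo_pool, 1L))
  })
  recs <- do.call(rbind, lapply(fams, generate_family))
  # negative twins for every member of a flagged family
  flagged <- recs[rowSums(recs[.metal_cols()]) > 0L, , drop = FALSE]
  if (nrow(flagged)) {
    freqs <- aa_frequencies(flagged$sequence)
    negs <- do.call(rbind, lapply(seq_len(nrow(flagged)), function(i)
      make_negative_example(flagged[i, , drop = FALSE], freqs)))
    recs <- rbind(recs, negs)
  }
  rownames(recs) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_records(recs, file.path(dir, "sequences.fasta"),
                  file.path(dir, "manifest.tsv"))
  }
  recs
}
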