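# Generation procedures.
#
# Metalloprotein task: posterior resampling — the input protein is encoded
# once with its (possibly modified) conditioning attribute and many
# reparameterised latent samples are decoded, yielding variants of the
# input with the requested binding character.
#
# Structure task: iterative latent-space search — round 1 samples the
# standard-normal prior under the topology attribute; each later round
# encodes the incumbent best sequence and samples its posterior,
# exploring the neighbourhood. Candidates are ranked by a pluggable
# scorer (lower is better); the incumbent is carried into every round's
# comparison, so the best score never worsens.

#' Posterior resampling of a sequence (metalloprotein task)
#'
#' Encodes \code{seq} once under \code{attr}, draws \code{n}
#' reparameterised latent samples from its posterior and decodes each
#' under the same attribute. Turning a metal flag on in \code{attr}
#' requests the corresponding binding character in the variants.
#'
#' @param object A fitted [cvae()] model.
#' @param seq Input amino-acid sequence.
#' @param attr Conditioning attribute vector (e.g. the 8 metal flags with
#'   the requested metal set to 1).
#' @param n Number of variants (default 1000).
#' @param seed Optional integer seed.
#' @return Character vector of \code{n} sequences.
#' @export
sample_metal_variants <- function(object, seq, attr, n = 1000L, seed = NULL) {
  stopifnot(inherits(object, "cvae"), n >= 1L)
  a <- .resolve_attribute(object, attr)
  post <- cvae_encode(object, seq, a)
  z <- reparameterize(post, n = n, seed = seed)
  decode_sequences(cvae_decode(object, z, a))
}

#' Sample sequences for a topology from the prior (structure task)
#'
#' Draws latent vectors from the standard-normal prior and decodes them
#' under the grammar encoding of the requested topology, generating
#' sequences from across the learned space for that fold.
#'
#' @param object A fitted grammar-mode [cvae()] model.
#' @param topology A topology string or \code{"topology"} object.
#' @param n Number of sequences (default 1000).
#' @param seed Optional integer seed.
#' @return Character vector of \code{n} sequences.
#' @export
sample_from_topology <- function(object, topology, n = 1000L, seed = NULL) {
  stopifnot(inherits(object, "cvae"), n >= 1L)
  if (object$config$mode != "grammar")
    stop("sample_from_topology needs a grammar-mode model", call. = FALSE)
  a <- .resolve_attribute(object, topology)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  z <- matrix(stats::rnorm(n * object$config$latent_dim), n,
              object$config$latent_dim)
  decode_sequences(cvae_decode(object, z, a))
}

#' Mock scorer: Hamming distance to a target sequence
#'
#' A reference scorer for testing the iterative search without external
#' structure tools: the score of a candidate is its Hamming distance to
#' \code{target} (position mismatches plus the length difference), lower
#' is better.
#'
#' @param target The hidden target sequence.
#' @return A scorer function \code{function(seq, context)} returning a
#'   numeric score.
#' @export
hamming_scorer <- function(target) {
  tc <- strsplit(target, "", fixed = TRUE)[[1L]]
  function(seq, context = NULL) {
    sc <- strsplit(seq, "", fixed = TRUE)[[1L]]
    k <- min(length(tc), length(sc))
    sum(tc[seq_len(k)] != sc[seq_len(k)]) + abs(length(tc) - length(sc))
  }
}

#' External command scorer
#'
#' Adapter for plugging an external structure-scoring pipeline into
#' [iterative_search()]: candidates are written to a FASTA file, the
#' command is run with the FASTA path and an output path substituted for
#' \code{"{fasta}"} and \code{"{scores}"}, and scores are read back from
#' the resulting two-column TSV (id, score).
#'
#' @param command Command template containing \code{"{fasta}"} and
#'   \code{"{scores}"} placeholders.
#' @return A scorer function suitable for [iterative_search()].
#' @export
command_scorer <- function(command) {
  function(seq, context = NULL) {
    fa <- tempfile(fileext = ".fasta")
    ts <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fa, ts)))
    s <- Biostrings::AAStringSet(seq)
    names(s) <- "candidate"
    Biostrings::writeXStringSet(s, fa)
    cmd <- gsub("{fasta}", fa, gsub("{scores}", ts, command, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("scorer command failed with status ", status,
                           call. = FALSE)
    tab <- utils::read.table(ts, sep = "\t", header = FALSE)
    as.numeric(tab[1L, 2L])
  }
}

#' Iterative sample-analyse-resample search (structure task)
#'
#' Round 1 draws \code{n_per_round} sequences from the prior for the
#' requested topology; every candidate is scored (a scorer failure skips
#' that candidate with a warning) and the best sequence — always compared
#' against the incumbent, so the best score is nonincreasing across
#' rounds — is fed back into the inference network, whose posterior is
#' sampled for the next round. The per-round shortlist of the
#' \code{top_k} best candidates is recorded for downstream structure
#' generation.
#'
#' @param object A fitted grammar-mode [cvae()] model.
#' @param topology Topology string or \code{"topology"} object.
#' @param scorer Function \code{(sequence, context) -> numeric}, lower is
#'   better; see [hamming_scorer()] and [command_scorer()].
#' @param rounds Number of rounds (default 3).
#' @param n_per_round Samples per round (default 1000).
#' @param top_k Shortlist size recorded per round (default 5).
#' @param seed Optional integer seed; each round derives its own
#'   sub-seed, recorded in the history.
#' @return Object of class \code{"iterative_search"}: list with
#'   \code{best} (sequence), \code{best_score}, and \code{history} — one
#'   entry per round holding \code{iteration}, \code{seed},
#'   \code{best}, \code{best_score}, \code{shortlist} (data.frame) and
#'   \code{scores} (all candidate scores of the round).
#' @export
iterative_search <- function(object, topology, scorer, rounds = 3L,
                             n_per_round = 1000L, top_k = 5L, seed = NULL) {
  stopifnot(inherits(object, "cvae"), rounds >= 1L, n_per_round >= 1L,
            is.function(scorer))
  a <- .resolve_attribute(object, topology)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  round_seeds <- sample.int(.Machine$integer.max, rounds)
  best <- NULL
  best_score <- Inf
  history <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    cand <- if (r == 1L) {
      sample_from_topology(object, topology, n = n_per_round,
                           seed = round_seeds[r])
    } else {
      sample_metal_variants(object, best, a, n = n_per_round,
                            seed = round_seeds[r])
    }
    if (!is.null(best)) cand <- c(best, cand)   # elitism: keep the incumbent
    scores <- vapply(cand, function(s) {
      v <- tryCatch(scorer(s, list(topology = topology, round = r)),
                    error = function(e) {
                      warning("scorer failed on a candidate: ",
                              conditionMessage(e), call. = FALSE)
                      NA_real_
                    })
      as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
    ok <- which(is.finite(scores))
    if (length(ok) == 0L) stop("scorer failed on every candidate in round ",
                               r, call. = FALSE)
    o <- ok[order(scores[ok], ok)]
    if (scores[o[1L]] <= best_score) {
      best <- cand[o[1L]]
      best_score <- scores[o[1L]]
    }
    k <- utils::head(o, top_k)
    history[[r]] <- list(iteration = r, seed = round_seeds[r], best = best,
                         best_score = best_score,
                         shortlist = data.frame(sequence = cand[k],
                                                score = scores[k],
                                                row.names = NULL),
                         scores = scores)
  }
  structure(list(best = best, best_score = best_score, history = history,
                 topology = if (inherits(topology, "topology"))
                   unparse_topology(topology) else topology),
            class = "iterative_search")
}

#' @export
print.iterative_search <- function(x, ...) {
  cat("Iterative latent-space search (", length(x$history), " rounds) for topology ",
      x$topology, "\n", sep = "")
  for (h in x$history)
    cat(sprintf("  round %d: best score %.4g (median candidate %.4g)\n",
                h$iteration, h$best_score,
                stats::median(h$scores, na.rm = TRUE)))
  cat("final best score:", x$best_score, "\n")
  cat("final best sequence:", x$best, "\n")
  invisible(x)
}
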