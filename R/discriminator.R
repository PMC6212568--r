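# Multi-label metal-binding discriminator.
#
# Six batch-normalised linear blocks (1024/512/256/128/64/8 by default);
# the last block swaps the rectifier for a sigmoid, yielding one
# independent binding probability per metal. Trained with per-class
# inverse-frequency weighted binary cross-entropy under the same Adam
# settings as the CVAE, a family-disjoint 90/10 validation split, and
# early stopping: the checkpoint with the lowest validation loss is kept,
# not the last one.

.BCE_EPS <- 1e-7

#' Inverse-frequency class weights
#'
#' One weight per metal, proportional to the inverse of the number of
#' training proteins binding it, normalised to average 1 so the overall
#' loss scale is unchanged. Metals with no positive examples are given the
#' weight a single-positive class would get.
#'
#' @param records Records data.frame (training side).
#' @return Named numeric 8-vector.
#' @export
class_weights <- function(records) {
  counts <- pmax(colSums(records[, .metal_cols(), drop = FALSE]), 1L)
  w <- 1 / counts
  w <- w / mean(w)
  stats::setNames(as.numeric(w), metal_order())
}

#' Class-weighted binary cross-entropy
#'
#' \code{sum_m w_m * BCE(pred_m, target_m)} with predictions clamped to
#' \code{[1e-7, 1 - 1e-7]} for stability; the weight scales both the
#' positive and negative terms of its class.
#'
#' @param pred Probability vector of length 8, or an n x 8 matrix.
#' @param target 0/1 vector or matrix conformable with \code{pred}.
#' @param weights Positive 8-vector (default uniform 1s).
#' @return Nonnegative scalar (vector input) or per-row vector.
#' @export
weighted_bce <- function(pred, target, weights = rep(1, 8L)) {
  vec <- is.null(dim(pred))
  if (vec) { pred <- matrix(pred, 1L); target <- matrix(target, 1L) }
  stopifnot(ncol(pred) == length(weights), all(weights > 0))
  p <- pmin(pmax(pred, .BCE_EPS), 1 - .BCE_EPS)
  ll <- -(target * log(p) + (1 - target) * log(1 - p))
  out <- rowSums(.rowmult(ll, weights))
  if (vec) out[[1L]] else out
}

#' Family-disjoint train/validation split
#'
#' Partitions records so that no family straddles the two sides
#' (preventing homology leakage), targeting \code{fraction} of the
#' sequences in validation by greedy packing: families are taken in
#' decreasing size order (seeded shuffle breaking ties) and added to the
#' validation side while they fit under the target. Designated hold-out
#' ids can be forced into validation, dragging their whole family along.
#'
#' @param records Records data.frame; every row needs a nonempty
#'   \code{family} label.
#' @param fraction Target validation fraction of sequences (default 0.1).
#' @param force_validation Ids whose families must land in validation.
#' @param seed Optional integer seed for the tie-breaking shuffle.
#' @return List with character vectors \code{train} and \code{validation}
#'   of record ids.
#' @export
family_split <- function(records, fraction = 0.1, force_validation = NULL,
                         seed = NULL) {
  fam <- records$family
  if (any(is.na(fam) | !nzchar(fam)))
    stop("every record needs a family label", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sizes <- table(fam)
  fams <- sample(names(sizes))                 # seeded tie-break order
  fams <- fams[order(-sizes[fams])]            # stable sort: largest first
  target <- round(fraction * nrow(records))
  val_fams <- unique(fam[records$id %in% force_validation])
  val_n <- sum(sizes[val_fams])
  for (f in setdiff(fams, val_fams)) {
    if (val_n + sizes[[f]] <= target) {
      val_fams <- c(val_fams, f)
      val_n <- val_n + sizes[[f]]
    }
  }
  if (length(val_fams) == 0L)                  # never return an empty side
    val_fams <- fams[length(fams)]
  in_val <- fam %in% val_fams
  list(train = records$id[!in_val], validation = records$id[in_val])
}

.disc_fb <- function(P, stats, X, Tg, w, train = TRUE, want_grads = TRUE) {
  n <- nrow(X)
  fw <- .stack_forward(P, X, stats, train, last_activation = "sigmoid")
  p <- fw$out
  loss <- mean(weighted_bce(p, Tg, w))
  out <- list(loss = loss, pred = p, stats = fw$stats)
  if (!want_grads) return(out)
  # gradient at the final BN output (through the sigmoid) is w * (p - t)/n
  caches <- fw$caches
  caches[[length(caches)]]$act <- "linear"
  dBn <- .rowmult(p - Tg, w) / n
  out$grads <- .stack_backward(P, caches, dBn)$grads
  out
}

#' Train the metal-binding discriminator
#'
#' Fits the multi-label classifier on one-hot sequence tensors, predicting
#' the 8 binding flags. A family-disjoint split (see [family_split()])
#' provides the validation set; after every epoch the validation loss is
#' evaluated and the parameters achieving the minimum are the ones
#' returned (early stopping by checkpointing).
#'
#' @param records Records data.frame with sequences, flags and families.
#' @param hidden Widths of the five hidden blocks (default
#'   \code{c(1024, 512, 256, 128, 64)}); the output block is always 8.
#' @param max_len Maximum sequence length for encoding (default 140).
#' @param fraction Validation fraction (default 0.1).
#' @param force_validation Ids forced into the validation side.
#' @param weighting \code{"inverse"} (default) for inverse-frequency class
#'   weights computed on the training side, or \code{"uniform"}.
#' @param epochs,batch_size,learning_rate,adam_betas Optimiser settings
#'   (defaults as for [cvae()]).
#' @param seed Integer seed; the run is reproducible given it.
#' @param verbose Print losses every 5 epochs.
#' @return Object of class \code{"metal_discriminator"} with the
#'   best-validation \code{params}/\code{stats}, \code{best_epoch}, the
#'   per-epoch \code{trace} (train and validation loss), the
#'   \code{split}, \code{weights} and \code{config}.
#' @export
discriminator <- function(records, hidden = c(1024L, 512L, 256L, 128L, 64L),
                          max_len = 140L, fraction = 0.1,
                          force_validation = NULL,
                          weighting = c("inverse", "uniform"),
                          epochs = 50L, batch_size = 512L,
                          learning_rate = 5e-4, adam_betas = c(0.9, 0.9),
                          seed = 1L, verbose = FALSE) {
  weighting <- match.arg(weighting)
  cl <- match.call()
  set.seed(seed)
  split <- family_split(records, fraction = fraction,
                        force_validation = force_validation)
  tr <- records[records$id %in% split$train, , drop = FALSE]
  va <- records[records$id %in% split$validation, , drop = FALSE]
  if (nrow(tr) == 0L || nrow(va) == 0L)
    stop("family split produced an empty side", call. = FALSE)
  Xtr <- encode_sequences(tr$sequence, max_len = max_len)
  Xva <- encode_sequences(va$sequence, max_len = max_len)
  Ttr <- as.matrix(tr[, .metal_cols()]) * 1.0
  Tva <- as.matrix(va[, .metal_cols()]) * 1.0
  w <- if (weighting == "inverse") class_weights(tr) else
    stats::setNames(rep(1, 8L), metal_order())

  dims <- c(max_len * 22L, hidden, 8L)
  P <- lapply(seq_len(length(dims) - 1L), function(i) .init_lb(dims[i], dims[i + 1L]))
  S <- lapply(dims[-1L], .init_bn_stats)
  opt <- .adam_init(P)

  n <- nrow(Xtr)
  steps <- max(1L, ceiling(n / batch_size))
  trace <- data.frame(epoch = seq_len(epochs), train = NA_real_, val = NA_real_)
  best <- list(loss = Inf, params = P, stats = S, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0L
    for (b in seq_len(steps)) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      if (length(idx) < 2L) next
      fb <- .disc_fb(P, S, Xtr[idx, , drop = FALSE], Ttr[idx, , drop = FALSE],
                     w, train = TRUE)
      if (!is.finite(fb$loss)) stop("non-finite loss at epoch ", ep, call. = FALSE)
      S <- fb$stats
      upd <- .adam_step(P, fb$grads, opt, lr = learning_rate,
                        beta1 = adam_betas[1], beta2 = adam_betas[2])
      P <- upd$params; opt <- upd$state
      tot <- tot + fb$loss; nb <- nb + 1L
    }
    vl <- .disc_fb(P, S, Xva, Tva, w, train = FALSE, want_grads = FALSE)$loss
    trace$train[ep] <- tot / nb
    trace$val[ep] <- vl
    if (vl < best$loss) best <- list(loss = vl, params = P, stats = S, epoch = ep)
    if (verbose && ep %% 5L == 0L)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, tot / nb, vl))
  }
  structure(
    list(params = best$params, stats = best$stats, best_epoch = best$epoch,
         trace = trace, split = split, weights = w,
         config = list(hidden = hidden, max_len = max_len,
                       d_in = max_len * 22L, fraction = fraction,
                       weighting = weighting, batch_size = batch_size,
                       learning_rate = learning_rate,
                       adam_betas = adam_betas, seed = seed),
         call = cl),
    class = "metal_discriminator")
}

#' @export
print.metal_discriminator <- function(x, ...) {
  cat("Metal-binding discriminator (", paste(x$config$hidden, collapse = "-"),
      "-8 )\n", sep = "")
  cat(sprintf("  best validation loss %.4f at epoch %d of %d\n",
              min(x$trace$val), x$best_epoch, nrow(x$trace)))
  cat("  class weights:",
      paste(sprintf("%s=%.2f", names(x$weights), x$weights), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.metal_discriminator <- function(object, ...) {
  structure(list(trace = object$trace, best_epoch = object$best_epoch,
                 weights = object$weights,
                 n_train = length(object$split$train),
                 n_val = length(object$split$validation)),
            class = "summary.metal_discriminator")
}

#' @export
print.summary.metal_discriminator <- function(x, ...) {
  cat("Discriminator:", x$n_train, "training /", x$n_val,
      "validation sequences (family-disjoint)\n")
  cat(sprintf("  early stop at epoch %d (val loss %.4f)\n",
              x$best_epoch, x$trace$val[x$best_epoch]))
  invisible(x)
}

#' Predict metal-binding probabilities
#'
#' @param object A fitted [discriminator()].
#' @param newdata Character vector of sequences or tensor matrix.
#' @param ... Unused.
#' @return n x 8 matrix of probabilities, columns in [metal_order()].
#' @export
predict.metal_discriminator <- function(object, newdata, ...) {
  X <- if (is.character(newdata))
    encode_sequences(newdata, max_len = object$config$max_len)
  else if (is.null(dim(newdata))) matrix(newdata, 1L) else newdata
  if (ncol(X) != object$config$d_in)
    stop("tensor width ", ncol(X), ", model expects ", object$config$d_in,
         call. = FALSE)
  p <- .stack_forward(object$params, X, object$stats, train = FALSE,
                      last_activation = "sigmoid")$out
  colnames(p) <- metal_order()
  p
}

#' Rank candidate sequences by predicted binding of one metal
#'
#' @param object A fitted [discriminator()].
#' @param sequences Character vector of candidates.
#' @param metal Metal name from [metal_order()].
#' @return data.frame with columns \code{sequence}, \code{score} and
#'   \code{input_index}, sorted by descending score; ties keep input
#'   order.
#' @export
rank_candidates <- function(object, sequences, metal) {
  metal <- match.arg(metal, metal_order())
  stopifnot(length(sequences) >= 1L)
  p <- predict(object, sequences)[, metal]
  o <- order(-p, seq_along(p))
  data.frame(sequence = sequences[o], score = p[o], input_index = o,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
plot.metal_discriminator <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$train, tr$val), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "weighted BCE", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
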