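# Conditional variational autoencoder over one-hot protein sequences.
#
# Architecture (all widths configurable, defaults as used for sequence
# generation): encoder MLP of three linear blocks LB(x) = ReLU(BN(Wx+b))
# sized 512/256/128 on the concatenation of the 3080-long sequence tensor
# and the conditioning attribute; affine head for the posterior mean and a
# softplus-affine head for the posterior variance in a 16-dimensional
# latent space; decoder MLP with the block sizes reversed on cbind(z, a),
# finished by a sigmoid affine layer back to 3080. Training minimises
# mean_batch[ BCE(x_hat, x) + burnin * KL(q(z|x,a) || N(0,I)) ] by Adam,
# with the KL weight ramping linearly from 0 to 1 over a burn-in to avoid
# early posterior collapse.

.SIGMA2_FLOOR <- 1e-10

.cvae_init_params <- function(d_in, attr_dim, hidden, latent_dim) {
  enc_dims <- c(d_in + attr_dim, hidden)
  dec_dims <- c(latent_dim + attr_dim, rev(hidden))
  list(
    enc = lapply(seq_along(hidden), function(i) .init_lb(enc_dims[i], enc_dims[i + 1L])),
    mu = .init_dense(hidden[length(hidden)], latent_dim),
    sig = .init_dense(hidden[length(hidden)], latent_dim),
    dec = lapply(seq_along(hidden), function(i) .init_lb(dec_dims[i], dec_dims[i + 1L])),
    out = .init_dense(rev(hidden)[length(hidden)], d_in)
  )
}

.cvae_init_stats <- function(hidden) {
  list(enc = lapply(hidden, .init_bn_stats),
       dec = lapply(rev(hidden), .init_bn_stats))
}

# One full forward + backward pass on a batch. `eps` is the standard-normal
# noise for the reparameterised sample, passed in explicitly so the pass is
# a deterministic function of (params, batch, eps) — which also makes exact
# finite-difference gradient checks possible.
.cvae_fb <- function(P, stats, X, A, burnin, eps, train = TRUE,
                     want_grads = TRUE) {
  n <- nrow(X)
  latent <- ncol(P$mu$W)
  Y <- cbind(X, A)
  enc <- .stack_forward(P$enc, Y, stats$enc, train)
  H <- enc$out
  mu <- .rowadd(H %*% P$mu$W, P$mu$b)
  Sl <- .rowadd(H %*% P$sig$W, P$sig$b)
  sigma2 <- pmax(.softplus(Sl), .SIGMA2_FLOOR)
  sd <- sqrt(sigma2)
  Z <- mu + sd * eps
  Dn <- cbind(Z, A)
  dec <- .stack_forward(P$dec, Dn, stats$dec, train)
  G <- dec$out
  O <- .rowadd(G %*% P$out$W, P$out$b)
  recon_i <- rowSums(.bce_logits(O, X))
  kl_i <- 0.5 * rowSums(mu * mu + sigma2 - 1 - log(sigma2))
  out <- list(total = mean(recon_i) + burnin * mean(kl_i),
              recon = mean(recon_i), kl = mean(kl_i),
              stats = list(enc = enc$stats, dec = dec$stats),
              logits = O, mu = mu, sigma2 = sigma2, z = Z)
  if (!want_grads) return(out)

  dO <- (.sigmoid(O) - X) / n
  g_out <- list(W = crossprod(G, dO), b = colSums(dO))
  dG <- tcrossprod(dO, P$out$W)
  dec_b <- .stack_backward(P$dec, dec$caches, dG)
  dZ <- dec_b$dX[, seq_len(latent), drop = FALSE]
  dmu <- dZ + burnin * mu / n
  dsigma2 <- dZ * eps * 0.5 / sd + burnin * 0.5 * (1 - 1 / sigma2) / n
  dSl <- dsigma2 * .sigmoid(Sl)
  g_mu <- list(W = crossprod(H, dmu), b = colSums(dmu))
  g_sig <- list(W = crossprod(H, dSl), b = colSums(dSl))
  dH <- tcrossprod(dmu, P$mu$W) + tcrossprod(dSl, P$sig$W)
  enc_b <- .stack_backward(P$enc, enc$caches, dH)
  out$grads <- list(enc = enc_b$grads, mu = g_mu, sig = g_sig,
                    dec = dec_b$grads, out = g_out)
  out
}

.as_attr_matrix <- function(a, n, attr_dim) {
  if (is.null(dim(a))) a <- matrix(a, nrow = n, ncol = length(a), byrow = TRUE)
  if (ncol(a) != attr_dim)
    stop("attribute has width ", ncol(a), ", model expects ", attr_dim,
         call. = FALSE)
  if (nrow(a) != n) stop("attribute rows do not match inputs", call. = FALSE)
  a
}

.as_x_matrix <- function(x, object) {
  if (is.character(x)) x <- encode_sequences(x, max_len = object$config$max_len)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != object$config$d_in)
    stop("sequence tensor has width ", ncol(x), ", model expects ",
         object$config$d_in, call. = FALSE)
  x
}

#' Fit a conditional variational autoencoder to protein sequences
#'
#' Trains a CVAE whose encoder and decoder are both conditioned on an
#' attribute vector: the 8-metal binding flags (\code{mode = "metal"}) or
#' the 1265-long one-hot grammar encoding of a topology string
#' (\code{mode = "grammar"}). Sequences are one-hot encoded over the
#' 22-symbol alphabet to \code{max_len * 22} entries. The objective is the
#' negative ELBO — summed binary cross-entropy between the sigmoid output
#' and the one-hot input plus the KL divergence of the Gaussian posterior
#' from the standard-normal prior — averaged over the batch, with the KL
#' term multiplied by a burn-in factor ramping linearly from 0 to 1 over
#' \code{kl_burnin} optimiser steps. Optimisation is Adam with both
#' moment-decay constants 0.9 and learning rate 5e-4 by default.
#'
#' Training stops at \code{epochs}, or earlier once the relative
#' improvement of the epoch-mean loss stays below \code{tol} for
#' \code{patience} consecutive epochs after the burn-in has completed. A
#' non-finite loss aborts with the offending epoch.
#'
#' @param data Either a records data.frame with columns \code{sequence}
#'   plus the attribute columns (metal flags, or \code{topology}; see
#'   [generate_dataset()]), or a list with elements \code{x} (n x
#'   \code{max_len*22} tensor matrix) and \code{attr} (n x attribute
#'   matrix).
#' @param mode \code{"metal"} (8-flag conditioning) or \code{"grammar"}
#'   (1265-long rule-encoding conditioning).
#' @param max_len Maximum sequence length (default 140).
#' @param latent_dim Latent dimensionality (default 16).
#' @param hidden Encoder MLP widths, reversed for the decoder (default
#'   \code{c(512, 256, 128)}).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (default 512).
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param adam_betas The two Adam moment-decay constants (default
#'   \code{c(0.9, 0.9)}).
#' @param kl_burnin Number of optimiser steps over which the KL weight
#'   ramps from 0 to 1; default is 100 epochs' worth of steps.
#' @param tol,patience Convergence: stop when the relative epoch-loss
#'   improvement is below \code{tol} for \code{patience} consecutive
#'   epochs (checked after burn-in completes).
#' @param seed Integer seed controlling initialisation, shuffling and the
#'   reparameterisation noise; the run is fully reproducible given it.
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class \code{"cvae"}: a list with the fitted
#'   \code{params}, batch-norm running \code{stats}, \code{config},
#'   \code{trace} (per-epoch data.frame with columns epoch, total, recon,
#'   kl, burnin) and the \code{alphabet} and metal order it was trained
#'   with. Use [predict.cvae()] to encode/reconstruct, [simulate.cvae()],
#'   [sample_metal_variants()] and [sample_from_topology()] to generate.
#' @examples
#' \donttest{
#' recs <- generate_dataset(n_families = 4, seed = 1, max_len = 40)
#' fit <- cvae(recs, mode = "metal", max_len = 40, hidden = c(64, 32, 16),
#'             epochs = 3, batch_size = 64, seed = 1)
#' print(fit)
#' }
#' @export
cvae <- function(data, mode = c("metal", "grammar"), max_len = 140L,
                 latent_dim = 16L, hidden = c(512L, 256L, 128L),
                 epochs = 300L, batch_size = 512L, learning_rate = 5e-4,
                 adam_betas = c(0.9, 0.9), kl_burnin = NULL, tol = 1e-4,
                 patience = 10L, seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.data.frame(data)) {
    X <- encode_sequences(data$sequence, max_len = max_len)
    A <- build_attributes(data, mode = mode)
  } else if (is.list(data) && !is.null(data$x)) {
    X <- data$x
    A <- data$attr
  } else stop("data must be a records data.frame or list(x, attr)", call. = FALSE)
  n <- nrow(X)
  if (n == 0L) stop("empty training set", call. = FALSE)
  attr_dim <- if (mode == "metal") 8L else 1265L
  if (ncol(A) != attr_dim)
    stop("attribute width ", ncol(A), " does not match mode '", mode, "'",
         call. = FALSE)
  d_in <- max_len * 22L
  if (ncol(X) != d_in) stop("tensor width does not match max_len", call. = FALSE)

  set.seed(seed)
  P <- .cvae_init_params(d_in, attr_dim, hidden, latent_dim)
  S <- .cvae_init_stats(hidden)
  opt <- .adam_init(P)
  steps_per_epoch <- max(1L, ceiling(n / batch_size))
  if (is.null(kl_burnin)) kl_burnin <- 100L * steps_per_epoch

  trace <- vector("list", epochs)
  step <- 0L
  best <- Inf
  stall <- 0L
  last_epoch <- epochs
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- rec <- klv <- 0
    nb <- 0L
    burnin_start <- min(1, step / kl_burnin)
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      if (length(idx) < 2L) next  # batch-norm needs at least two samples
      burnin <- min(1, step / kl_burnin)
      eps <- matrix(stats::rnorm(length(idx) * latent_dim), length(idx), latent_dim)
      fb <- .cvae_fb(P, S, X[idx, , drop = FALSE], A[idx, , drop = FALSE],
                     burnin, eps, train = TRUE)
      if (!is.finite(fb$total))
        stop("non-finite loss at epoch ", ep, call. = FALSE)
      S <- fb$stats
      upd <- .adam_step(P, fb$grads, opt, lr = learning_rate,
                        beta1 = adam_betas[1], beta2 = adam_betas[2])
      P <- upd$params
      opt <- upd$state
      step <- step + 1L
      tot <- tot + fb$total; rec <- rec + fb$recon; klv <- klv + fb$kl
      nb <- nb + 1L
    }
    trace[[ep]] <- data.frame(epoch = ep, total = tot / nb, recon = rec / nb,
                              kl = klv / nb, burnin = burnin_start)
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: loss %.3f (recon %.3f, kl %.3f)",
                      ep, tot / nb, rec / nb, klv / nb))
    if (step >= kl_burnin) {  # convergence only judged once KL fully on
      cur <- tot / nb
      if (is.finite(best) && (best - cur) / abs(best) < tol) stall <- stall + 1L
      else stall <- 0L
      best <- min(best, cur)
      if (stall >= patience) { last_epoch <- ep; break }
    }
  }
  structure(
    list(params = P, stats = S,
         config = list(mode = mode, max_len = max_len, d_in = d_in,
                       attr_dim = attr_dim, latent_dim = latent_dim,
                       hidden = hidden, learning_rate = learning_rate,
                       batch_size = batch_size, adam_betas = adam_betas,
                       kl_burnin = kl_burnin, tol = tol, patience = patience,
                       seed = seed),
         trace = do.call(rbind, trace[seq_len(last_epoch)]),
         alphabet = aa_alphabet(), metals = metal_order(), call = cl),
    class = "cvae")
}

#' Encode sequences to their latent posterior
#'
#' Runs the inference network in evaluation mode (batch normalisation uses
#' the accumulated running statistics, so a single sequence encodes
#' deterministically) and returns the Gaussian posterior parameters.
#'
#' @param object A fitted [cvae()] model.
#' @param x Sequences: a character vector, an encoded tensor vector, or a
#'   tensor matrix (one row per sequence).
#' @param a Conditioning attribute: a single attribute vector (recycled
#'   across rows) or a matrix with one row per sequence.
#' @return An object of class \code{"cvae_posterior"}: list with matrices
#'   \code{mu} and \code{sigma2} (rows = inputs, columns = latent
#'   dimensions); \code{sigma2} is strictly positive.
#' @export
cvae_encode <- function(object, x, a) {
  stopifnot(inherits(object, "cvae"))
  X <- .as_x_matrix(x, object)
  A <- .as_attr_matrix(a, nrow(X), object$config$attr_dim)
  enc <- .stack_forward(object$params$enc, cbind(X, A), object$stats$enc,
                        train = FALSE)
  H <- enc$out
  mu <- .rowadd(H %*% object$params$mu$W, object$params$mu$b)
  sigma2 <- pmax(.softplus(.rowadd(H %*% object$params$sig$W, object$params$sig$b)),
                 .SIGMA2_FLOOR)
  structure(list(mu = mu, sigma2 = sigma2), class = "cvae_posterior")
}

#' @export
print.cvae_posterior <- function(x, ...) {
  cat("Latent posterior for", nrow(x$mu), "input(s),",
      ncol(x$mu), "latent dimensions\n")
  cat("  |mu| range:", sprintf("%.3f..%.3f", min(abs(x$mu)), max(abs(x$mu))),
      " sigma2 range:", sprintf("%.3g..%.3g", min(x$sigma2), max(x$sigma2)), "\n")
  invisible(x)
}

#' Reparameterised draw from a latent posterior
#'
#' \code{z = mu + sqrt(sigma2) * eps} with standard-normal \code{eps} — the
#' reparameterisation trick that keeps sampling differentiable during
#' training, exposed here for generation.
#'
#' @param posterior A \code{"cvae_posterior"} (or list with \code{mu},
#'   \code{sigma2}).
#' @param n Number of draws \emph{per posterior row}.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return Matrix of latent vectors with \code{n * nrow(mu)} rows.
#' @export
reparameterize <- function(posterior, n = 1L, seed = NULL) {
  mu <- posterior$mu
  sigma2 <- posterior$sigma2
  if (is.null(dim(mu))) { mu <- matrix(mu, 1L); sigma2 <- matrix(sigma2, 1L) }
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu_r <- mu[rep(seq_len(nrow(mu)), each = n), , drop = FALSE]
  s_r <- sqrt(sigma2[rep(seq_len(nrow(mu)), each = n), , drop = FALSE])
  eps <- matrix(stats::rnorm(length(mu_r)), nrow(mu_r), ncol(mu_r))
  mu_r + s_r * eps
}

#' Decode latent vectors to soft sequence tensors
#'
#' Runs the generative network in evaluation mode: the latent vector is
#' concatenated with the attribute, passed through the decoder MLP and the
#' sigmoid output layer. Entries of the result lie strictly in (0, 1);
#' apply [decode_sequences()] for amino-acid strings.
#'
#' @param object A fitted [cvae()] model.
#' @param z Latent vector (length \code{latent_dim}) or matrix of latent
#'   rows.
#' @param a Attribute vector or matrix (recycled across rows if a vector).
#' @return Soft tensor matrix, one row per latent input.
#' @export
cvae_decode <- function(object, z, a) {
  stopifnot(inherits(object, "cvae"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != object$config$latent_dim)
    stop("latent width ", ncol(z), ", model expects ",
         object$config$latent_dim, call. = FALSE)
  A <- .as_attr_matrix(a, nrow(z), object$config$attr_dim)
  dec <- .stack_forward(object$params$dec, cbind(z, A), object$stats$dec,
                        train = FALSE)
  .sigmoid(.rowadd(dec$out %*% object$params$out$W, object$params$out$b))
}

#' KL divergence of a Gaussian posterior from the standard-normal prior
#'
#' Closed form per posterior row:
#' \deqn{KL = \tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - 1 - \ln \sigma_d^2),}
#' nonnegative, and zero exactly when \code{mu = 0}, \code{sigma2 = 1}.
#'
#' @param posterior A \code{"cvae_posterior"} or list with \code{mu} and
#'   \code{sigma2} (vectors or matrices).
#' @return Numeric vector, one KL value per posterior row.
#' @export
kl_divergence <- function(posterior) {
  mu <- posterior$mu
  sigma2 <- posterior$sigma2
  if (is.null(dim(mu))) { mu <- matrix(mu, 1L); sigma2 <- matrix(sigma2, 1L) }
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive", call. = FALSE)
  0.5 * rowSums(mu * mu + sigma2 - 1 - log(sigma2))
}

#' Evaluate the (negative) ELBO on given sequences
#'
#' Computes the training objective in evaluation mode: per-sequence summed
#' binary cross-entropy between the decoded soft tensor and the one-hot
#' input, the closed-form KL to the prior, and their burn-in-weighted
#' total, averaged over the inputs.
#'
#' @inheritParams cvae_encode
#' @param burnin_factor KL weight in \code{[0, 1]}.
#' @param seed Seed for the single reparameterised sample.
#' @return List with \code{total}, \code{reconstruction} and \code{kl}
#'   (batch means); \code{total == reconstruction + burnin_factor * kl}.
#' @export
elbo_loss <- function(object, x, a, burnin_factor = 1, seed = NULL) {
  stopifnot(inherits(object, "cvae"),
            burnin_factor >= 0, burnin_factor <= 1)
  X <- .as_x_matrix(x, object)
  A <- .as_attr_matrix(a, nrow(X), object$config$attr_dim)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  eps <- matrix(stats::rnorm(nrow(X) * object$config$latent_dim),
                nrow(X), object$config$latent_dim)
  fb <- .cvae_fb(object$params, object$stats, X, A, burnin_factor, eps,
                 train = FALSE, want_grads = FALSE)
  list(total = fb$total, reconstruction = fb$recon, kl = fb$kl)
}

# ---- standard S3 methods ---------------------------------------------------

#' @export
print.cvae <- function(x, ...) {
  cfg <- x$config
  cat("Conditional VAE for protein sequences\n")
  cat("  conditioning  :", cfg$mode,
      sprintf("(attribute width %d)\n", cfg$attr_dim))
  cat("  sequence size :", cfg$max_len, "x 22 =", cfg$d_in, "\n")
  cat("  encoder MLP   :", paste(cfg$hidden, collapse = "-"),
      "-> latent", cfg$latent_dim, "\n")
  if (!is.null(x$trace)) {
    fin <- x$trace[nrow(x$trace), ]
    cat(sprintf("  trained %d epochs; final loss %.3f (recon %.3f, kl %.3f)\n",
                fin$epoch, fin$total, fin$recon, fin$kl))
  }
  invisible(x)
}

#' @export
summary.cvae <- function(object, ...) {
  n_par <- sum(unlist(.tree_map(length, object$params)))
  out <- list(config = object$config, n_parameters = n_par,
              trace = object$trace)
  class(out) <- "summary.cvae"
  out
}

#' @export
print.summary.cvae <- function(x, ...) {
  cfg <- x$config
  cat("Conditional VAE (", cfg$mode, " mode)\n", sep = "")
  cat("  parameters:", format(x$n_parameters, big.mark = ","), "\n")
  cat("  latent dim:", cfg$latent_dim, " hidden:",
      paste(cfg$hidden, collapse = "/"), "\n")
  cat("  adam lr", cfg$learning_rate, "betas",
      paste(cfg$adam_betas, collapse = "/"),
      "batch", cfg$batch_size, "kl burn-in", cfg$kl_burnin, "steps\n")
  if (!is.null(x$trace)) {
    fin <- x$trace[nrow(x$trace), ]
    cat(sprintf("  epochs run: %d  final: total %.3f recon %.3f kl %.3f\n",
                fin$epoch, fin$total, fin$recon, fin$kl))
  }
  invisible(x)
}

#' @export
coef.cvae <- function(object, ...) object$params

#' Reconstruct or embed sequences with a fitted CVAE
#'
#' @param object A fitted [cvae()] model.
#' @param newdata Character vector of sequences, tensor matrix, or records
#'   data.frame (attributes are then built from it in the model's mode).
#' @param attributes Attribute vector/matrix; required unless
#'   \code{newdata} is a records data.frame.
#' @param type \code{"sequence"} (default) decodes the reconstruction back
#'   to amino-acid strings; \code{"tensor"} returns the soft output
#'   tensor; \code{"latent"} returns the latent posterior.
#' @param sample If \code{TRUE} use a reparameterised latent sample,
#'   otherwise the posterior mean (deterministic).
#' @param seed Seed used when \code{sample = TRUE}.
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.cvae <- function(object, newdata, attributes = NULL,
                         type = c("sequence", "tensor", "latent"),
                         sample = FALSE, seed = NULL, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    attributes <- build_attributes(newdata, mode = object$config$mode)
    newdata <- newdata$sequence
  }
  if (is.null(attributes))
    stop("attributes must be supplied (or newdata be a records data.frame)",
         call. = FALSE)
  post <- cvae_encode(object, newdata, attributes)
  if (type == "latent") return(post)
  z <- if (sample) reparameterize(post, seed = seed) else post$mu
  A <- .as_attr_matrix(attributes, nrow(z), object$config$attr_dim)
  ten <- cvae_decode(object, z, A)
  if (type == "tensor") ten else decode_sequences(ten)
}

#' Generate sequences from a fitted CVAE
#'
#' Draws latent vectors from the standard-normal prior (or, if
#' \code{input} is given, from the posterior of that sequence) and decodes
#' them under \code{attribute}. This is the S3 face of
#' [sample_from_topology()] / [sample_metal_variants()].
#'
#' @param object A fitted [cvae()] model.
#' @param nsim Number of sequences to generate.
#' @param seed Optional integer seed.
#' @param attribute Conditioning attribute vector (metal flags, or a
#'   topology string / \code{"topology"} object / 1265 encoding in grammar
#'   mode).
#' @param input Optional input sequence for posterior resampling.
#' @param ... Unused.
#' @return Character vector of \code{nsim} generated sequences.
#' @export
simulate.cvae <- function(object, nsim = 1L, seed = NULL, attribute,
                          input = NULL, ...) {
  a <- .resolve_attribute(object, attribute)
  if (is.null(input)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    z <- matrix(stats::rnorm(nsim * object$config$latent_dim),
                nsim, object$config$latent_dim)
    decode_sequences(cvae_decode(object, z, a))
  } else {
    sample_metal_variants(object, input, a, n = nsim, seed = seed)
  }
}

# attribute in user-facing form -> numeric vector of the model's width
.resolve_attribute <- function(object, attribute) {
  if (inherits(attribute, "topology") ||
      (is.character(attribute) && length(attribute) == 1L)) {
    if (object$config$mode != "grammar")
      stop("topology attribute supplied to a metal-mode model", call. = FALSE)
    t <- if (inherits(attribute, "topology")) attribute else parse_topology(attribute)
    return(encode_rules(derive_rules(t)))
  }
  if (is.numeric(attribute)) {
    if (is.null(dim(attribute)) && length(attribute) == object$config$attr_dim)
      return(attribute)
    if (!is.null(dim(attribute)) && ncol(attribute) == object$config$attr_dim)
      return(attribute)
  }
  stop("cannot interpret attribute for mode '", object$config$mode, "'",
       call. = FALSE)
}

#' Plot the training trace of a CVAE
#'
#' @param x A fitted [cvae()] model.
#' @param which \code{"loss"} draws the per-epoch total/reconstruction/KL
#'   curves.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cvae <- function(x, which = "loss", ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$total, tr$recon, tr$kl), type = "l",
                    lty = 1, col = c("black", "steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "reconstruction", "KL"),
                   col = c("black", "steelblue", "firebrick"), lty = 1,
                   bty = "n")
  invisible(x)
}
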