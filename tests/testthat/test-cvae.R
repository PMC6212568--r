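test_that("encoding is deterministic with strictly positive variance", {
  fit <- fix_cvae_tiny()
  set.seed(8)
  seqs <- vapply(1:5, function(i) random_aa_string(20), character(1))
  a <- matrix(0, 5L, 8L)
  p1 <- cvae_encode(fit, seqs, a)
  p2 <- cvae_encode(fit, seqs, a)
  expect_identical(p1, p2)
  expect_true(all(p1$sigma2 > 0))
  # dimension mismatches are caught
  expect_error(cvae_encode(fit, seqs, matrix(0, 5L, 7L)), "width")
})

test_that("a zero-weight encoder returns its biases", {
  fit <- fix_cvae_tiny()
  set.seed(9)
  fit$params <- pcvae:::.tree_map(function(x) x * 0, fit$params)
  fit$params$mu$b <- rnorm(4)
  fit$params$sig$b <- rnorm(4)
  for (s in c("ACDEF", "WWWW", "")) {
    p <- cvae_encode(fit, s, rep(0, 8))
    expect_equal(as.numeric(p$mu), fit$params$mu$b)
    expect_equal(as.numeric(p$sigma2), pcvae:::.softplus(fit$params$sig$b),
                 tolerance = 1e-12)
  }
})

test_that("reparameterisation is z = mu + sd * eps", {
  post <- list(mu = matrix(c(1, -2, 0.5, 3), 1L), sigma2 = matrix(rep(0, 4), 1L))
  expect_equal(reparameterize(post, seed = 1), post$mu)   # zero-noise limit
  post$sigma2 <- matrix(rep(2, 4), 1L)
  expect_identical(reparameterize(post, n = 10L, seed = 3),
                   reparameterize(post, n = 10L, seed = 3))
  # sample mean within 4 sd / sqrt(n) of mu, per coordinate
  z <- reparameterize(post, n = 1e5L, seed = 4)
  tol <- 4 * sqrt(2) / sqrt(1e5)
  expect_true(all(abs(colMeans(z) - as.numeric(post$mu)) < tol))
})

test_that("decoding yields sigmoid-range tensors of the right width", {
  fit <- fix_cvae_tiny()
  z <- matrix(rnorm(3 * 4), 3L)
  out <- cvae_decode(fit, z, rep(0, 8))
  expect_equal(dim(out), c(3L, 24L * 22L))
  expect_true(all(out > 0 & out < 1))
  expect_true(all(nchar(decode_sequences(out)) <= 24L))
  expect_error(cvae_decode(fit, matrix(0, 1L, 7L), rep(0, 8)), "latent")
})

test_that("closed-form KL matches quadrature and Monte-Carlo oracles", {
  # prior match
  expect_equal(kl_divergence(list(mu = rep(0, 16), sigma2 = rep(1, 16))), 0)
  # 1-dim, mu=1, sigma2=1: numerical integration of q log(q/p)
  q <- function(z) dnorm(z, 1, 1)
  oracle <- integrate(function(z) q(z) * (dnorm(z, 1, 1, log = TRUE) -
                                            dnorm(z, 0, 1, log = TRUE)),
                      -10, 10)$value
  expect_equal(kl_divergence(list(mu = 1, sigma2 = 1)), oracle,
               tolerance = 1e-8)
  expect_equal(oracle, 0.5, tolerance = 1e-8)
  # Monte-Carlo estimator on random posteriors, 3 SE at 1e5 draws
  set.seed(10)
  for (i in 1:20) {
    mu <- rnorm(4); sigma2 <- exp(rnorm(4, 0, 0.5))
    z <- matrix(rnorm(1e5 * 4), ncol = 4)
    z <- sweep(sweep(z, 2, sqrt(sigma2), "*"), 2, mu, "+")
    lq <- rowSums(sapply(1:4, function(d) dnorm(z[, d], mu[d], sqrt(sigma2[d]),
                                                log = TRUE)))
    lp <- rowSums(dnorm(z, log = TRUE))
    mc <- mean(lq - lp)
    se <- sd(lq - lp) / sqrt(1e5)
    expect_lt(abs(kl_divergence(list(mu = mu, sigma2 = sigma2)) - mc), 3 * se)
  }
  expect_error(kl_divergence(list(mu = 0, sigma2 = 0)), "positive")
})

test_that("the ELBO decomposes as reconstruction plus weighted KL", {
  fit <- fix_cvae_tiny()
  set.seed(11)
  seqs <- vapply(1:4, function(i) random_aa_string(15), character(1))
  a <- matrix(rbinom(32, 1, 0.3), 4L)
  l0 <- elbo_loss(fit, seqs, a, burnin_factor = 0, seed = 5)
  l1 <- elbo_loss(fit, seqs, a, burnin_factor = 1, seed = 5)
  lh <- elbo_loss(fit, seqs, a, burnin_factor = 0.5, seed = 5)
  expect_equal(l0$total, l0$reconstruction)           # KL off at burn-in 0
  expect_equal(l1$total, l1$reconstruction + l1$kl)
  expect_equal(lh$total, lh$reconstruction + 0.5 * lh$kl)
  expect_gte(l1$total, l0$total)                      # KL is nonnegative
})

test_that("training is reproducible and converges on a small family", {
  recs <- generate_dataset(n_families = 2L, n_binding = 1L, n_homologues = 8L,
                           max_len = 24L, seed = 3)
  args <- list(recs, mode = "metal", max_len = 24L, hidden = c(32L, 16L, 8L),
               latent_dim = 4L, epochs = 5L, batch_size = 16L,
               kl_burnin = 20L, seed = 6)
  f1 <- do.call(cvae, args)
  f2 <- do.call(cvae, args)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params, f2$params)
  # burn-in factor ramps from 0 to 1
  expect_equal(f1$trace$burnin[1L], 0)
  expect_true(all(diff(f1$trace$burnin) >= 0))
})

test_that("moderate training reaches most of the long-run memorisation", {
  specs <- lapply(1:4, function(i)
    family_spec(sprintf("m%02d", i), length = 28L, n_homologues = 49L,
                conservation = 0.85))
  set.seed(12)
  recs <- do.call(rbind, lapply(specs, generate_family))
  fit_short <- cvae(list(x = encode_sequences(recs$sequence, 30L),
                         attr = matrix(0, nrow(recs), 8L)),
                    mode = "metal", max_len = 30L, hidden = c(64L, 32L, 16L),
                    epochs = 60L, batch_size = 64L, kl_burnin = 24L, seed = 1)
  fit_long <- cvae(list(x = encode_sequences(recs$sequence, 30L),
                        attr = matrix(0, nrow(recs), 8L)),
                   mode = "metal", max_len = 30L, hidden = c(64L, 32L, 16L),
                   epochs = 300L, batch_size = 64L, kl_burnin = 24L, seed = 1)
  idx <- seq(1L, nrow(recs), by = 5L)
  ident <- function(fit) {
    out <- predict(fit, recs$sequence[idx], matrix(0, length(idx), 8L))
    mean(mapply(sequence_identity, recs$sequence[idx], out))
  }
  expect_gte(ident(fit_short), 0.9 * ident(fit_long))
  # epoch-mean loss decreases over the long run
  tr <- fit_long$trace$total
  expect_lt(mean(tail(tr, 10)), mean(head(tr, 10)))
})

test_that("a 2-dimensional latent space clusters families", {
  recs <- fix_dataset()
  fit2 <- cvae(recs, mode = "metal", max_len = 60L, hidden = c(128L, 64L, 32L),
               latent_dim = 2L, epochs = 30L, batch_size = 256L,
               kl_burnin = 80L, seed = 4)
  sub <- recs[recs$provenance == "homologue", ]
  sub <- sub[seq(1L, nrow(sub), by = 12L), ]
  post <- cvae_encode(fit2, sub$sequence, build_attributes(sub, "metal"))
  D <- as.matrix(dist(post$mu))
  same <- outer(sub$family, sub$family, "==") & upper.tri(D)
  diff <- (!outer(sub$family, sub$family, "==")) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})
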