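# Shared fixtures. Trained models are expensive, so they are built once on
# first use and cached for the whole test run. All fixture seeds and sizes
# are fixed: they define the desk-scale study conditions, not tuning knobs.

.fixtures <- new.env(parent = emptyenv())

.fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# ~2000 sequences: 24 families (16 metal-binding), 50 homologues each,
# sequences up to 60 residues, plus negative twins
fix_dataset <- function() .fixture("dataset", function() generate_dataset(seed = 11))

# metal-conditioned CVAE trained to convergence at reduced widths
fix_cvae_metal <- function() .fixture("cvae_metal", function() {
  cvae(fix_dataset(), mode = "metal", max_len = 60L, hidden = c(256L, 128L, 64L),
       epochs = 250L, batch_size = 256L, kl_burnin = 80L, seed = 7)
})

# the planted tripeptide motif of each metal, as used by the generator
metal_motifs <- c(Fe = "HEH", Zn = "CHC", Ca = "DND", Na = "DGD",
                  Cu = "HMH", Mg = "DED", Cd = "CCC", Ni = "HTH")

# grammar-conditioned CVAE on the positive records (all carry topologies)
fix_cvae_grammar <- function() .fixture("cvae_grammar", function() {
  recs <- fix_dataset()
  cvae(recs[recs$provenance != "negative", ], mode = "grammar", max_len = 60L,
       hidden = c(128L, 64L, 32L), epochs = 50L, batch_size = 256L,
       kl_burnin = 50L, seed = 3)
})

# discriminator dataset: more, smaller families so every metal has held-out
# positives under a family-disjoint split
fix_disc_dataset <- function() .fixture("disc_dataset", function() {
  generate_dataset(n_families = 48L, n_binding = 40L, n_homologues = 10L,
                   seed = 11)
})

fix_discriminator <- function() .fixture("discriminator", function() {
  recs <- fix_disc_dataset()
  force_ids <- vapply(metal_order(), function(m)
    recs$id[recs[[tolower(m)]] == 1L & recs$provenance == "native"][1L],
    character(1))
  discriminator(recs, hidden = c(256L, 128L, 64L, 32L, 16L), max_len = 60L,
                fraction = 0.2, force_validation = force_ids,
                epochs = 200L, batch_size = 128L, seed = 5)
})

# tiny fitted model for unit tests of the model surface (shape/determinism
# checks, not learning quality)
fix_cvae_tiny <- function() .fixture("cvae_tiny", function() {
  recs <- generate_dataset(n_families = 3L, n_binding = 2L, n_homologues = 5L,
                           max_len = 24L, seed = 2)
  cvae(recs, mode = "metal", max_len = 24L, hidden = c(32L, 16L, 8L),
       latent_dim = 4L, epochs = 3L, batch_size = 16L, kl_burnin = 10L,
       seed = 2)
})

# rank-statistic AUROC
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_aa_string <- function(n) {
  paste(sample(aa_alphabet()[1:20], n, replace = TRUE), collapse = "")
}
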