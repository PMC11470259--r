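# Small programmatic fixtures shared across test files.

# a hand-built cohort: `nb` bags across `sites`, P patches, D features
tiny_cohort <- function(n_slides = 4L, P = 6L, D = 4L, sites = c("A", "B"),
                        seed = 1L, attrs = NULL) {
  set.seed(seed)
  bags <- lapply(seq_len(n_slides), function(s) {
    patch_bag(sprintf("s%02d", s), sites[((s - 1L) %% length(sites)) + 1L],
              matrix(rnorm(P * D), P, D),
              coords = cbind((seq_len(P) - 1L) %/% 3L,
                             (seq_len(P) - 1L) %% 3L))
  })
  att <- data.frame(slide_id = sprintf("s%02d", seq_len(n_slides)),
                    stringsAsFactors = FALSE)
  if (!is.null(attrs)) for (nm in names(attrs)) att[[nm]] <- attrs[[nm]]
  cohort(bags, att)
}

# separable two-class bag classification problem: class 2 bags get a strong
# mean shift on the first half of the features
separable_cohort <- function(n_per_class = 20L, P = 30L, D = 8L,
                             shift = 3, seed = 1L) {
  sh <- matrix(0, 2, D)
  sh[2, seq_len(D / 2)] <- shift
  cfg <- simulation_config(
    n_sites = 2, slides_per_site = n_per_class, patches_per_slide = P,
    n_features = D, additive_prior = list(mu = c(0, 0), tau2 = c(0, 0)),
    attributes = list(attribute_spec("lab", 2, sh, rho = 0)),
    seed = seed)
  simulate_cohort(cfg)$cohort
}

# quick A-MIL config for tests (small net, few epochs, hot learning rate)
fast_amil <- function(D, C, epochs = 12L, seed = 1L)
  amil_config(D, C, embed_dim = 32L, attn_dim = 16L, max_epochs = epochs,
              patience = epochs, batch_size = 16L, max_lr = 1e-3,
              seed = seed)
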