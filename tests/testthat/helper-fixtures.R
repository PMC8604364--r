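# Small in-code fixtures shared across tests.

# A tiny complete dataset: 2 subjects x 3 times x 2 responses.
tiny_dataset <- function() {
  longitudinal_dataset(
    subject = rep(c("a", "b"), each = 3),
    time = rep(c("t0", "t1", "t2"), 2),
    group = rep(c("ctrl", "trt"), each = 3),
    responses = cbind(m1 = c(1, 2, 3, 4, 5, 6),
                      m2 = c(6, 5, 4, 3, 2, 1))
  )
}

# Balanced complete two-group data from the generative model.
balanced_sim <- function(I_per_group = 20, K = 3, J = 2,
                         sigma_u = 1, sigma_e = 1, seed = 42,
                         group_coding = coding_scheme("reference", "g1"),
                         B = NULL) {
  H <- 2
  p <- 1 + (K - 1) + 1 + (K - 1)
  if (is.null(B)) {
    set.seed(seed + 1000)
    B <- matrix(stats::rnorm(p * J), p, J)
  }
  cfg <- simulation_config(
    subjects_per_group = rep(I_per_group, H), K = K, J = J, B_true = B,
    sigma_u = sigma_u, sigma_e = sigma_e, group_coding = group_coding
  )
  generate_dataset(cfg, seed = seed)
}

# Identity resampler: every subject drawn exactly once.
identity_resampler <- function(subjects_by_group) {
  unlist(subjects_by_group, use.names = FALSE)
}
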