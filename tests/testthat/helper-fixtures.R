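# Shared fixtures, all built in code.

# A 21-point observed/predicted pair constructed numerically so that its
# external-validation statistics reproduce, at reporting precision, the
# published checklist values r2 = 0.923, (r2-r0_2)/r2 = 0.00062,
# (r2-r0'_2)/r2 = 0.00227, k = 1.0015, k' = 0.982.
gt_reference_pair <- function() {
  list(
    obs = seq(0.5, 7.0, length.out = 21),
    pred = c(0.7834752857, 0.1870540395, 1.660052101, 1.518717197,
             2.313495259, 2.641037296, 2.888483582, 2.121457246,
             2.972218941, 3.902782145, 2.965944641, 3.558159177,
             4.763489077, 5.185701487, 5.228532343, 4.45400608,
             4.590072169, 6.878886445, 6.30481207, 6.524364837,
             6.735175864))
}

# random full-rank regression problem with planted linear signal
planted_linear <- function(n, p, beta, noise_sd, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("d", seq_len(p))
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

# a synthetic study with independent descriptors (one column per block) and
# noise at a fixed fraction of the planted signal SD
independent_study <- function(n, p, noise_frac, seed) {
  base <- synthetic_spec(n_compounds = n, n_descriptors = p, n_blocks = p,
                         n_constant = 0L, n_near_constant = 0L,
                         n_missing = 0L, n_discordant = 0L,
                         noise_sd = 0, seed = seed)
  sig <- make_study(base)$truth$signal_sd
  base$noise_sd <- noise_frac * sig
  make_study(base)
}
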