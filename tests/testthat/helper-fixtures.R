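# Build a noiseless (or noisy) profile directly from known parameters.
profile_from_params <- function(params, times = seq(0, 21, by = 3),
                                id = "sim", noise_cv = 0) {
  mu <- evaluate_model(params, times)
  if (noise_cv > 0) mu <- pmax(mu * (1 + rnorm(length(times), 0, noise_cv)), 0)
  sampling_profile(id, times, mu)
}

random_valid_params <- function(b1 = runif(1, 0, 20), b2 = runif(1, 40, 250),
                                b3 = runif(1, 0, 24), b4 = runif(1, 0.5, 11.5)) {
  secretion_params(b1, b2, b3, b4)
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# Independent brute-force oracle for the exact two-sided Mann-Whitney p:
# enumerate every assignment of the pooled values into groups (tie-free).
brute_force_mw <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  min(2 * min(mean(us <= u_obs), mean(us >= u_obs)), 1)
}
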