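# shared fixtures, built once per test run

.fixtures <- new.env()

fix <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small three-cluster Friedman benchmark (fast hierarchy tests)
sim_small <- function() fix("sim_small", function() {
  simulate_hc_dataset(sim_config(n_samples = 360, seed = 11))
})

# the paper-sized benchmark (used by the acceptance tests)
sim_default <- function(seed) {
  simulate_hc_dataset(sim_config(seed = seed))
}

# two far-apart Gaussian blobs in 2 dimensions
two_blobs <- function(n_per = 50, sep = 50, seed = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  list(X = X, labels = rep(1:2, each = n_per))
}

# spectra fixture with one response-linked peak at 1400 cm-1
spectra_fixture <- function(noise_sd = 0, seed = 3) {
  make_synthetic_spectra(n_samples = 40, n_replicates = 3,
                         noise_sd = noise_sd, seed = seed)
}

# plain Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# independent straight-line Friedman formulas (oracle re-implementation)
friedman_oracle <- function(U, variant) {
  apply(U, 1, function(u) {
    if (variant == 1) {
      10 * sin(pi * u[1] * u[2]) + 20 * (u[3] - 0.5)^2 + 10 * u[4] + 5 * u[5]
    } else if (variant == 2) {
      sqrt(u[1]^2 + (u[2] * u[3] - 1 / (u[2] * u[4]))^2)
    } else {
      atan((u[2] * u[3] - 1 / (u[2] * u[4])) / u[1])
    }
  })
}

# squared distances between row sets (test-side helper)
sq_dist_test <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

# all permutations of 1..k as a matrix (brute-force oracle)
all_perms <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- all_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
}
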