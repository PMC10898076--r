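# Independent oracles used to cross-check the implementation.

# Brute-force time-averaged MSD: explicit enumeration of every overlapping
# displacement pair at each lag.
brute_msd <- function(traj, max_lag_fraction = 1) {
  n <- nrow(traj)
  dt <- mean(diff(traj$t_hours))
  k_max <- max(1L, floor(max_lag_fraction * (n - 1L)))
  out <- data.frame(lag_h = numeric(0), msd_um2 = numeric(0),
                    n_pairs = integer(0))
  for (k in seq_len(k_max)) {
    acc <- c()
    for (i in seq_len(n - k)) {
      acc <- c(acc, (traj$x_um[i + k] - traj$x_um[i])^2 +
                 (traj$y_um[i + k] - traj$y_um[i])^2)
    }
    out <- rbind(out, data.frame(lag_h = k * dt, msd_um2 = mean(acc),
                                 n_pairs = length(acc)))
  }
  out
}

# Brute-force Benjamini-Hochberg: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / j, computed literally from the definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- sapply(seq_len(m), function(j) {
      if (p[ord[j]] >= p[ord[i]]) p[ord[j]] * m / j else Inf
    })
    q[ord[i]] <- min(1, min(candidates))
  }
  q
}

# A random short track for property tests.
random_track <- function(n, seed) {
  set.seed(seed)
  data.frame(t_hours = (seq_len(n) - 1) / 6,
             x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)))
}
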