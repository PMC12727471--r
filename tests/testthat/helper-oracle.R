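# Independent dense-matrix reference for small spin systems: builds the full
# Hamiltonian from explicit Kronecker products of single-spin operators (a
# deliberately different construction from the package's bit-indexed m_z-block
# implementation) and extracts transitions from all eigenstate pairs.
oracle_transitions <- function(shifts, J, f0, tol = 1e-10) {
  n <- length(shifts)
  I2 <- diag(2)
  Ix <- matrix(c(0, 0.5, 0.5, 0), 2)
  Iy <- matrix(c(0, 0.5i, -0.5i, 0), 2)
  Iz <- diag(c(0.5, -0.5))
  Iminus <- Ix - 1i * Iy
  op <- function(M, k) {
    out <- matrix(1, 1, 1)
    for (i in seq_len(n)) out <- kronecker(out, if (i == k) M else I2)
    out
  }
  H <- matrix(0 + 0i, 2^n, 2^n)
  for (k in seq_len(n)) H <- H + shifts[k] * f0 * op(Iz, k)
  if (n > 1) {
    for (k in seq_len(n - 1)) for (l in (k + 1):n) {
      if (J[k, l] != 0) {
        H <- H + J[k, l] * (op(Ix, k) %*% op(Ix, l) +
                            op(Iy, k) %*% op(Iy, l) +
                            op(Iz, k) %*% op(Iz, l))
      }
    }
  }
  e <- eigen(H, symmetric = TRUE)
  Lm <- matrix(0 + 0i, 2^n, 2^n)
  for (k in seq_len(n)) Lm <- Lm + op(Iminus, k)
  Tm <- Conj(t(e$vectors)) %*% Lm %*% e$vectors
  intens <- Mod(Tm)^2 / 2^(n - 1)
  freq <- outer(e$values, e$values, function(ef, ei) ei - ef)
  keep <- intens > tol
  data.frame(frequency_hz = Re(freq[keep]), intensity = intens[keep])
}

# Aggregate a transition table by rounding frequencies, for comparison between
# implementations whose degenerate lines may split differently.
aggregate_transitions <- function(df, digits = 6) {
  f <- round(df$frequency_hz, digits)
  agg <- tapply(df$intensity, f, sum)
  data.frame(frequency_hz = as.numeric(names(agg)), intensity = as.numeric(agg))
}

# Random small spin system for property loops.
random_spin_system <- function(n, seed) {
  set.seed(seed)
  Jm <- matrix(stats::rnorm(n * n, 0, 6), n)
  Jm <- (Jm + t(Jm)) / 2
  diag(Jm) <- 0
  spin_system(paste0("rnd", seed), stats::runif(n, 0, 6), Jm)
}
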