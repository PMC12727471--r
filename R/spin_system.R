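#' Spin systems and quantum-mechanical transition calculation
#'
#' A spin system is the standard liquid-state description of one metabolite
#' species: isotropic chemical shifts (ppm) for each spin-1/2 proton and a
#' symmetric scalar-coupling matrix J (Hz). At low field the shift differences
#' in Hz become comparable to J, so first-order multiplet rules break down;
#' transitions are therefore obtained from the full Hamiltonian
#'   H/h = sum_i nu_i Iz_i + sum_{i<j} J_ij (I_i . I_j),  nu_i = delta_i * f0,
#' with f0 the spectrometer frequency in MHz, by exact diagonalization.
#'
#' @name spin_system-module
NULL

# Dense diagonalization of a 2^n space: cap keeps this tractable and
# covers the bundled species (largest is TSP with 9 equivalent protons).
.MAX_SPINS <- 12L

#' Construct a spin system
#'
#' @param name Text label for the species.
#' @param shifts Numeric vector of chemical shifts in ppm, one per spin-1/2
#'   nucleus.
#' @param couplings Symmetric matrix of scalar couplings J_ij in Hz with zero
#'   diagonal, or `NULL` for an uncoupled system.
#' @param population Relative molar fraction (>= 0); used when mixing species
#'   such as glucose anomers.
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(name, shifts, couplings = NULL, population = 1) {
  shifts <- as.numeric(shifts)
  n <- length(shifts)
  if (n < 1L) stop("spin system must contain at least one spin")
  if (n > .MAX_SPINS) {
    stop(sprintf("spin system '%s' has %d spins; the supported maximum is %d",
                 name, n, .MAX_SPINS))
  }
  if (is.null(couplings)) couplings <- matrix(0, n, n)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n))) {
    stop("couplings must be an n x n matrix matching the number of shifts")
  }
  if (any(abs(couplings - t(couplings)) > 1e-12)) {
    stop("couplings matrix must be symmetric")
  }
  if (any(abs(diag(couplings)) > 1e-12)) {
    stop("couplings matrix must have a zero diagonal")
  }
  if (!is.numeric(population) || length(population) != 1L || population < 0) {
    stop("population must be a single non-negative number")
  }
  structure(
    list(name = as.character(name), shifts = shifts,
         couplings = couplings, population = as.numeric(population)),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s: %d spin(s), population %.3g\n",
              x$name, length(x$shifts), x$population))
  cat("  shifts (ppm):", paste(format(x$shifts, digits = 4), collapse = ", "), "\n")
  nz <- sum(abs(x$couplings[upper.tri(x$couplings)]) > 0)
  cat(sprintf("  %d nonzero coupling(s)\n", nz))
  invisible(x)
}

#' Compute NMR transitions by Hamiltonian diagonalization
#'
#' Builds the isotropic spin Hamiltonian in the Zeeman product basis, exploits
#' conservation of total magnetization quantum number (the Hamiltonian is block
#' diagonal in m_z), diagonalizes each block, and computes single-quantum
#' transition intensities as squared matrix elements of the total lowering
#' operator between eigenstates of adjacent blocks. Intensities are normalized
#' so their sum equals the number of spins (one unit per observable proton,
#' the equal-population high-temperature convention); this sum is invariant
#' under the couplings.
#'
#' @param system A [spin_system()].
#' @param spectrometer_freq Spectrometer proton frequency in MHz (> 0).
#' @param intensity_floor Transitions with intensity below this fraction of
#'   the total are dropped (numerical hygiene; default 1e-8).
#' @return A `transition_list`: a data frame with columns `frequency_hz`
#'   (offset from the 0 ppm reference) and `intensity` (dimensionless, >= 0),
#'   with the spin count and spectrometer frequency as attributes.
#' @export
compute_transitions <- function(system, spectrometer_freq,
                                intensity_floor = 1e-8) {
  stopifnot(inherits(system, "spin_system"))
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0) {
    stop("spectrometer_freq must be a positive frequency in MHz")
  }
  n <- length(system$shifts)
  nu <- system$shifts * spectrometer_freq  # Larmor offsets, Hz
  J <- system$couplings

  # Basis states are integers 0..2^n-1; bit k set means spin k is beta
  # (m_k = -1/2). m_z for each basis state:
  states <- 0:(2^n - 1L)
  bits <- matrix(0L, length(states), n)
  for (k in seq_len(n)) bits[, k] <- bitwAnd(states, bitwShiftL(1L, k - 1L)) > 0L
  mz <- rowSums(!bits) - n / 2  # number of alpha spins - n/2

  m_spin <- 0.5 - bits  # m_k per state per spin

  # Diagonal part: sum_k nu_k m_k + sum_{k<l} J_kl m_k m_l
  diag_e <- as.numeric(m_spin %*% nu)
  for (k in seq_len(n - 1L)) for (l in (k + 1L):n) {
    if (J[k, l] != 0) diag_e <- diag_e + J[k, l] * m_spin[, k] * m_spin[, l]
  }

  # Eigen-decompose each m_z block; off-diagonal flip-flop terms J_kl/2
  # connect states differing by an alpha-beta exchange on spins k,l.
  levels_m <- sort(unique(mz), decreasing = TRUE)
  eig <- vector("list", length(levels_m))
  idx_m <- lapply(levels_m, function(m) which(abs(mz - m) < 1e-9))
  for (b in seq_along(levels_m)) {
    idx <- idx_m[[b]]
    d <- length(idx)
    H <- matrix(0, d, d)
    diag(H) <- diag_e[idx]
    if (d > 1L) {
      pos <- integer(length(states)); pos[idx] <- seq_len(d)
      for (k in seq_len(n - 1L)) for (l in (k + 1L):n) {
        if (J[k, l] == 0) next
        for (ii in seq_len(d)) {
          s <- states[idx[ii]]
          bk <- bitwAnd(s, bitwShiftL(1L, k - 1L)) > 0L
          bl <- bitwAnd(s, bitwShiftL(1L, l - 1L)) > 0L
          if (bk != bl) {
            s2 <- bitwXor(s, bitwOr(bitwShiftL(1L, k - 1L), bitwShiftL(1L, l - 1L)))
            jj <- pos[s2 + 1L]
            H[ii, jj] <- H[ii, jj] + J[k, l] / 2
          }
        }
      }
    }
    e <- eigen(H, symmetric = TRUE)
    eig[[b]] <- list(values = e$values, vectors = e$vectors, idx = idx)
  }

  # Single-quantum transitions: block m -> block m-1 via the total lowering
  # operator (basis matrix element 1 for each single alpha->beta flip).
  freqs <- numeric(0); ints <- numeric(0)
  for (b in seq_len(length(levels_m) - 1L)) {
    up <- eig[[b]]; dn <- eig[[b + 1L]]
    L <- matrix(0, length(dn$idx), length(up$idx))
    pos_dn <- integer(length(states)); pos_dn[dn$idx] <- seq_along(dn$idx)
    for (ii in seq_along(up$idx)) {
      s <- states[up$idx[ii]]
      for (k in seq_len(n)) {
        if (bitwAnd(s, bitwShiftL(1L, k - 1L)) == 0L) {  # spin k is alpha
          s2 <- bitwOr(s, bitwShiftL(1L, k - 1L))
          L[pos_dn[s2 + 1L], ii] <- 1
        }
      }
    }
    Tmat <- crossprod(dn$vectors, L %*% up$vectors)  # <f| I- |i>
    intens <- Tmat^2 / 2^(n - 1L)
    dE <- outer(dn$values, up$values, function(ef, ei) ei - ef)
    keep <- intens > 0
    freqs <- c(freqs, dE[keep])
    ints <- c(ints, intens[keep])
  }

  total <- sum(ints)
  keep <- ints >= intensity_floor * total
  out <- data.frame(frequency_hz = freqs[keep], intensity = ints[keep])
  out <- out[order(-out$frequency_hz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("transition_list", "data.frame"),
            n_spins = n, spectrometer_freq = spectrometer_freq,
            total_intensity = total)
}

#' @export
print.transition_list <- function(x, ...) {
  cat(sprintf("<transition_list> %d transition(s), %d spin(s), sum intensity %.6f\n",
              nrow(x), attr(x, "n_spins"), sum(x$intensity)))
  NextMethod()
}
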