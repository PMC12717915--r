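# Independent oracles, kept deliberately naive and separate from the
# package's own algorithms.

# physicists' Hermite polynomial by the three-term recursion
hermite_poly <- function(n, x) {
  if (n == 0L) return(rep(1, length(x)))
  hm1 <- rep(1, length(x))
  h <- 2 * x
  if (n == 1L) return(h)
  for (k in 2:n) {
    tmp <- 2 * x * h - 2 * (k - 1) * hm1
    hm1 <- h
    h <- tmp
  }
  h
}

# harmonic-oscillator eigenfunction with dimensionless frequency w,
# centered at `center` (hbar = mass = 1)
ho_wavefunction <- function(n, x, w, center = 0) {
  q <- sqrt(w) * (x - center)
  (w / pi)^0.25 / sqrt(2^n * factorial(n)) * hermite_poly(n, q) *
    exp(-q^2 / 2)
}

# brute-force FC overlap by adaptive quadrature of the explicit
# wavefunctions; displacement d in ground-state dimensionless coordinates
fc_overlap_quadrature <- function(m, n, freq_ground, freq_excited, d) {
  f <- freq_excited / freq_ground
  stats::integrate(function(x) {
    ho_wavefunction(m, x, 1, 0) * ho_wavefunction(n, x, f, d)
  }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# monomer concentration by brute-force root finding on
# K_D = ((C_i - M)/2) / M^2, with Newton polish to machine precision
speciate_root <- function(k_d, c_i) {
  if (k_d == 0) return(c_i)
  r <- stats::uniroot(function(m) 2 * k_d * m^2 + m - c_i,
                      lower = 0, upper = c_i, tol = 1e-16)$root
  for (i in 1:3) r <- r - (2 * k_d * r^2 + r - c_i) / (4 * k_d * r + 1)
  r
}

# a unit-height Gaussian spectrum on a grid
gaussian_spectrum <- function(center, sigma, grid, height = 1) {
  spectrum(grid, height * exp(-(grid - center)^2 / (2 * sigma^2)),
           label = "gaussian")
}
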