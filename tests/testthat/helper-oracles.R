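# Independent oracles, deliberately written apart from the package internals.

# Hand transcription of the A1 pigment template constants (alpha + beta band),
# un-normalized; used to cross-check the package's template evaluation.
gov_a1_oracle <- function(lmax, lam) {
  x <- lmax / lam
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lm_beta <- 189 + 0.315 * lmax
  b_beta <- -40.5 + 0.195 * lmax
  s_alpha + 0.26 * exp(-((lam - lm_beta) / b_beta)^2)
}

# unit-peak oracle via the same dense scan the contract specifies
gov_a1_oracle_unit <- function(lmax, lam) {
  gov_a1_oracle(lmax, lam) / max(gov_a1_oracle(lmax, seq(300, 700, by = 0.1)))
}

# Textbook Gotoh dynamic-programming global aligner (affine gaps, end gaps
# penalized); gap of length L costs open + L * ext. Returns the optimal score.
nw_score_oracle <- function(s1, s2, submat, open = 10, ext = 1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - (open + ext))
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             X[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# five-LED wavelength set used throughout
led_wl <- c(410, 430, 470, 510, 540)

# sensitivity points generated exactly from the package template
template_points <- function(lmax, wl = led_wl, scale = 1) {
  tpl <- spectral_template(lmax)
  data.frame(wavelength_nm = wl,
             rel_sensitivity = scale * evaluate_template(tpl, wl))
}

# a clean synthetic trace built directly (not via the generator)
flat_trace <- function(level = 7.3, onset = 60, dt = 1, total = 300, ...) {
  times <- seq(0, total, by = dt)
  luminescence_trace(times, rep(level, length(times)), stimulus_onset = onset,
                     stimulus_wavelength = 470, photon_flux = 6.2e14, ...)
}
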