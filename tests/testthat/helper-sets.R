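# Shared fixtures: all synthetic, generated in code.

std_porosities <- seq(0.05, 0.5, by = 0.05)

constant_set <- function(L = 0.5, n_s = 1.86, f = std_porosities) {
  gen_set(n_s, L, f)
}

# random AB-EMA-consistent set with constant L
random_consistent_set <- function() {
  n_s <- runif(1, 1.3, 2.6)
  L <- runif(1, 0.05, 0.95)
  f <- sort(runif(8, 0.02, 0.6))
  f <- f[!duplicated(round(f / 1e-9))]
  gen_set(n_s, L, f)
}

# Eq. residual of the real AB-EMA, used as an independent oracle
abema_residual <- function(f, n_eff, n_s, L) {
  e <- n_eff^2
  s <- n_s^2
  f * (1 - e) / (e + L * (1 - e)) + (1 - f) * (s - e) / (e + L * (s - e))
}
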