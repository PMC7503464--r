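# Shared fixtures, built in code at test time.

# Noiseless wild-type-anchored scenario (k_on 31, k_off 1100, k_slow 400)
noiseless_scenario <- function(...) {
  kinetic_scenario(noise_sd = 0, ref_noise_sd = 0, ...)
}

# Independent scalar forward model used as the oracle for the generator:
# written directly from the relaxation closed form, no shared code path.
oracle_transient_value <- function(t, f0, amp_fast, k_fast, amp_slow, k_slow,
                                   bg_step = 0) {
  if (t <= 0) return(f0)
  f0 * (1 + amp_fast * (1 - exp(-k_fast * t)) +
          amp_slow * (1 - exp(-k_slow * t)) + bg_step)
}

# Free-concentration oracle: 1-D root search on the mass-action equation.
oracle_EL <- function(E, L, Kd) {
  if (E == 0 || L == 0) return(0)
  uniroot(function(x) (E - x) * (L - x) / Kd - x,
          interval = c(0, min(E, L)), tol = 1e-13)$root
}

# Critical-r oracle: invert the two-tailed t test p-value by root search
# (independent of the quantile-relation implementation).
oracle_critical_r <- function(confidence, DF) {
  uniroot(function(r) {
    tstat <- r * sqrt(DF) / sqrt(1 - r^2)
    2 * (1 - pt(tstat, DF)) - (1 - confidence)
  }, interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}
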