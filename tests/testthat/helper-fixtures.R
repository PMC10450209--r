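# Shared fixtures: BCCG anchor sets at the reference-curve endpoint
# medians, and compact cohort configurations used across test files.

mhr_anchors <- function(L = 1, S = 0.03) {
  data.frame(age = c(11, 18), L = L, M = c(208.64, 196.93), S = S)
}

rhr_anchors_bccg <- function(L = 1, S = 0.08) {
  data.frame(age = c(11, 18), L = L, M = c(73.86, 63.64), S = S)
}

# Equal-weight cohort with per-age BCCG draws for MHR.
bccg_mhr_config <- function(seed, n_per_age = 100) {
  cohort_config(n_players = 8 * n_per_age,
                age_proportions = rep(1 / 8, 8),
                bccg_anchors = list(mhr = mhr_anchors()),
                seed = seed)
}

# BCCG log-likelihood evaluated directly from the definition; used as an
# independent check of the fitted optimum.
ref_bccg_loglik <- function(x, L, M, S) {
  z <- if (abs(L) < 1e-7) log(x / M) / S else ((x / M)^L - 1) / (L * S)
  sum(L * log(x / M) - log(S) - z^2 / 2)
}
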