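## Shared fixtures, built once per test run. All tests use the corrected
## literature parameterization unless they construct their own.
P <- sorensen_params()
B <- basal_state(P)                 # exact equilibrium
B_paper <- basal_state(P, exact = FALSE)
SP_FIT <- simo_params("ogtt_fit")
SP_PRIOR <- simo_params("simo_prior")
SIMO_RATES <- c("k_js", "k_gj", "k_rj", "k_lr", "k_gl")

random_feasible_state <- function() {
  ## a physiologically plausible random state: concentrations jittered
  ## around basal, regulatory/pancreas states positive
  s <- B$state
  s[1:8] <- s[1:8] * runif(8, 0.5, 2.5)     # glucose, mg/dl
  s[9:15] <- s[9:15] * runif(7, 0.3, 5)     # insulin, mU/l
  s[16] <- runif(1, 0.5, 2)                 # glucagon (normalized)
  s[17:18] <- runif(2, 0.2, 2)              # slow multipliers
  s[19] <- runif(1, -0.2, 0.5)              # f2
  s[20] <- runif(1, 0, 1)                   # potentiator
  s[21] <- runif(1, 0, 1)                   # inhibitor
  s[22] <- runif(1, 1, 30)                  # labile insulin, U
  s[23:26] <- runif(4, 0, 3e4)              # gut contents, mg
  s
}
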