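## Shared fixtures: ionic conditions and small generator configurations
## used across the module tests.

sym_kcl <- function(mM = 100) {
  ionic_condition(c(K = mM, Cl = mM), c(K = mM, Cl = mM))
}

asym_kcl <- function() {
  ionic_condition(c(K = 300, Cl = 300), c(K = 100, Cl = 100))
}

sym_kno3 <- function(mM = 100) {
  ionic_condition(c(K = mM, NO3 = mM), c(K = mM, NO3 = mM))
}

## piecewise-constant two-level trace alternating closed/open every
## `period` samples, for exact histogram/idealization checks
two_level_trace <- function(i_open, n = 1000, period = 10, fs = 5000,
                            ionic = sym_kcl(), v = 80) {
  level <- rep(rep(c(0, 1), each = period), length.out = n)
  current_trace(time = (seq_len(n) - 1) / fs, current = level * i_open,
                holding_potential = v, ionic = ionic, sampling_rate = fs)
}
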