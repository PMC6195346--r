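# Independent oracles and shared fixtures. Constants are written out here
# (not taken from the package) so the oracles stay independent of the code
# they check.

.o_R <- 8.314
.o_F <- 96485
.o_T <- 293.15
.o_RT_kJ <- .o_R * .o_T / 1000

# closed-form symmetric-barrier symmetric-solution current
sinh_current <- function(A, c, V_mV, z = -1, T = .o_T) {
  2 * z * .o_F * A * c * sinh(z * .o_F * (V_mV / 1000) / (6 * .o_R * T))
}

nernst_mV <- function(ci, co, z, T = .o_T) {
  1000 * .o_R * T / (z * .o_F) * log(co / ci)
}

default_cond <- function() ion_condition(ci = 150, co = 150, z = -1,
                                         T = 293.15)

quiet_pipeline <- function(cfg) {
  suppressWarnings(run_pipeline(run_config(input = generate_cohort(cfg)$sweeps)))
}
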