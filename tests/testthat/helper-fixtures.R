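# Small simulated datasets shared across test files. All fixtures are
# generated in code under fixed seeds.

GAS_R <- 8.3145e-3 # kJ/(mol K), duplicated here so oracles stay independent

tiny_solubility <- function(n_materials = 12, temps = 3, seed = 101, ...) {
  simulate_qspr_dataset(sim_config(n_materials = n_materials,
                                   temps_per_material = temps,
                                   seed = seed, ...))
}

tiny_enthalpy <- function(n_materials = 40, seed = 202, ...) {
  simulate_qspr_dataset(sim_config(n_materials = n_materials,
                                   endpoint_kind = "enthalpy",
                                   seed = seed, ...))
}

# hand-built dataset with a known exactly-linear endpoint for learner tests
linear_dataset <- function(n = 60, seed = 303) {
  set.seed(seed)
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * x$a - 1.5 * x$b + 0.25
  qspr_dataset(sprintf("I%03d", seq_len(n)), y, x,
               registry = list(Blk = c("a", "b", "c")),
               endpoint_kind = "enthalpy")
}
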