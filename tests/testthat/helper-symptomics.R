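# Shared fixtures for the test suite.  Everything is generated in code and
# cached for the session so expensive objects are built once.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) assign(name, builder(), fixture_env)
  get(name, envir = fixture_env)
}

# worked 12-sample fixture plus a small trained model on it
trained_fixture <- function() {
  cached("trained_fixture", function() {
    fx <- make_worked_fixture()
    arch <- architecture_spec(6, fx$scores$schema, width_z1 = 16,
                              width_z2 = 8, width_z3 = 4)
    model <- train_model(build_model(arch, seed = 1), fx$omics, fx$scores,
                         hyperparams(learning_rate = 5e-3, epochs = 60,
                                     batch_size = 4, seed = 2))
    c(fx, list(model = model))
  })
}

# a trained model with all three head types (binary, categorical,
# continuous) on a small simulated cohort
mixed_head_model <- function() {
  cached("mixed_head_model", function() {
    co <- simulate_cohort(sim_config(n_samples = 80, n_species = 0,
                                     n_kegg = 0, n_immune = 10,
                                     n_metabolome = 0, n_blood = 0,
                                     n_shared_biomarkers = 3,
                                     n_specific_per_output = 0,
                                     effect_size = 2, seed = 5))
    x <- co$omics$immune
    arch <- architecture_spec(10, co$scores$schema, width_z1 = 16,
                              width_z2 = 8, width_z3 = 4)
    model <- train_model(build_model(arch, seed = 3), x, co$scores,
                         hyperparams(learning_rate = 5e-3, epochs = 40,
                                     batch_size = 32, seed = 4))
    list(cohort = co, x = x, model = model)
  })
}

# write a small delimited table and return its path
write_tmp_table <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
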