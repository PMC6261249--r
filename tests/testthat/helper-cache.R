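# heavy shared fixtures, computed once per test run
.cardioem_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cardioem_cache)) {
    assign(name, force(expr), envir = .cardioem_cache)
  }
  get(name, envir = .cardioem_cache)
}

get_setup <- function() cached("setup", study_setup(seed = 1))

get_study <- function() cached("study", run_study(get_setup()))

# one steady paced endo cell run shared by several tests
get_paced_endo <- function() {
  cached("paced_endo",
         run_paced_cell(cell_params("endo"),
                        pacing_protocol(bcl = 600, n_beats = 20)))
}

default_ca <- function() make_ca_transient()
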