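# Shared settings for the analysis scripts. Every script can be rerun in
# isolation: stages are deterministic given the seed below.

library(gbsnet)

RESULTS <- "results/analysis"
SEED <- 1L

# Study conditions: a 7-vs-7 cohort with five planted co-expression
# modules (r = 0.9), one carrying a 2-SD disease effect, riding on a
# scale-free PPI overlay that contains every planted module pair.
study_config <- function() {
  sim_config(n_genes = 1000L, n_case = 7L, n_control = 7L,
             n_modules = 5L, module_size = 10L,
             within_module_r = 0.9, disease_effect = 2,
             n_disease_modules = 1L, frac_module_edges_in_ppi = 1,
             seed = SEED)
}

dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
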