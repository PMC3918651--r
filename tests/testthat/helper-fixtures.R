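# shared fixture builders; everything is generated in code

# small hand-sized panel with strongly informative markers
tiny_panel <- function(n = 5, eps = 0.001) {
  aim_panel(paste0("m", seq_len(n)),
            p_afr = seq(0.1, 0.3, length.out = n),
            p_eur = seq(0.9, 0.7, length.out = n), eps = eps)
}

# simulated cohort small enough for unit tests
tiny_cohort <- function(n = 120, m = 80, seed = 42) {
  simulate_cohort(sim_config(n_individuals = n, n_markers = m,
                             missing_rate = 0.02, seed = seed))
}

# derived table built from true ancestry (isolates the downstream
# statistics from estimation noise)
tiny_derived <- function(n = 400, seed = 11, pea_modifier = "obesity") {
  cfg <- sim_config(n_individuals = n, seed = seed,
                    pea_modifier = pea_modifier)
  s <- simulate_true_pea(n, seed = seed)
  ph <- simulate_phenotypes(s, cfg, seed = seed + 1L)
  anc <- data.frame(individual_id = ph$individual_id, pea = s)
  suppressWarnings(derive_cohort(ph, anc, glucose_unit = "mg/dL"))
}
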