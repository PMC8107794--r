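# Shared fixtures, all generated in code.

# small 12-region / 3-network parcellation: DMN carries planted signal in
# most tests, VIS and SMN are noise networks
tiny_parc <- function()
  make_parcellation(12, networks = c("DMN", "VIS", "SMN"))

# young-adult cohort with a constant-sign planted effect on intra-DMN edges
young_cohort <- function(n = 400, d = 0.8, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_subjects = n, age_range = c(22, 36), crossing_age = 50,
    network_effect_profile = c(DMN = d), slope = 0,
    parcellation = tiny_parc(), seed = seed, ...))
}

# lifespan cohort whose planted sex effect crosses zero at 50 years
crossing_cohort <- function(n = 1500, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_subjects = n, age_range = c(17, 78), crossing_age = 50,
    network_effect_profile = c(DMN = 0.8, VIS = 0.6),
    parcellation = tiny_parc(), seed = seed, ...))
}

# brute-force Cohen's d oracle (independent of cohens_d)
oracle_d <- function(x, sex) {
  xm <- x[sex == "M"]; xf <- x[sex == "F"]
  sp2 <- ((length(xm) - 1) * var(xm) + (length(xf) - 1) * var(xf)) /
    (length(xm) + length(xf) - 2)
  (mean(xm) - mean(xf)) / sqrt(sp2)
}
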