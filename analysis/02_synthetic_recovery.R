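#!/usr/bin/env Rscript
# Planted-genotype recovery across seeded synthetic cohorts: sensitivity of
# the full pipeline per inheritance mechanism and specificity against the
# two decoy classes.
#
# Writes: results/synthetic_recovery.tsv

suppressMessages(library(nshldx))
suppressMessages(library(dplyr))
dir.create("results", showWarnings = FALSE)

plants <- list(
  plant_spec("ar_hom", count = 3), plant_spec("ar_compound_het", count = 3),
  plant_spec("xl_hemizygous", count = 2), plant_spec("de_novo_ad", count = 2),
  plant_spec("decoy_single_het_ar", count = 2),
  plant_spec("decoy_ad_nonsegregating", count = 2))

rows <- list()
for (seed in 1:20) {
  cfg <- cohort_config(n_probands = 28, trio_fraction = 0.5,
                       background_variants_per_subject = 2000,
                       planted_scenarios = plants, seed = seed)
  co <- generate_cohort(cfg)
  calls <- classify_cohort(co)$calls
  m <- left_join(co$truth, calls, by = "subject_id")
  rows[[seed]] <- m %>%
    group_by(scenario, causal) %>%
    summarise(n = n(),
              solved = sum(status == "solved_known_gene" &
                             (!causal | gene.y == gene.x)),
              .groups = "drop") %>%
    mutate(seed = seed)
}
tab <- bind_rows(rows) %>%
  group_by(scenario, causal) %>%
  summarise(n = sum(n), solved = sum(solved), .groups = "drop") %>%
  mutate(rate = solved / n)
readr::write_tsv(tab, "results/synthetic_recovery.tsv")

cat("Recovery over 20 cohorts (28 probands, 2000 background sites each):\n")
print(as.data.frame(tab))
cat("Causal mechanisms should recover at rate 1.0; decoys at 0.0.\n")
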