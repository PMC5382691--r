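test_that("population-frequency step removes strictly above 1% only", {
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 100, "G1", dbsnp_maf = 0.02),
    mk_var("1", 200, "G1", dbsnp_maf = 0.01),    # boundary: retained
    mk_var("1", 300, "G1", kg_maf = 0.10),
    mk_var("1", 400, "G1"),                      # unannotated: retained
    mk_var("7", 500, "SLC26A4", dbsnp_maf = 0.001)))
  out <- filter_population_frequency(v)
  expect_setequal(out$variant_id,
                  c("1:200:A:G", "1:400:A:G", "7:500:A:G"))
})

test_that("internal-control step excludes homozygous/hemizygous carriers only", {
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 100, "G1"), mk_var("1", 200, "G1"),
    mk_var("X", 50000000, "XG"), mk_var("1", 300, "G1")))
  ctrl <- matrix(0L, nrow = 3, ncol = 5,
                 dimnames = list(c("1:100:A:G", "1:200:A:G", "X:50000000:A:G"),
                                 NULL))
  ctrl["1:100:A:G", 2] <- 2L      # one hom-alt control
  ctrl["1:200:A:G", ] <- 1L       # five het carriers: not excluding
  ctrl["X:50000000:A:G", 4] <- 3L # hemizygous-alt male control
  out <- filter_internal_controls(v, ctrl)
  expect_setequal(out$variant_id, c("1:200:A:G", "1:300:A:G"))
  expect_warning(filter_internal_controls(v, ctrl, n_controls = 32),
                 "expected 32")
  expect_equal(nrow(filter_internal_controls(v, NULL)), 4)
})

test_that("consequence step drops synonymous/intronic, keeps splice site", {
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 100, "G1", consequence = "synonymous"),
    mk_var("1", 200, "G1", consequence = "intronic"),
    mk_var("7", 300, "SLC26A4", consequence = "splice_site"),
    mk_var("1", 400, "G1", consequence = "missense"),
    mk_var("1", 500, "G1", consequence = "frameshift_deletion")))
  out <- filter_consequence(v)
  expect_setequal(out$consequence,
                  c("splice_site", "missense", "frameshift_deletion"))
  v$consequence[1] <- "stop_gained"  # not in the closed vocabulary
  expect_error(filter_consequence(v), "unknown consequence")
})

test_that("panel restriction partitions by symbol and preserves both sides", {
  panel <- test_panel()
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 1000, "AGENE"), mk_var("9", 100, "NOVEL1")))
  parts <- partition_by_panel(v, panel)
  expect_equal(parts$panel$gene, "AGENE")
  expect_equal(parts$nonpanel$gene, "NOVEL1")
  empty <- partition_by_panel(v[0, ], panel)
  expect_equal(nrow(empty$panel), 0)
  expect_equal(nrow(empty$nonpanel), 0)
})

test_that("ranking re-filters by mode-specific MAF and orders by damage", {
  panel <- test_panel()
  # the published MYO15A pair: fully damaging, fish-deep conservation vs a
  # benign-scoring partner allele
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("17", 18045000, "AGENE", ref = "G", alt = "T", pp2 = 1.000,
           mutation_taster = "disease_causing", provean = -8.66, sift = 0.000,
           conservation_depth = 4L, exac_ac = 1, exac_an = 116996),
    mk_var("17", 18025000, "AGENE", pp2 = 0.004,
           mutation_taster = "polymorphism", provean = -0.82, sift = 0.012,
           conservation_depth = 2L)))
  out <- rank_variants(v, panel = panel)
  expect_equal(out$variant_id[1], "17:18045000:G:T")
  expect_equal(out$n_damaging, c(4L, 1L))

  # an AD-only gene uses the 0.0005 cut, an AR gene the 0.005 cut
  v2 <- as_variant_table(dplyr::bind_rows(
    mk_var("2", 3000, "DGENE", dbsnp_maf = 0.001),
    mk_var("1", 1000, "AGENE", dbsnp_maf = 0.001)))
  out2 <- rank_variants(v2, panel = panel)
  expect_equal(out2$gene, "AGENE")

  # equal keys: stable lexicographic order by variant id
  v3 <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 1000, "AGENE"), mk_var("1", 1001, "AGENE", ref = "C",
                                       alt = "T")))
  out3 <- rank_variants(v3, panel = panel)
  expect_equal(out3$variant_id, sort(out3$variant_id))
})

cascade_cohort <- function(seed = 5) {
  cfg <- cohort_config(n_probands = 4, trio_fraction = 1,
                       background_variants_per_subject = 400, seed = seed,
                       planted_scenarios = list(plant_spec("ar_compound_het")))
  generate_cohort(cfg)
}

test_that("the cascade waterfall is monotone and every variant is accounted
           for", {
  co <- cascade_cohort()
  tr <- run_cascade("SIM001", co)
  expect_true(all(diff(tr$step_counts$n) <= 0))
  expect_equal(tr$step_counts$step[1], "raw")

  # completeness: retained + uniquely-excluded = raw
  raw_ids <- co$genotypes$variant_id[
    co$genotypes$subject_id == "SIM001" &
      co$genotypes$zygosity %in% c("het", "hom_alt", "hemizygous")]
  expect_setequal(c(tr$retained$variant_id, tr$excluded_reasons$variant_id),
                  raw_ids)
  expect_equal(anyDuplicated(tr$excluded_reasons$variant_id), 0)
  expect_equal(length(intersect(tr$retained$variant_id,
                                tr$excluded_reasons$variant_id)), 0)

  # the planted compound heterozygote survives to the final set
  planted <- strsplit(co$truth$variant_ids[1], ",")[[1]]
  expect_true(all(planted %in% tr$retained$variant_id))
  expect_true(any(tr$mechanisms$mechanism == "compound_het" &
                    tr$mechanisms$diagnostic))
})

test_that("cascade output is order-independent in the variant table", {
  co <- cascade_cohort(seed = 6)
  tr1 <- run_cascade("SIM002", co)
  co2 <- co
  set.seed(99)
  perm <- sample(nrow(co2$variants))
  co2$variants <- co2$variants[perm, ]
  co2$genotypes <- co2$genotypes[sample(nrow(co2$genotypes)), ]
  tr2 <- run_cascade("SIM002", co2)
  expect_equal(tr1$step_counts, tr2$step_counts)
  expect_equal(tr1$retained$variant_id, tr2$retained$variant_id)
})

test_that("a subject with no variants produces an all-zero trace", {
  co <- cascade_cohort(seed = 7)
  co$genotypes <- co$genotypes[co$genotypes$subject_id != "SIM003", ]
  tr <- run_cascade("SIM003", co)
  expect_true(all(tr$step_counts$n == 0))
  expect_equal(nrow(tr$retained), 0)
  expect_error(run_cascade("NOBODY", co), "pedigree missing")
})

test_that("candidate discovery runs only when the panel is not diagnostic", {
  co <- cascade_cohort(seed = 8)
  tr_planted <- run_cascade("SIM001", co)     # carries the AR plant
  expect_equal(tr_planted$path, "panel")
  tr_bg <- run_cascade("SIM004", co)          # background only
  expect_equal(tr_bg$path, "candidate")
  tr_forced <- run_cascade("SIM001", co, force_candidate = TRUE)
  expect_equal(tr_forced$path, "candidate")
  # forcing keeps the panel plant in the final set all the same
  planted <- strsplit(co$truth$variant_ids[1], ",")[[1]]
  expect_true(all(planted %in% tr_forced$retained$variant_id))
})
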