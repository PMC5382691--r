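small_config <- function(seed = 1, trio_fraction = 0.5, ...) {
  cohort_config(n_probands = 6, trio_fraction = trio_fraction,
                background_variants_per_subject = 300, seed = seed, ...)
}

test_that("identical seeds give identical cohorts and VCF bodies", {
  cfg <- small_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$variants, b$variants)
  expect_equal(a$genotypes, b$genotypes)
  expect_identical(unclass(a$controls), unclass(b$controls))

  fa <- withr::local_tempfile(fileext = ".vcf")
  fb <- withr::local_tempfile(fileext = ".vcf")
  samples <- unique(a$genotypes$subject_id)
  write_cohort_vcf(a$variants, a$genotypes, samples, fa)
  write_cohort_vcf(b$variants, b$genotypes, samples, fb)
  expect_identical(readLines(fa), readLines(fb))

  c2 <- generate_cohort(small_config(seed = 43))
  expect_false(identical(a$genotypes, c2$genotypes))
})

test_that("trio_fraction 1 gives every proband both parents", {
  co <- generate_cohort(small_config(seed = 2, trio_fraction = 1))
  expect_true(all(co$pedigrees$trio))
  co0 <- generate_cohort(small_config(seed = 2, trio_fraction = 0))
  expect_true(all(is.na(co0$pedigrees$father_id)))
})

test_that("trio genotypes are Mendelian-consistent at every background site", {
  co <- generate_cohort(cohort_config(n_probands = 3, trio_fraction = 1,
                                      background_variants_per_subject = 500,
                                      seed = 9))
  code <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, hemizygous = 3L)
  lookup <- function(subj) {
    g <- co$genotypes[co$genotypes$subject_id == subj, ]
    stats::setNames(code[g$zygosity], g$variant_id)
  }
  alleles <- function(gc) switch(as.character(gc),
    "0" = 0L, "1" = c(0L, 1L), "2" = 1L, "3" = 1L)
  x_np <- is_x_nonpar(co$variants$chrom, co$variants$pos)
  for (i in 1:3) {
    ped <- co$pedigrees[i, ]
    child <- lookup(ped$proband_id); fat <- lookup(ped$father_id)
    mot <- lookup(ped$mother_id)
    for (j in seq_len(nrow(co$variants))) {
      vid <- co$variants$variant_id[j]
      cc <- child[vid]; if (is.na(cc)) cc <- 0L
      fc <- fat[vid]; if (is.na(fc)) fc <- 0L
      mc <- mot[vid]; if (is.na(mc)) mc <- 0L
      ok <- if (x_np[j] && ped$proband_sex == "male") {
        # a son draws only the maternal X
        if (cc == 3L) 1L %in% alleles(mc)
        else if (cc == 0L) 0L %in% alleles(mc)
        else FALSE
      } else if (x_np[j]) {
        pa <- as.integer(fc == 3L)
        cc %in% outer(pa, alleles(mc), `+`)
      } else {
        cc %in% outer(alleles(fc), alleles(mc), `+`)
      }
      if (!ok) fail(paste("non-Mendelian genotype at", vid, "family", i))
    }
    succeed()
  }
})

test_that("planted genotypes appear exactly as specified and are recorded", {
  cfg <- cohort_config(
    n_probands = 8, trio_fraction = 0.5, background_variants_per_subject = 200,
    seed = 4,
    planted_scenarios = list(plant_spec("ar_hom"), plant_spec("ar_compound_het"),
                             plant_spec("xl_hemizygous"),
                             plant_spec("de_novo_ad"),
                             plant_spec("decoy_single_het_ar"),
                             plant_spec("decoy_ad_nonsegregating")))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth), 6)
  expect_equal(sum(co$truth$causal), 4)
  for (i in seq_len(nrow(co$truth))) {
    vids <- strsplit(co$truth$variant_ids[i], ",")[[1]]
    expect_true(all(vids %in% co$variants$variant_id))
    g <- co$genotypes[co$genotypes$subject_id == co$truth$subject_id[i] &
                        co$genotypes$variant_id %in% vids, ]
    expect_equal(nrow(g), length(vids))
    want <- switch(co$truth$scenario[i],
                   ar_hom = "hom_alt", xl_hemizygous = "hemizygous", "het")
    expect_true(all(g$zygosity == want))
    # panel plants land in a gene with the required mode
    modes <- panel_modes(co$panel, co$truth$gene[i])
    need <- switch(co$truth$scenario[i], xl_hemizygous = "XL",
                   de_novo_ad = "AD", decoy_ad_nonsegregating = "AD", "AR")
    expect_true(need %in% modes)
  }
  # controls never carry a planted allele in the excluding state
  planted_ids <- unlist(strsplit(co$truth$variant_ids, ","))
  expect_true(all(co$controls[planted_ids, ] <= 1L))
})

test_that("compound-het plants realise the requested phase", {
  panel <- test_panel()
  gene <- list(symbol = "AGENE", modes = "AR",
               exons = panel$exons[panel$exons$symbol == "AGENE", ])
  set.seed(10)
  ped <- mk_ped("P1", father = "F1", mother = "M1")

  tr <- plant_compound_het(ped, gene, "trans")
  vids <- variant_id(tr$variants$chrom, tr$variants$pos, tr$variants$ref,
                     tr$variants$alt)
  got <- resolve_phase(vids[1], vids[2], tr$genotypes, ped)
  expect_equal(got$phase_status, "confirmed_trans")

  ci <- plant_compound_het(ped, gene, "cis")
  vids <- variant_id(ci$variants$chrom, ci$variants$pos, ci$variants$ref,
                     ci$variants$alt)
  expect_equal(resolve_phase(vids[1], vids[2], ci$genotypes, ped)$phase_status,
               "cis_rejected")

  # father unavailable: plant goes in, phase stays presumed
  ped_m <- mk_ped("P2", mother = "M2")
  pr <- plant_compound_het(ped_m, gene, "trans")
  vids <- variant_id(pr$variants$chrom, pr$variants$pos, pr$variants$ref,
                     pr$variants$alt)
  expect_equal(resolve_phase(vids[1], vids[2], pr$genotypes, ped_m)$phase_status,
               "presumed_unconfirmed")

  # planted alleles are rare and protein-altering by construction
  expect_true(all(tr$variants$site_maf < 0.005))
  expect_true(all(tr$variants$consequence != "synonymous"))
  expect_error(plant_compound_het(ped, list(symbol = "D", modes = "AD",
                                            exons = gene$exons), "trans"),
               "AR")
})

test_that("control heterozygosity matches Hardy-Weinberg expectation", {
  set.seed(12)
  p <- 0.3
  m <- simulate_control_matrix(rep(p, 3000), n_controls = 20)
  obs <- mean(m == 1L)
  expected <- 2 * p * (1 - p)
  se <- sqrt(expected * (1 - expected) / length(m))
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("depth tables honour the gap specification deterministically", {
  panel <- default_panel()
  set.seed(3)
  d <- generate_depth_table(panel, gap_spec = c(24L, 14L))
  expect_equal(nrow(d), 1340)
  expect_equal(sum(d$mean_depth < 1), 38)
  expect_equal(sum(!d$targeted), 24)
  expect_equal(sum(d$targeted & d$mean_depth < 1), 14)
  expect_true(all(d$mean_depth[d$mean_depth >= 1] >= 1))

  set.seed(3)
  d2 <- generate_depth_table(panel, gap_spec = c(24L, 14L))
  expect_identical(d, d2)

  expect_error(generate_depth_table(panel, gap_spec = c(1400L, 0L)),
               "exceed")
  set.seed(4)
  clean <- generate_depth_table(panel, gap_spec = c(0L, 0L))
  expect_equal(find_uncovered_exons(clean)$summary$n_uncovered, 0)
})

test_that("configuration validation catches impossible requests", {
  expect_error(cohort_config(trio_fraction = 1.5), "fractions")
  expect_error(cohort_config(n_probands = 0), "positive")
  expect_error(cohort_config(n_probands = 2,
                             planted_scenarios = list(plant_spec("ar_hom",
                                                                 count = 3))),
               "exceeds")
  # a parent-dependent plant without trios cannot be generated
  cfg <- cohort_config(n_probands = 4, trio_fraction = 0,
                       background_variants_per_subject = 100,
                       planted_scenarios = list(plant_spec("de_novo_ad")))
  expect_error(generate_cohort(cfg), "trio")
})
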