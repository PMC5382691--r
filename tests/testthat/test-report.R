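test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_up(100 * 18 / 28, 1), 64.3)
  expect_equal(round_half_up(100 * 3 / 13, 1), 23.1)
  expect_equal(round_half_up(100 * 6 / 16, 1), 37.5)
  expect_equal(round_half_up(0.25, 1), 0.3)     # banker's rounding would say 0.2
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

solo_cohort <- function(genotypes, variants, ped = mk_ped("P1"),
                        eva = FALSE, panel = test_panel(), cnv_flags = NULL) {
  subjects <- tibble::tibble(subject_id = ped$proband_id,
                             family_id = ped$family_id,
                             sex = ped$proband_sex, eva = eva)
  mk_cohort(variants, genotypes, ped, panel = panel, subjects = subjects,
            cnv_flags = cnv_flags)
}

test_that("a single heterozygous allele in a recessive gene never solves", {
  v <- mk_var("1", 1000, "AGENE")
  co <- solo_cohort(mk_geno("P1", "1:1000:A:G", "het"), v)
  d <- classify_subject("P1", co)
  expect_equal(d$status, "unsolved")
  expect_match(paste(d$notes, collapse = " "), "AGENE")
})

test_that("a cis-rejected pair is never diagnostic", {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  v <- dplyr::bind_rows(mk_var("1", 1000, "AGENE"),
                        mk_var("1", 1100, "AGENE", ref = "C", alt = "T"))
  g <- dplyr::bind_rows(
    mk_geno("P1", "1:1000:A:G", "het"), mk_geno("P1", "1:1100:C:T", "het"),
    mk_geno("F1", "1:1000:A:G", "het"), mk_geno("F1", "1:1100:C:T", "het"))
  co <- solo_cohort(g, v, ped)
  d <- classify_subject("P1", co)
  expect_false(d$status == "solved_known_gene")
})

test_that("dominant variants carried by an unaffected mother are noted, not
           diagnostic", {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  v <- mk_var("2", 3000, "DGENE", exac_ac = 1, exac_an = 121000)
  g <- dplyr::bind_rows(mk_geno("P1", "2:3000:A:G", "het"),
                        mk_geno("M1", "2:3000:A:G", "het"))
  co <- solo_cohort(g, v, ped)
  d <- classify_subject("P1", co)
  expect_equal(d$status, "unsolved")
  expect_match(paste(d$notes, collapse = " "), "non-segregating")
})

test_that("a segregating de novo dominant variant is diagnostic with a note", {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  v <- mk_var("2", 3000, "DGENE", exac_ac = 1, exac_an = 121000)
  co <- solo_cohort(mk_geno("P1", "2:3000:A:G", "het"), v, ped)
  d <- classify_subject("P1", co)
  expect_equal(d$status, "solved_known_gene")
  expect_equal(d$gene, "DGENE")
  expect_match(paste(d$notes, collapse = " "), "de novo")
})

test_that("solved calls in two panel genes are both recorded as multilocus", {
  ped <- mk_ped("P1")
  v <- dplyr::bind_rows(mk_var("1", 1000, "AGENE"),
                        mk_var("1", 2000, "BGENE"))
  g <- dplyr::bind_rows(mk_geno("P1", "1:1000:A:G", "hom_alt"),
                        mk_geno("P1", "1:2000:A:G", "hom_alt"))
  co <- solo_cohort(g, v, ped)
  d <- classify_subject("P1", co)
  expect_equal(d$status, "solved_known_gene")
  expect_equal(nrow(d$mechanism), 2)
  expect_true("multilocus" %in% d$notes)
})

test_that("a flagged bi-allelic CNV yields candidate_only", {
  flags <- tibble::tibble(subject_id = "P1", chrom = "6", start = 30995157L,
                          end = 30996641L, type = "deletion",
                          copy_number = 0L, gene = "MUC22",
                          exon_index = "3", note = "truncation")
  co <- solo_cohort(mk_geno("P1", "9:999:A:G", "missing")[0, ],
                    mk_var("9", 999, "ZZ"), cnv_flags = flags)
  d <- classify_subject("P1", co)
  expect_equal(d$status, "candidate_only")
  expect_match(paste(d$notes, collapse = " "), "MUC22")
})

test_that("cohort yield arithmetic, strata and report round-trip", {
  calls <- tibble::tibble(
    subject_id = c("A", "B", "C"),
    status = c("solved_known_gene", "unsolved", "solved_known_gene"),
    route = c("sanger_slc26a4", "wes_candidate", "wes_panel"),
    gene = c("SLC26A4", NA, "MYO15A"),
    mechanism = c("compound_het", NA, "compound_het"),
    phase_status = c("presumed_unconfirmed", NA, "confirmed_trans"),
    notes = c("", "", ""))
  y <- cohort_yield(calls)
  expect_equal(y$yield_pct, 66.7)
  expect_equal(y$strata$excl_slc26a4_route$n, 2)
  expect_equal(y$strata$excl_slc26a4_route$yield_pct, 50)
  expect_equal(y$strata$wes_only$n, 2)
  # strata denominators partition the cohort
  expect_equal(y$n_total,
               y$strata$excl_slc26a4_route$n +
                 as.integer(y$per_route[["sanger_slc26a4"]]))

  rep <- render_report(y, calls)
  back <- jsonlite::fromJSON(rep$json)
  expect_equal(back$yield_pct, y$yield_pct)
  expect_equal(back$n_solved, y$n_solved)
  expect_equal(back$per_gene$MYO15A, 1)
  expect_equal(back$subjects$subject_id, calls$subject_id)
  expect_equal(back$strata$wes_only$yield_pct, y$strata$wes_only$yield_pct)
  expect_true(any(grepl("66.7", rep$markdown)))

  # one solved subject alone is a 100% cohort; no subjects is an error
  y1 <- cohort_yield(calls[3, ])
  expect_equal(y1$yield_pct, 100)
  expect_error(cohort_yield(calls[0, ]), "no diagnostic calls")
})

test_that("classification is deterministic", {
  co <- load_published_cohort()
  a <- classify_cohort(co)$calls
  b <- classify_cohort(co)$calls
  expect_identical(a, b)
})
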