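test_that("resolve_phase matches the brute-force transmission oracle on all
           parental genotype combinations", {
  zs <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(fzA = zs, fzB = zs, mzA = zs, mzB = zs,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    s <- two_locus_setup(grid$fzA[i], grid$fzB[i], grid$mzA[i], grid$mzB[i])
    got <- resolve_phase("1:100:A:G", "1:200:C:T", s$g, s$ped)
    want <- oracle_phase(grid$fzA[i], grid$fzB[i], grid$mzA[i], grid$mzB[i])
    expected_status <- switch(want,
      trans = "confirmed_trans", cis = "cis_rejected",
      mixed = "presumed_unconfirmed", none = "presumed_unconfirmed")
    expect_equal(got$phase_status, expected_status,
                 info = paste(grid[i, ], collapse = "/"))
    if (want == "none") {
      # unexplained alleles must be flagged de novo
      cf <- grid$fzA[i] != "hom_ref" | grid$mzA[i] != "hom_ref"
      cb <- grid$fzB[i] != "hom_ref" | grid$mzB[i] != "hom_ref"
      if (!cf) expect_equal(unname(got$parental_origin["1:100:A:G"]), "de_novo")
      if (!cb) expect_equal(unname(got$parental_origin["1:200:C:T"]), "de_novo")
    }
  }
})

test_that("phase resolution reproduces the canonical family patterns", {
  # father carries one allele, mother the other: confirmed trans with origins
  s <- two_locus_setup("het", "hom_ref", "hom_ref", "het")
  got <- resolve_phase("1:100:A:G", "1:200:C:T", s$g, s$ped)
  expect_equal(got$phase_status, "confirmed_trans")
  expect_equal(unname(got$parental_origin), c("father", "mother"))

  # one parent carries both, the other neither: the pair travelled together
  s <- two_locus_setup("het", "het", "hom_ref", "hom_ref")
  expect_equal(resolve_phase("1:100:A:G", "1:200:C:T", s$g, s$ped)$phase_status,
               "cis_rejected")

  # one parent carries both and the other one of them: transmission ambiguous
  s <- two_locus_setup("het", "het", "het", "hom_ref")
  expect_equal(resolve_phase("1:100:A:G", "1:200:C:T", s$g, s$ped)$phase_status,
               "presumed_unconfirmed")

  # parents untyped: presumed, still reportable
  ped <- mk_ped("P1")
  g <- dplyr::bind_rows(mk_geno("P1", "1:100:A:G", "het"),
                        mk_geno("P1", "1:200:C:T", "het"))
  got <- resolve_phase("1:100:A:G", "1:200:C:T", g, ped)
  expect_equal(got$phase_status, "presumed_unconfirmed")
  expect_equal(unname(got$parental_origin), c("unknown", "unknown"))

  # proband not het at both loci is a caller error
  g2 <- dplyr::bind_rows(mk_geno("P1", "1:100:A:G", "hom_alt"),
                         mk_geno("P1", "1:200:C:T", "het"))
  expect_error(resolve_phase("1:100:A:G", "1:200:C:T", g2, ped),
               "heterozygous at both")
})

test_that("bi-allelic detection calls homozygotes and the best het pair", {
  panel <- test_panel()
  ped <- mk_ped("P1")
  v <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 1000, "AGENE"),
    mk_var("1", 1100, "AGENE", ref = "C", alt = "T")))

  # a homozygous-alternate single allele is a diagnosis on its own
  g <- mk_geno("P1", "1:1000:A:G", "hom_alt")
  call <- detect_biallelic(v, g, ped)
  expect_equal(call$mechanism, "homozygous")
  expect_equal(call$phase_status, "not_applicable")

  # two hets without parental data: presumed compound heterozygote
  g <- dplyr::bind_rows(mk_geno("P1", "1:1000:A:G", "het"),
                        mk_geno("P1", "1:1100:C:T", "het"))
  call <- detect_biallelic(v, g, ped)
  expect_equal(call$mechanism, "compound_het")
  expect_equal(call$phase_status, "presumed_unconfirmed")

  # three hets: all pairs evaluated, exactly one call, the confirmed pair wins
  ped3 <- mk_ped("P1", father = "F1", mother = "M1")
  v3 <- as_variant_table(dplyr::bind_rows(
    mk_var("1", 1000, "AGENE"),
    mk_var("1", 1100, "AGENE", ref = "C", alt = "T"),
    mk_var("1", 5000, "AGENE", ref = "G", alt = "C")))
  g3 <- dplyr::bind_rows(
    mk_geno("P1", "1:1000:A:G", "het"),
    mk_geno("P1", "1:1100:C:T", "het"),
    mk_geno("P1", "1:5000:G:C", "het"),
    mk_geno("F1", "1:1000:A:G", "het"),   # A and B from father (cis-ish)
    mk_geno("F1", "1:1100:C:T", "het"),
    mk_geno("M1", "1:5000:G:C", "het"))   # C from mother
  call <- detect_biallelic(v3, g3, ped3)
  expect_equal(nrow(call), 1)
  expect_equal(call$phase_status, "confirmed_trans")
  expect_setequal(c(call$origin1, call$origin2), c("father", "mother"))
})

test_that("compound heterozygote origins never share one parent", {
  set.seed(7)
  panel <- test_panel()
  for (i in 1:40) {
    ped <- mk_ped("P1", father = "F1", mother = "M1")
    pl <- plant_compound_het(ped, list(symbol = "AGENE", modes = "AR",
                                       exons = panel$exons[
                                         panel$exons$symbol == "AGENE", ]),
                             phase = "trans")
    call <- detect_biallelic(as_variant_table(pl$variants), pl$genotypes, ped)
    expect_equal(call$phase_status, "confirmed_trans")
    expect_false(identical(call$origin1, call$origin2))
  }
})

test_that("de novo detection demands a typed trio", {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  g <- mk_geno("P1", "1:100:A:G", "het")
  expect_true(detect_de_novo("1:100:A:G", g, ped)$is_de_novo)

  g2 <- dplyr::bind_rows(g, mk_geno("M1", "1:100:A:G", "het"))
  expect_false(detect_de_novo("1:100:A:G", g2, ped)$is_de_novo)

  solo <- mk_ped("P1")
  dn <- detect_de_novo("1:100:A:G", g, solo)
  expect_false(dn$is_de_novo)
  expect_equal(dn$reason, "trio unavailable")
})

test_that("hemizygous detection needs male + X non-PAR + hemizygous call", {
  v <- as_variant_table(mk_var("X", 50000000, "XGENE"))
  ped_m <- mk_ped("P1", sex = "male")
  ped_f <- mk_ped("P2", sex = "female")
  g <- mk_geno("P1", v$variant_id, "hemizygous")
  expect_true(detect_hemizygous(v, g, ped_m))
  expect_false(detect_hemizygous(v, mk_geno("P2", v$variant_id, "het"), ped_f))
  v7 <- as_variant_table(mk_var("7", 50000000, "G7"))
  expect_false(detect_hemizygous(v7, mk_geno("P1", v7$variant_id, "het"),
                                 ped_m))
})

test_that("dominant segregation: unaffected carrier parents veto the variant", {
  ped <- mk_ped("P1", father = "F1", mother = "M1")
  g <- dplyr::bind_rows(mk_geno("P1", "3:3000:A:G", "het"),
                        mk_geno("M1", "3:3000:A:G", "het"))
  expect_equal(check_ad_segregation("3:3000:A:G", g, ped), "non_segregating")

  g_dn <- mk_geno("P1", "3:3000:A:G", "het")
  expect_equal(check_ad_segregation("3:3000:A:G", g_dn, ped), "segregates")

  solo <- mk_ped("P1")
  expect_equal(check_ad_segregation("3:3000:A:G", g_dn, solo), "indeterminate")
})
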