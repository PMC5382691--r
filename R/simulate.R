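#' Configuration for a synthetic cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a shared pool of exome variant sites whose minor allele
#' frequencies come from a two-component mixture (common sites uniform on
#' 0.02-0.5, rare sites log-uniform on 1e-6 to 5e-3), Hardy-Weinberg
#' genotypes for parents and internal controls, Mendelian transmission to
#' trio children, and planted causal or decoy genotypes of each inheritance
#' class. `background_variants_per_subject` is the size of the shared site
#' pool; a subject's raw variant list is the subset of sites they carry in
#' a non-reference state, as in real variant calling.
#'
#' @param n_probands number of probands
#' @param trio_fraction fraction of probands with both parents genotyped
#' @param n_controls internal-control subjects (default 32)
#' @param background_variants_per_subject site-pool size (default 2000;
#'   170215 reproduces full exome scale)
#' @param common_fraction fraction of pool sites with MAF above 1%
#' @param synonymous_intronic_fraction fraction of background consequences
#'   that the consequence filter should remove
#' @param common_db_presence,rare_db_presence probability that a
#'   common/rare site is known to dbSNP (and usually 1000 Genomes); unknown
#'   sites carry no population frequency and survive the frequency step
#' @param planted_scenarios list of [plant_spec()] entries
#' @param seed RNG seed; identical configs give identical cohorts
#' @return validated config list
#' @export
cohort_config <- function(n_probands = 28, trio_fraction = 0.5,
                          n_controls = 32,
                          background_variants_per_subject = 2000,
                          common_fraction = 0.9,
                          synonymous_intronic_fraction = 0.6,
                          common_db_presence = 0.99,
                          rare_db_presence = 0.3,
                          planted_scenarios = list(), seed = 1) {
  fr <- c(trio_fraction, common_fraction, synonymous_intronic_fraction,
          common_db_presence, rare_db_presence)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (n_probands < 1 || n_controls < 0 || background_variants_per_subject < 1) {
    abort("counts must be positive")
  }
  n_planted <- sum(vapply(planted_scenarios, `[[`, numeric(1), "count"))
  if (n_planted > n_probands) {
    abort("sum of planted counts exceeds n_probands")
  }
  list(n_probands = n_probands, trio_fraction = trio_fraction,
       n_controls = n_controls,
       background_variants_per_subject = background_variants_per_subject,
       common_fraction = common_fraction,
       synonymous_intronic_fraction = synonymous_intronic_fraction,
       common_db_presence = common_db_presence,
       rare_db_presence = rare_db_presence,
       planted_scenarios = planted_scenarios, seed = seed)
}

PLANT_SCENARIOS <- c("ar_hom", "ar_compound_het", "xl_hemizygous",
                     "de_novo_ad", "decoy_single_het_ar",
                     "decoy_ad_nonsegregating")
CAUSAL_SCENARIOS <- c("ar_hom", "ar_compound_het", "xl_hemizygous",
                      "de_novo_ad")

#' One planted-genotype specification
#' @param scenario one of ar_hom, ar_compound_het, xl_hemizygous,
#'   de_novo_ad, decoy_single_het_ar, decoy_ad_nonsegregating
#' @param gene_source "panel" (a panel gene with the required mode) or
#'   "genome_wide"
#' @param count number of probands receiving this plant
#' @return plant spec list
#' @export
plant_spec <- function(scenario, gene_source = "panel", count = 1) {
  scenario <- match.arg(scenario, PLANT_SCENARIOS)
  gene_source <- match.arg(gene_source, c("panel", "genome_wide"))
  list(scenario = scenario, gene_source = gene_source, count = count)
}

# genotype codes: 0 hom_ref, 1 het, 2 hom_alt, 3 hemizygous-alt
code_to_zygosity <- c("hom_ref", "het", "hom_alt", "hemizygous")

# Hardy-Weinberg genotype codes for one subject over all sites
sample_genotype_codes <- function(maf, male, x_np) {
  n <- length(maf)
  g <- stats::rbinom(n, 2L, maf)
  if (male && any(x_np)) {
    g[x_np] <- 3L * stats::rbinom(sum(x_np), 1L, maf[x_np])
  }
  g
}

# allele transmitted by a parent at each site (X non-PAR handled by caller)
transmit_allele <- function(codes) {
  a <- as.integer(codes == 2L | codes == 3L)
  het <- codes == 1L
  a[het] <- stats::rbinom(sum(het), 1L, 0.5)
  a
}

# Mendelian child codes from parental codes
child_codes <- function(father, mother, child_male, x_np) {
  fa <- transmit_allele(father)
  ma <- transmit_allele(mother)
  g <- fa + ma
  if (any(x_np)) {
    if (child_male) {
      g[x_np] <- 3L * ma[x_np]  # son: maternal X only
    } else {
      # daughter: paternal X is the father's single haplotype
      g[x_np] <- as.integer(father[x_np] == 3L) + ma[x_np]
    }
  }
  g
}

#' Simulate an internal-control genotype matrix
#'
#' Draws Hardy-Weinberg genotypes at the supplied per-site minor allele
#' frequencies for `n_controls` subjects; used both inside
#' [generate_cohort()] and directly for calibration checks. Codes: 0
#' hom_ref, 1 het, 2 hom_alt, 3 hemizygous-alt.
#'
#' @param maf numeric vector of site MAFs
#' @param n_controls number of control subjects
#' @param x_np logical vector marking X non-PAR sites (default none)
#' @param sexes optional control sexes ("male"/"female"); random otherwise
#' @param variant_ids optional rownames
#' @return integer matrix, sites x controls
#' @export
simulate_control_matrix <- function(maf, n_controls, x_np = NULL,
                                    sexes = NULL, variant_ids = NULL) {
  x_np <- x_np %||% rep(FALSE, length(maf))
  sexes <- sexes %||% ifelse(stats::rbinom(n_controls, 1, 0.5) == 1,
                             "male", "female")
  m <- vapply(seq_len(n_controls), function(j) {
    sample_genotype_codes(maf, sexes[j] == "male", x_np)
  }, integer(length(maf)))
  m <- matrix(m, nrow = length(maf), ncol = n_controls)
  rownames(m) <- variant_ids
  attr(m, "sexes") <- sexes
  m
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

# a gene "view" as used by the planting helpers
gene_view <- function(panel, symbol) {
  list(symbol = symbol, modes = panel_modes(panel, symbol),
       exons = panel$exons[panel$exons$symbol == symbol, , drop = FALSE])
}

# pick exonic positions inside a gene
gene_positions <- function(gene, k) {
  ex <- gene$exons
  if (nrow(ex) == 0) abort(paste0("gene ", gene$symbol, " has no exons"))
  if (nrow(ex) == 1 && (ex$end[1] - ex$start[1]) < (k - 1)) {
    abort(paste0("gene ", gene$symbol, " cannot host ", k, " distinct loci"))
  }
  rows <- ex[rep_len(seq_len(nrow(ex)), k), ]
  pos <- integer(k)
  for (i in seq_len(k)) {
    repeat {
      p <- rows$start[i] + sample.int(rows$end[i] - rows$start[i] + 1L, 1) - 1L
      if (!p %in% pos[seq_len(i - 1)]) break
    }
    pos[i] <- p
  }
  tibble(chrom = rows$chrom, pos = pos)
}

# a rare, damaging, non-synonymous planted variant row; maf_max matches the
# mode-specific rarity a qualifying causal allele must satisfy
planted_variant_rows <- function(gene, k, maf_max = 2e-3) {
  loci <- gene_positions(gene, k)
  al <- random_alleles(k)
  maf <- 10^stats::runif(k, log10(1e-5), log10(maf_max))
  known <- stats::rbinom(k, 1, 0.5) == 1
  tibble(
    chrom = loci$chrom, pos = loci$pos, ref = al$ref, alt = al$alt,
    gene = gene$symbol, cdna_change = NA_character_,
    protein_change = NA_character_, consequence = "missense",
    dbsnp_maf = ifelse(known, maf, NA_real_), kg_maf = NA_real_,
    exac_ac = ifelse(known, pmax(1, round(maf * 121000)), NA_real_),
    exac_an = ifelse(known, 121000, NA_real_),
    exac_hom = ifelse(known, 0, NA_real_), nbk_maf = NA_real_,
    pp2 = stats::runif(k, 0.8, 1),
    mutation_taster = "disease_causing",
    provean = stats::runif(k, -9, -3), sift = stats::runif(k, 0, 0.04),
    hgmd_listed = FALSE, conservation_depth = sample(3:4, k, replace = TRUE),
    site_maf = maf
  )
}

#' Plant a compound-heterozygous genotype in one recessive gene
#'
#' Creates two rare non-synonymous variants at distinct exonic loci of an
#' AR-mode gene and the genotype rows realising the requested phase: in
#' trans, the father carries allele A and the mother allele B (each
#' heterozygous) and the proband both; in cis, one parent carries both
#' alleles on the same haplotype. Parents absent from the pedigree simply
#' contribute no genotype rows, which downstream analysis reports as a
#' presumed (unconfirmed) compound heterozygote.
#'
#' @param pedigree one pedigree row
#' @param gene gene view (list with `symbol`, `modes`, `exons`, e.g. from a
#'   panel); must have the AR mode
#' @param phase "trans" or "cis"
#' @return list with `variants` (2-row annotation tibble) and `genotypes`
#'   (tibble subject_id, variant_id, zygosity)
#' @export
plant_compound_het <- function(pedigree, gene, phase = c("trans", "cis")) {
  phase <- match.arg(phase)
  if (!"AR" %in% gene$modes) {
    abort(paste0("gene ", gene$symbol, " lacks the AR mode"))
  }
  v <- planted_variant_rows(gene, 2)
  vid <- variant_id(v$chrom, v$pos, v$ref, v$alt)
  g <- tibble(subject_id = rep(pedigree$proband_id, 2), variant_id = vid,
              zygosity = "het")
  if (phase == "trans") {
    if (!is.na(pedigree$father_id)) {
      g <- bind_rows(g, tibble(subject_id = pedigree$father_id,
                               variant_id = vid[1], zygosity = "het"))
    }
    if (!is.na(pedigree$mother_id)) {
      g <- bind_rows(g, tibble(subject_id = pedigree$mother_id,
                               variant_id = vid[2], zygosity = "het"))
    }
  } else {
    carrier <- if (!is.na(pedigree$mother_id)) pedigree$mother_id
               else pedigree$father_id
    if (!is.na(carrier)) {
      g <- bind_rows(g, tibble(subject_id = carrier, variant_id = vid,
                               zygosity = "het"))
    }
  }
  list(variants = v, genotypes = g)
}

plant_genotypes <- function(scenario, pedigree, panel) {
  pick_gene <- function(mode) {
    has <- vapply(panel$genes$symbol, function(s)
      mode %in% panel_modes(panel, s), logical(1))
    if (!any(has)) {
      abort(paste0("panel lacks a gene with mode ", mode,
                   " required by scenario ", scenario))
    }
    gene_view(panel, sample(panel$genes$symbol[has], 1))
  }
  pid <- pedigree$proband_id
  fid <- pedigree$father_id
  mid <- pedigree$mother_id
  row <- function(subj, vid, zyg) tibble(subject_id = subj, variant_id = vid,
                                         zygosity = zyg)
  if (scenario == "ar_compound_het") {
    gene <- pick_gene("AR")
    out <- plant_compound_het(pedigree, gene, "trans")
    return(c(out, list(gene = gene$symbol)))
  }
  if (scenario == "ar_hom") {
    gene <- pick_gene("AR")
    v <- planted_variant_rows(gene, 1)
  } else if (scenario == "xl_hemizygous") {
    gene <- pick_gene("XL")
    v <- planted_variant_rows(gene, 1)
  } else if (scenario == "de_novo_ad") {
    # dominant causal alleles must clear the stricter dominant rarity cut
    gene <- pick_gene("AD")
    v <- planted_variant_rows(gene, 1, maf_max = 3e-4)
  } else if (scenario == "decoy_single_het_ar") {
    gene <- pick_gene("AR")
    v <- planted_variant_rows(gene, 1)
  } else if (scenario == "decoy_ad_nonsegregating") {
    gene <- pick_gene("AD")
    v <- planted_variant_rows(gene, 1, maf_max = 3e-4)
  } else {
    abort(paste0("unknown scenario ", scenario))
  }
  vid <- variant_id(v$chrom, v$pos, v$ref, v$alt)
  g <- switch(scenario,
    ar_hom = {
      gg <- row(pid, vid, "hom_alt")
      if (!is.na(fid)) gg <- bind_rows(gg, row(fid, vid, "het"))
      if (!is.na(mid)) gg <- bind_rows(gg, row(mid, vid, "het"))
      gg
    },
    xl_hemizygous = {
      gg <- row(pid, vid, "hemizygous")
      if (!is.na(mid)) gg <- bind_rows(gg, row(mid, vid, "het"))
      gg
    },
    de_novo_ad = {
      if (is.na(fid) || is.na(mid)) {
        abort("de_novo_ad plant requires a genotyped trio")
      }
      row(pid, vid, "het")  # parents stay reference
    },
    decoy_single_het_ar = {
      gg <- row(pid, vid, "het")
      if (!is.na(mid)) gg <- bind_rows(gg, row(mid, vid, "het"))
      gg
    },
    decoy_ad_nonsegregating = {
      if (is.na(mid)) {
        abort("decoy_ad_nonsegregating plant requires a genotyped mother")
      }
      bind_rows(row(pid, vid, "het"), row(mid, vid, "het"))
    }
  )
  list(variants = v, genotypes = g, gene = gene$symbol)
}

#' Generate a synthetic cohort
#'
#' See [cohort_config()] for the generative model. Probands are allocated
#' to planted scenarios first (plants that need parental genotypes claim
#' the trio slots); background genotypes are Hardy-Weinberg at each site's
#' MAF with Mendelian transmission inside trios; planted genotypes are laid
#' down at fresh exonic loci of panel genes with the required inheritance
#' mode. Internal controls never carry a planted causal allele in the
#' homozygous or hemizygous state (they are unaffected), though they may be
#' heterozygous carriers. The truth table records every plant.
#'
#' @param config from [cohort_config()]
#' @param panel an `nshl_panel` (default [default_panel()])
#' @return an `nshl_cohort` list: `subjects`, `pedigrees`, `variants`,
#'   `genotypes` (carrier rows only), `controls` (code matrix), `panel`,
#'   `truth`, `config`
#' @export
generate_cohort <- function(config, panel = default_panel()) {
  set.seed(config$seed)
  n <- config$n_probands

  # scenario allocation: plants first, in spec order
  scen <- rep(NA_character_, n)
  k <- 1L
  for (ps in config$planted_scenarios) {
    if (ps$count == 0) next
    scen[k:(k + ps$count - 1L)] <- ps$scenario
    k <- k + ps$count
  }
  needs_parents <- scen %in% c("de_novo_ad", "decoy_ad_nonsegregating")
  n_trio <- round(config$trio_fraction * n)
  if (sum(needs_parents) > n_trio) {
    abort("trio_fraction provides too few trios for the parent-dependent plants")
  }
  trio <- rep(FALSE, n)
  trio[needs_parents] <- TRUE
  extra <- n_trio - sum(trio)
  if (extra > 0) trio[which(!trio)[seq_len(extra)]] <- TRUE

  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
  sex[scen %in% "xl_hemizygous"] <- "male"

  ids <- sprintf("SIM%03d", seq_len(n))
  pedigrees <- tibble(
    family_id = ids, proband_id = ids,
    father_id = ifelse(trio, paste0(ids, "-F"), NA_character_),
    mother_id = ifelse(trio, paste0(ids, "-M"), NA_character_),
    proband_sex = sex, trio = trio
  )
  subjects <- tibble(subject_id = ids, family_id = ids, sex = sex,
                     eva = FALSE, scenario = scen)

  # --- background site pool ---
  B <- config$background_variants_per_subject
  chrom <- sample(c(as.character(1:22), "X"), B, replace = TRUE)
  pos <- sample.int(147000000L, B, replace = TRUE) + 3000000L
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  al <- random_alleles(B)
  vid <- variant_id(chrom, pos, al$ref, al$alt)
  keep <- !duplicated(vid)
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- al$ref[keep]; alt <- al$alt[keep]; vid <- vid[keep]
  B <- length(vid)

  common <- stats::rbinom(B, 1, config$common_fraction) == 1
  maf <- numeric(B)
  maf[common] <- stats::runif(sum(common), 0.02, 0.5)
  maf[!common] <- 10^stats::runif(sum(!common), log10(1e-6), log10(5e-3))

  syn <- stats::rbinom(B, 1, config$synonymous_intronic_fraction) == 1
  consequence <- character(B)
  consequence[syn] <- sample(c("synonymous", "intronic"), sum(syn),
                             replace = TRUE)
  consequence[!syn] <- sample(
    c("missense", "nonsense", "frameshift_deletion", "frameshift_insertion",
      "inframe_indel", "splice_site"),
    sum(!syn), replace = TRUE,
    prob = c(0.8, 0.05, 0.03, 0.03, 0.04, 0.05))

  known <- stats::rbinom(B, 1, ifelse(common, config$common_db_presence,
                                      config$rare_db_presence)) == 1
  kg_known <- known & stats::rbinom(B, 1, 0.9) == 1
  exac_known <- known & stats::rbinom(B, 1, 0.9) == 1
  nbk_known <- stats::rbinom(B, 1, 0.4) == 1 & known
  exac_an <- 121000
  exac_ac <- ifelse(exac_known, pmax(1, round(maf * exac_an)), NA_real_)

  mt_lab <- sample(c("disease_causing", "polymorphism"), B, replace = TRUE,
                   prob = c(0.05, 0.95))
  scored <- stats::rbinom(B, 1, 0.8) == 1
  # synthetic non-panel gene symbols; ~8 consecutive sorted sites share one
  genes <- sprintf("BG%05d", (seq_len(B) - 1L) %/% 8L + 1L)

  variants <- tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = genes,
    cdna_change = NA_character_, protein_change = NA_character_,
    consequence = consequence,
    dbsnp_maf = ifelse(known, maf, NA_real_),
    kg_maf = ifelse(kg_known, maf, NA_real_),
    exac_ac = exac_ac,
    exac_an = ifelse(exac_known, exac_an, NA_real_),
    exac_hom = ifelse(exac_known, round(maf^2 * exac_an / 2), NA_real_),
    nbk_maf = ifelse(nbk_known, maf, NA_real_),
    pp2 = ifelse(scored, stats::rbeta(B, 1, 6), NA_real_),
    mutation_taster = ifelse(scored, mt_lab, NA_character_),
    provean = ifelse(scored, stats::rnorm(B, -0.5, 1.2), NA_real_),
    sift = ifelse(scored, stats::rbeta(B, 3, 2), NA_real_),
    hgmd_listed = FALSE,
    conservation_depth = sample(0:4, B, replace = TRUE,
                                prob = c(0.35, 0.25, 0.2, 0.12, 0.08))
  )
  site_maf <- maf
  x_np <- is_x_nonpar(chrom, pos)

  # --- background genotypes ---
  geno <- list()
  add_codes <- function(subject, codes) {
    nz <- which(codes > 0L)
    if (length(nz) == 0) return()
    geno[[length(geno) + 1L]] <<- tibble(
      subject_id = subject, variant_id = vid[nz],
      zygosity = code_to_zygosity[codes[nz] + 1L])
  }
  for (i in seq_len(n)) {
    male <- sex[i] == "male"
    if (trio[i]) {
      fc <- sample_genotype_codes(site_maf, TRUE, x_np)
      mc <- sample_genotype_codes(site_maf, FALSE, x_np)
      cc <- child_codes(fc, mc, male, x_np)
      if (male) cc[x_np] <- ifelse(cc[x_np] > 0L, 3L, 0L)
      add_codes(pedigrees$father_id[i], fc)
      add_codes(pedigrees$mother_id[i], mc)
      add_codes(ids[i], cc)
    } else {
      add_codes(ids[i], sample_genotype_codes(site_maf, male, x_np))
    }
  }

  controls <- simulate_control_matrix(site_maf, config$n_controls,
                                      x_np = x_np, variant_ids = vid)

  # --- plants ---
  truth <- tibble(subject_id = character(0), scenario = character(0),
                  gene = character(0), variant_ids = character(0),
                  causal = logical(0))
  plant_var <- list()
  for (i in which(!is.na(scen))) {
    ped_i <- pedigrees[i, ]
    pl <- plant_genotypes(scen[i], ped_i, panel)
    pv <- pl$variants
    pvid <- variant_id(pv$chrom, pv$pos, pv$ref, pv$alt)
    plant_var[[length(plant_var) + 1L]] <- pv
    geno[[length(geno) + 1L]] <- pl$genotypes
    truth <- bind_rows(truth, tibble(
      subject_id = ids[i], scenario = scen[i], gene = pl$gene,
      variant_ids = paste(pvid, collapse = ","),
      causal = scen[i] %in% CAUSAL_SCENARIOS))
  }

  genotypes <- bind_rows(geno)
  if (length(plant_var) > 0) {
    pv <- bind_rows(plant_var)
    pvids <- variant_id(pv$chrom, pv$pos, pv$ref, pv$alt)
    # unaffected controls may carry a planted allele but never two copies
    pm <- matrix(0L, nrow = nrow(pv), ncol = config$n_controls,
                 dimnames = list(pvids, NULL))
    ctrl_sex <- attr(controls, "sexes")
    for (r in seq_len(nrow(pv))) {
      p <- pv$site_maf[r]
      het <- stats::rbinom(config$n_controls, 1L, 2 * p * (1 - p))
      if (is_x_nonpar(pv$chrom[r], pv$pos[r])) het[ctrl_sex == "male"] <- 0L
      pm[r, ] <- het
    }
    sexes <- attr(controls, "sexes")
    controls <- rbind(controls, pm)
    attr(controls, "sexes") <- sexes
    variants <- bind_rows(variants, pv[, setdiff(names(pv), "site_maf")])
    site_maf <- c(site_maf, pv$site_maf)
  }

  # two plants can legitimately hit the same site; keep one annotation row
  all_ids <- variant_id(variants$chrom, variants$pos, variants$ref,
                        variants$alt)
  keep_row <- !duplicated(all_ids)
  variants <- variants[keep_row, , drop = FALSE]
  site_maf <- site_maf[keep_row]

  variants <- as_variant_table(variants)
  attr(variants, "site_maf") <- stats::setNames(site_maf, variants$variant_id)

  structure(list(
    subjects = subjects, pedigrees = pedigrees, variants = variants,
    genotypes = genotypes, controls = controls, panel = panel,
    truth = truth, config = config, cnv_flags = NULL
  ), class = "nshl_cohort")
}

#' @export
print.nshl_cohort <- function(x, ...) {
  cat("<nshl_cohort> ", nrow(x$subjects), " probands (",
      sum(x$pedigrees$trio), " trios), ", nrow(x$variants),
      " variant sites, ",
      if (is.null(x$controls)) 0L else ncol(x$controls),
      " internal controls\n", sep = "")
  if (!is.null(x$truth) && nrow(x$truth) > 0) {
    tab <- table(x$truth$scenario)
    cat("  plants: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Generate a per-exon capture depth table with deliberate gaps
#'
#' Every panel exon gets a mean read depth drawn around `mean_depth`
#' (truncated so covered exons stay at or above the audit threshold),
#' except a chosen set of gap exons set to depth 0: `gap_spec[1]` exons
#' marked as not targeted by the capture design and `gap_spec[2]` targeted
#' but uncovered.
#'
#' @param panel an `nshl_panel`
#' @param gap_spec integer pair (n_untargeted, n_targeted_uncovered)
#' @param mean_depth mean coverage of covered exons (default 65.8)
#' @param sd_depth standard deviation of the depth draw
#' @param threshold minimum depth of a covered exon
#' @return tibble (gene, exon_index, chrom, start, end, mean_depth, targeted)
#' @export
generate_depth_table <- function(panel, gap_spec = c(0L, 0L),
                                 mean_depth = 65.8, sd_depth = 15,
                                 threshold = 1) {
  ex <- panel$exons
  n <- nrow(ex)
  if (sum(gap_spec) > n) abort("gap counts exceed the panel exon count")
  out <- tibble(gene = ex$symbol, exon_index = ex$exon_index,
                chrom = ex$chrom, start = ex$start, end = ex$end,
                mean_depth = pmax(threshold,
                                  round(stats::rnorm(n, mean_depth, sd_depth),
                                        1)),
                targeted = TRUE)
  gap <- sample.int(n, sum(gap_spec))
  untargeted <- gap[seq_len(gap_spec[1])]
  uncovered <- setdiff(gap, untargeted)
  out$mean_depth[gap] <- 0
  out$targeted[untargeted] <- FALSE
  out
}

#' Fabricate a pair of read-depth CNV call sets for one subject
#'
#' Emulates the outputs of two independent exome CNV callers: a shared set
#' of calls with caller-specific boundary jitter, a few caller-private
#' calls, and (optionally) a homozygous deletion placed at the supplied
#' interval so consensus + bi-allelic flagging can be exercised end to end.
#'
#' @param subject_id subject label
#' @param biallelic_deletion NULL, or list(chrom, start, end) for a CN-0
#'   deletion present in both call sets
#' @param n_shared,n_private counts of shared CN-1/CN-3 noise calls and of
#'   caller-private calls
#' @return list of two call-set tibbles, `setA` and `setB`
#' @export
simulate_cnv_callsets <- function(subject_id,
                                  biallelic_deletion = list(
                                    chrom = "6", start = 30995157L,
                                    end = 30996641L),
                                  n_shared = 4, n_private = 2) {
  mk <- function(chrom, start, end, type, cn, caller) {
    tibble(subject_id = subject_id, caller = caller, chrom = chrom,
           start = as.integer(start), end = as.integer(end), type = type,
           copy_number = as.integer(cn))
  }
  rand_call <- function(caller) {
    chrom <- sample(as.character(1:22), 1)
    start <- sample.int(100000000L, 1) + 1000000L
    len <- sample(2000:50000, 1)
    type <- sample(c("deletion", "duplication"), 1)
    mk(chrom, start, start + len, type, if (type == "deletion") 1L else 3L,
       caller)
  }
  a <- list(); b <- list()
  for (i in seq_len(n_shared)) {
    base <- rand_call("EXCAVATOR")
    jit <- sample(-300:300, 2)
    a[[length(a) + 1L]] <- base
    shifted <- base
    shifted$caller <- "ExomeDepth"
    shifted$start <- base$start + jit[1]
    shifted$end <- base$end + jit[2]
    b[[length(b) + 1L]] <- shifted
  }
  for (i in seq_len(n_private)) {
    a[[length(a) + 1L]] <- rand_call("EXCAVATOR")
    b[[length(b) + 1L]] <- rand_call("ExomeDepth")
  }
  if (!is.null(biallelic_deletion)) {
    d <- biallelic_deletion
    a[[length(a) + 1L]] <- mk(d$chrom, d$start, d$end, "deletion", 0L,
                              "EXCAVATOR")
    b[[length(b) + 1L]] <- mk(d$chrom, d$start - 150L, d$end + 60L,
                              "deletion", 0L, "ExomeDepth")
  }
  list(setA = bind_rows(a), setB = bind_rows(b))
}
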