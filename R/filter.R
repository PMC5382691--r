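#' Default thresholds for the filter cascade
#'
#' `common_maf_cut` (0.01) is the population-frequency exclusion applied to
#' dbSNP / 1000 Genomes annotations (a variant is removed when strictly
#' above the cut); `ar_maf_cut` (0.005) and `ad_maf_cut` (0.0005) are the
#' mode-specific rarity requirements applied to the worst-case database
#' frequency at the ranking step (a variant is kept when strictly below the
#' cut). The in-silico damaging-call cutoffs are conventional tool defaults.
#'
#' @param common_maf_cut,ar_maf_cut,ad_maf_cut frequency cuts
#' @param pp2_cut,provean_cut,sift_cut damaging-call cutoffs
#' @return named list of thresholds
#' @export
default_thresholds <- function(common_maf_cut = 0.01, ar_maf_cut = 0.005,
                               ad_maf_cut = 0.0005, pp2_cut = 0.5,
                               provean_cut = -2.5, sift_cut = 0.05) {
  if (!(ad_maf_cut <= ar_maf_cut && ar_maf_cut <= common_maf_cut)) {
    abort("thresholds must satisfy ad_maf_cut <= ar_maf_cut <= common_maf_cut")
  }
  list(common_maf_cut = common_maf_cut, ar_maf_cut = ar_maf_cut,
       ad_maf_cut = ad_maf_cut, pp2_cut = pp2_cut, provean_cut = provean_cut,
       sift_cut = sift_cut)
}

#' Step 1: exclude common variants by population frequency
#'
#' Removes variants whose dbSNP or 1000 Genomes minor allele frequency is
#' strictly greater than `common_maf_cut`. Absent annotations never trigger
#' removal; other databases are consulted later, at the ranking step.
#'
#' @param variants variant table
#' @param thresholds see [default_thresholds()]
#' @return the surviving variant table
#' @export
filter_population_frequency <- function(variants, thresholds = default_thresholds()) {
  cut <- thresholds$common_maf_cut
  drop <- (!is.na(variants$dbsnp_maf) & variants$dbsnp_maf > cut) |
    (!is.na(variants$kg_maf) & variants$kg_maf > cut)
  variants[!drop, , drop = FALSE]
}

#' Step 2: exclude variants homozygous or hemizygous in internal controls
#'
#' The control matrix is an integer matrix (rows = variant ids, columns =
#' control subjects) coded 0 = hom_ref, 1 = het, 2 = hom_alt, 3 =
#' hemizygous-alt. A variant is removed when at least one control carries it
#' in the homozygous or hemizygous state; heterozygous carriers do not
#' exclude. Variants absent from the matrix are treated as absent from all
#' controls. `NULL` controls disable the step.
#'
#' @param variants variant table
#' @param controls control genotype matrix (or NULL)
#' @param n_controls expected number of control subjects; a mismatch warns
#' @return the surviving variant table
#' @export
filter_internal_controls <- function(variants, controls, n_controls = NULL) {
  if (is.null(controls) || nrow(variants) == 0 || ncol(controls) == 0) {
    return(variants)
  }
  if (!is.null(n_controls) && ncol(controls) != n_controls) {
    warn(paste0("control matrix has ", ncol(controls),
                " subjects, expected ", n_controls))
  }
  excl <- rownames(controls)[rowSums(controls >= 2L) > 0L]
  variants[!variants$variant_id %in% excl, , drop = FALSE]
}

#' Step 3: exclude synonymous and (non-splice) intronic variants
#'
#' Splice-site variants are encoded with their own consequence label
#' (`splice_site`, the canonical +/-2 bp dinucleotide window, assigned
#' upstream by the annotator), so the step is a label filter: it removes
#' `synonymous` and `intronic` and keeps every protein-altering class.
#' Unknown labels are an error — the consequence vocabulary is closed.
#'
#' @param variants variant table
#' @return the surviving variant table
#' @export
filter_consequence <- function(variants) {
  bad <- setdiff(unique(variants$consequence), CONSEQUENCES)
  if (length(bad) > 0) {
    abort(paste0("unknown consequence label(s): ", paste(bad, collapse = ", ")))
  }
  variants[!variants$consequence %in% c("synonymous", "intronic"), ,
           drop = FALSE]
}

#' Step 4: partition variants by panel membership
#'
#' Splits by gene-symbol membership in the panel. Both partitions are
#' preserved: the panel side feeds the known-gene diagnosis, the non-panel
#' side feeds genome-wide candidate discovery.
#'
#' @param variants variant table
#' @param panel an `nshl_panel`
#' @return list with variant tables `panel` and `nonpanel`
#' @export
partition_by_panel <- function(variants, panel) {
  in_panel <- variants$gene %in% panel$genes$symbol
  list(panel = variants[in_panel, , drop = FALSE],
       nonpanel = variants[!in_panel, , drop = FALSE])
}

#' Step 5: retain variants compatible with a causal inheritance mechanism
#'
#' Applies the recessive/sporadic genotype logic gene by gene: homozygous
#' alternate genotypes, genes with two or more heterozygous variants
#' (bi-allelic candidates, phased by the inheritance engine), hemizygous X
#' genotypes in affected males, and de novo heterozygous variants (trio
#' only) are retained; any other single heterozygous variant is dropped.
#' Heterozygous singletons in panel genes are additionally recorded as
#' observations: dominant-gene singletons get a segregation status, and
#' recessive-gene singletons are kept as "one het allele" notes that later
#' drive the uncovered-exon Sanger worklist.
#'
#' @param variants variant table (the subject's surviving variants)
#' @param genotypes genotype table
#' @param pedigree one pedigree row
#' @param panel an `nshl_panel` (used for the observation notes)
#' @param thresholds see [default_thresholds()]
#' @return list with `retained` (variant table), `mechanisms` (tibble of
#'   mechanism calls), `dropped` (tibble variant_id, reason), and
#'   `observations` (tibble subject_id, gene, variant_id, kind, status)
#' @export
filter_inheritance <- function(variants, genotypes, pedigree, panel,
                               thresholds = default_thresholds()) {
  if (is.null(pedigree) || nrow(pedigree) != 1) {
    abort("pedigree for the proband is required")
  }
  pid <- pedigree$proband_id
  mechs <- empty_mechanisms()
  obs <- tibble(subject_id = character(0), gene = character(0),
                variant_id = character(0), kind = character(0),
                status = character(0))
  if (nrow(variants) == 0) {
    return(list(retained = variants, mechanisms = mechs,
                dropped = tibble(variant_id = character(0), reason = character(0)),
                observations = obs))
  }

  g <- genotypes[genotypes$subject_id == pid &
                   genotypes$variant_id %in% variants$variant_id, ]
  zyg <- g$zygosity[match(variants$variant_id, g$variant_id)]
  zyg[is.na(zyg)] <- "hom_ref"

  keep <- rep(FALSE, nrow(variants))
  reason <- rep(NA_character_, nrow(variants))

  keep[zyg == "hom_alt"] <- TRUE
  hemi <- zyg == "hemizygous" & is_x_nonpar(variants$chrom, variants$pos) &
    identical(pedigree$proband_sex, "male")
  keep[hemi] <- TRUE

  het_idx <- which(zyg == "het")
  het_by_gene <- split(het_idx, variants$gene[het_idx])
  for (gene in names(het_by_gene)) {
    idx <- het_by_gene[[gene]]
    if (gene != "" && length(idx) >= 2) {
      keep[idx] <- TRUE
    } else {
      for (i in idx) {
        dn <- detect_de_novo(variants$variant_id[i], genotypes, pedigree)
        if (dn$is_de_novo) {
          keep[i] <- TRUE
          mechs <- bind_rows(mechs, mechanism_call(
            pid, gene, "de_novo", "not_applicable", variants$variant_id[i],
            origin1 = "de_novo"))
        } else {
          reason[i] <- "single heterozygous, not de novo"
        }
      }
    }
  }
  reason[zyg %in% c("hom_ref", "missing") & !keep] <- "not carried by proband"
  reason[zyg == "hemizygous" & !keep] <- "hemizygous outside male X"

  # mechanism calls per carried gene
  for (gene in unique(variants$gene[keep & (zyg %in% c("hom_alt", "het"))])) {
    if (gene == "") next
    gv <- variants[variants$gene == gene & zyg %in% c("hom_alt", "het") & keep, ,
                   drop = FALSE]
    if (nrow(gv) == 0) next
    bi <- detect_biallelic(gv, genotypes, pedigree, thresholds)
    bi <- bi[bi$mechanism != "de_novo", , drop = FALSE]
    mechs <- bind_rows(mechs, bi)
  }
  for (i in which(hemi)) {
    mechs <- bind_rows(mechs, mechanism_call(
      pid, variants$gene[i], "hemizygous", "not_applicable",
      variants$variant_id[i]))
  }

  # observations on panel-gene heterozygous singletons
  single_idx <- setdiff(het_idx, unlist(het_by_gene[
    vapply(het_by_gene, length, 1L) >= 2]))
  for (i in single_idx) {
    gene <- variants$gene[i]
    modes <- panel_modes(panel, gene)
    if (length(modes) == 0) next
    if ("AD" %in% modes) {
      obs <- bind_rows(obs, tibble(
        subject_id = pid, gene = gene, variant_id = variants$variant_id[i],
        kind = "ad_singleton",
        status = check_ad_segregation(variants$variant_id[i], genotypes,
                                      pedigree)))
    }
    if ("AR" %in% modes) {
      obs <- bind_rows(obs, tibble(
        subject_id = pid, gene = gene, variant_id = variants$variant_id[i],
        kind = "ar_single_het", status = "one_allele"))
    }
  }

  list(retained = variants[keep, , drop = FALSE], mechanisms = mechs,
       dropped = tibble(variant_id = variants$variant_id[!keep],
                        reason = reason[!keep]),
       observations = obs)
}

# mode-specific rarity cut for one gene: AD-only genes use the dominant cut,
# everything else (AR, XL, mixed-mode and non-panel genes under the recessive
# assumption) the recessive cut
mode_maf_cut <- function(gene, panel, thresholds) {
  modes <- panel_modes(panel, gene)
  if (length(modes) > 0 && identical(modes, "AD")) {
    thresholds$ad_maf_cut
  } else {
    thresholds$ar_maf_cut
  }
}

#' Step 6: mode-specific rarity refilter and ranking
#'
#' First re-filters on the worst-case database frequency ([max_maf()]):
#' variants in AD-only genes must be strictly below `ad_maf_cut`, all other
#' variants strictly below `ar_maf_cut`. Survivors are ranked by the number
#' of damaging in-silico calls (descending), conservation depth
#' (descending), worst-case frequency (ascending), and variant id as the
#' stable tie-break.
#'
#' @param variants variant table
#' @param thresholds see [default_thresholds()]
#' @param panel an `nshl_panel`
#' @return the surviving variants, ranked, with columns `n_damaging`,
#'   `max_maf` and `rank` appended
#' @export
rank_variants <- function(variants, thresholds = default_thresholds(),
                          panel = NULL) {
  cuts <- vapply(variants$gene, mode_maf_cut, numeric(1),
                 panel = panel, thresholds = thresholds)
  mm <- max_maf(variants)
  out <- variants[mm < cuts, , drop = FALSE]
  out$n_damaging <- damaging_calls(out, thresholds)
  out$max_maf <- max_maf(out)
  out <- out[rank_key_order(out, thresholds), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

cascade_steps <- c("raw", "population_frequency", "internal_controls",
                   "consequence", "panel_restriction", "inheritance",
                   "rank_maf")

#' Run the six-step filter cascade for one subject
#'
#' Executes the prioritization pipeline in order — population frequency,
#' internal controls, consequence class, panel restriction, inheritance
#' mechanism, mode-specific rarity + ranking — recording the surviving
#' count after every step and the first step that removed each variant.
#' Known-gene (panel) evaluation comes first; genome-wide candidate
#' discovery runs only when the panel yields no diagnostic genotype (or when
#' `force_candidate = TRUE`), in which case the inheritance and ranking
#' steps operate on the full post-consequence variant set.
#'
#' @param subject_id proband id
#' @param cohort a cohort list with elements `variants`, `genotypes`,
#'   `controls`, `pedigrees`, `panel` (see [load_published_cohort()],
#'   [generate_cohort()])
#' @param thresholds see [default_thresholds()]
#' @param force_candidate run candidate discovery even when the panel is
#'   diagnostic
#' @return a `FilterTrace`-style list: `subject_id`, `step_counts` (tibble
#'   step, n), `retained` (ranked variant table), `excluded_reasons` (tibble
#'   variant_id, step, reason), `mechanisms`, `observations`,
#'   `diagnostic_panel` (logical), `path` ("panel" or "candidate")
#' @export
run_cascade <- function(subject_id, cohort, thresholds = default_thresholds(),
                        force_candidate = FALSE) {
  ped <- cohort$pedigrees[cohort$pedigrees$proband_id == subject_id, ]
  if (nrow(ped) != 1) {
    abort(paste0("pedigree missing for proband ", subject_id))
  }
  g <- cohort$genotypes[cohort$genotypes$subject_id == subject_id, ]
  carried <- g$variant_id[g$zygosity %in% c("het", "hom_alt", "hemizygous")]
  raw <- cohort$variants[cohort$variants$variant_id %in% carried, , drop = FALSE]

  reasons <- tibble(variant_id = character(0), step = character(0),
                    reason = character(0))
  note_excluded <- function(prev, cur, step, why) {
    gone <- setdiff(prev$variant_id, cur$variant_id)
    if (length(gone) == 0) return(reasons)
    bind_rows(reasons, tibble(variant_id = gone, step = step, reason = why))
  }

  s1 <- filter_population_frequency(raw, thresholds)
  reasons <- note_excluded(raw, s1, "population_frequency", "common in dbSNP/1000G")
  s2 <- filter_internal_controls(s1, cohort$controls)
  reasons <- note_excluded(s1, s2, "internal_controls",
                           "homozygous/hemizygous in internal controls")
  s3 <- filter_consequence(s2)
  reasons <- note_excluded(s2, s3, "consequence", "synonymous or intronic")

  parts <- partition_by_panel(s3, cohort$panel)

  inh_panel <- filter_inheritance(parts$panel, cohort$genotypes, ped,
                                  cohort$panel, thresholds)
  ranked_panel <- rank_variants(inh_panel$retained, thresholds, cohort$panel)
  panel_mechs <- finalize_mechanisms(inh_panel$mechanisms, ranked_panel,
                                     cohort$panel, cohort$genotypes, ped)
  diagnostic <- any(panel_mechs$diagnostic)

  if (diagnostic && !force_candidate) {
    path <- "panel"
    active <- parts$panel
    inh <- inh_panel
    ranked <- ranked_panel
    mechs <- panel_mechs
    reasons <- note_excluded(s3, active, "panel_restriction",
                             "outside the known-gene panel")
  } else {
    path <- "candidate"
    active <- s3
    inh <- filter_inheritance(active, cohort$genotypes, ped, cohort$panel,
                              thresholds)
    ranked <- rank_variants(inh$retained, thresholds, cohort$panel)
    mechs <- finalize_mechanisms(inh$mechanisms, ranked, cohort$panel,
                                 cohort$genotypes, ped)
  }
  reasons <- bind_rows(
    reasons,
    inh$dropped %>%
      filter(.data$variant_id %in% active$variant_id) %>%
      mutate(step = "inheritance") %>%
      select("variant_id", "step", "reason"),
    tibble(variant_id = setdiff(inh$retained$variant_id, ranked$variant_id),
           step = "rank_maf", reason = "above mode-specific MAF cut")
  )

  counts <- tibble(
    step = cascade_steps,
    n = c(nrow(raw), nrow(s1), nrow(s2), nrow(s3), nrow(active),
          nrow(inh$retained), nrow(ranked))
  )
  structure(list(
    subject_id = subject_id, step_counts = counts, retained = ranked,
    excluded_reasons = reasons, mechanisms = mechs,
    observations = inh_panel$observations,
    diagnostic_panel = diagnostic, path = path
  ), class = "nshl_trace")
}

# keep only mechanisms whose supporting variants survived the rarity
# refilter, then attach mode/segregation-aware diagnostic eligibility
finalize_mechanisms <- function(mechs, ranked, panel, genotypes, pedigree) {
  if (nrow(mechs) == 0) {
    mechs$diagnostic <- logical(0)
    mechs$segregation <- character(0)
    return(mechs)
  }
  ok <- mechs$var1 %in% ranked$variant_id &
    (is.na(mechs$var2) | mechs$var2 %in% ranked$variant_id)
  mechs <- mechs[ok, , drop = FALSE]
  if (nrow(mechs) == 0) {
    mechs$diagnostic <- logical(0)
    mechs$segregation <- character(0)
    return(mechs)
  }
  mechs$segregation <- vapply(seq_len(nrow(mechs)), function(i) {
    if (mechs$mechanism[i] == "de_novo") {
      check_ad_segregation(mechs$var1[i], genotypes, pedigree)
    } else NA_character_
  }, character(1))
  mechs$diagnostic <- vapply(seq_len(nrow(mechs)), function(i) {
    is_diagnostic_mechanism(mechs[i, ], panel_modes(panel, mechs$gene[i]),
                            mechs$segregation[i] %||% "indeterminate")
  }, logical(1))
  mechs
}

#' @export
print.nshl_trace <- function(x, ...) {
  cat("<nshl_trace> subject ", x$subject_id, " (", x$path, " path)\n", sep = "")
  for (i in seq_len(nrow(x$step_counts))) {
    cat(sprintf("  %-22s %d\n", x$step_counts$step[i], x$step_counts$n[i]))
  }
  if (nrow(x$mechanisms) > 0) {
    cat("  mechanisms: ",
        paste(x$mechanisms$gene, x$mechanisms$mechanism, sep = "/",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
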