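#' Load the bundled reconstruction of the published 28-subject cohort
#'
#' Reads the fixture files under `inst/extdata/published_cohort/`: the subject table
#' (sex and imaging status), the PED pedigrees (parents are present only
#' where segregation DNA was available), the genotype table transcribed from
#' the published mutation tables, the variant annotations, and the two CNV
#' call sets, then computes the CNV consensus and bi-allelic deletion flags.
#' The fixture is a synthetic reconstruction — diagnostic alleles follow the
#' published tables, coordinates and supplementary-only alleles are
#' documented stand-ins (see the README next to the files).
#'
#' @param panel panel to attach (default [default_panel()])
#' @return an `nshl_cohort`-style list with elements `subjects`,
#'   `pedigrees`, `variants`, `genotypes`, `controls` (none), `panel`,
#'   `cnv_consensus`, `cnv_flags`
#' @export
load_published_cohort <- function(panel = default_panel()) {
  dir <- system.file("extdata", "published_cohort", package = "nshldx")
  subjects <- readr::read_tsv(file.path(dir, "subjects.tsv"),
                              show_col_types = FALSE)
  pedigrees <- read_pedigrees(file.path(dir, "pedigrees.ped"))
  variants <- as_variant_table(
    readr::read_tsv(file.path(dir, "variants.tsv"), show_col_types = FALSE,
                    col_types = readr::cols(chrom = readr::col_character())))
  genotypes <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                               show_col_types = FALSE)
  stopifnot(all(genotypes$variant_id %in% variants$variant_id))

  cnv_a <- readr::read_tsv(file.path(dir, "cnv_excavator.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(chrom = readr::col_character()))
  cnv_b <- readr::read_tsv(file.path(dir, "cnv_exomedepth.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(chrom = readr::col_character()))
  gene_exons <- readr::read_tsv(file.path(dir, "candidate_gene_exons.tsv"),
                                show_col_types = FALSE,
                                col_types = readr::cols(chrom = readr::col_character()))

  subj_cnv <- intersect(unique(cnv_a$subject_id), unique(cnv_b$subject_id))
  consensus <- bind_rows(lapply(subj_cnv, function(s) {
    consensus_calls(cnv_a[cnv_a$subject_id == s, ],
                    cnv_b[cnv_b$subject_id == s, ])
  }))
  flags <- flag_biallelic_deletions(consensus, gene_exons)

  structure(list(
    subjects = subjects, pedigrees = pedigrees, variants = variants,
    genotypes = genotypes, controls = NULL, panel = panel,
    cnv_consensus = consensus, cnv_flags = flags,
    candidate_gene_exons = gene_exons
  ), class = "nshl_cohort")
}
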