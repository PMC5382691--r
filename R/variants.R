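#' @importFrom dplyr %>% arrange bind_rows case_when desc distinct filter group_by
#'   left_join mutate n pull rename row_number select semi_join summarise ungroup
#'   anti_join across all_of
#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
NULL

#' Closed set of functional consequence labels
#'
#' Consequence annotations are restricted to this closed vocabulary; the
#' consequence filter errors on anything else rather than silently passing
#' unknown labels through.
#' @export
CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift_insertion", "frameshift_deletion",
  "inframe_indel", "splice_site", "synonymous", "intronic", "other"
)

#' Zygosity levels for genotype calls
#' @export
ZYGOSITIES <- c("hom_ref", "het", "hom_alt", "hemizygous", "missing")

#' Inheritance modes recognised for panel genes
#' @export
INHERITANCE_MODES <- c("AR", "AD", "XL")

# hg19 X pseudo-autosomal regions, 1-based inclusive
PAR1_X <- c(60001L, 2699520L)
PAR2_X <- c(154931044L, 155260560L)

#' Is a position on the X chromosome outside the pseudo-autosomal regions?
#'
#' Male genotypes are single-copy (hemizygous) only outside PAR1/PAR2 (hg19
#' coordinates). Chromosome names are accepted with or without a "chr" prefix.
#'
#' @param chrom character vector of chromosome names
#' @param pos integer vector of 1-based positions
#' @return logical vector
#' @export
is_x_nonpar <- function(chrom, pos) {
  cc <- sub("^chr", "", as.character(chrom))
  is_x <- cc %in% c("X", "x")
  in_par <- (pos >= PAR1_X[1] & pos <= PAR1_X[2]) |
    (pos >= PAR2_X[1] & pos <= PAR2_X[2])
  is_x & !in_par
}

#' Build the canonical variant identifier
#'
#' One normalized allele per identifier: `chrom:pos:ref:alt`.
#' @param chrom,pos,ref,alt vectors describing one decomposed allele each
#' @return character vector of identifiers
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# template with every column a variant table may carry; annotation columns
# default to NA (= annotation absent)
variant_columns <- function() {
  tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    cdna_change = character(), protein_change = character(),
    consequence = character(),
    dbsnp_maf = double(), kg_maf = double(),
    exac_ac = double(), exac_an = double(), exac_hom = double(),
    nbk_maf = double(),
    pp2 = double(), mutation_taster = character(),
    provean = double(), sift = double(),
    hgmd_listed = logical(), conservation_depth = integer()
  )
}

#' Assemble and validate a variant table
#'
#' Takes any data frame with at least `chrom`, `pos`, `ref`, `alt`,
#' `consequence` columns, fills in missing annotation columns as absent (NA),
#' computes `variant_id`, and enforces the domain invariants: positions are
#' 1-based (>= 1), ref differs from alt, exactly one alternate allele per row
#' (no commas), consequence labels come from [CONSEQUENCES], frequencies lie
#' in [0, 1], and ExAC allele counts do not exceed allele numbers.
#'
#' @param df data frame of variant records
#' @return validated tibble, one row per normalized allele
#' @export
as_variant_table <- function(df) {
  df <- as_tibble(df)
  tmpl <- variant_columns()
  for (col in setdiff(names(tmpl), names(df))) {
    df[[col]] <- rep(tmpl[[col]][NA_integer_], length.out = nrow(df))
  }
  df$pos <- as.integer(df$pos)
  df$conservation_depth <- as.integer(df$conservation_depth)
  df$variant_id <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  df <- df[, names(tmpl)]

  if (any(df$pos < 1, na.rm = TRUE)) abort("variant positions must be >= 1 (1-based)")
  if (any(df$ref == df$alt)) abort("ref and alt alleles must differ")
  if (any(grepl(",", df$alt, fixed = TRUE))) {
    abort("multi-allelic records must be decomposed to one alt per row")
  }
  bad <- setdiff(unique(df$consequence), CONSEQUENCES)
  if (length(bad) > 0) {
    abort(paste0("unknown consequence label(s): ", paste(bad, collapse = ", ")))
  }
  for (col in c("dbsnp_maf", "kg_maf", "nbk_maf", "pp2", "sift")) {
    x <- df[[col]]
    if (any(x < 0 | x > 1, na.rm = TRUE)) abort(paste0(col, " must lie in [0, 1]"))
  }
  both <- !is.na(df$exac_ac) & !is.na(df$exac_an)
  if (any(df$exac_ac[both] > df$exac_an[both])) abort("exac_ac must be <= exac_an")
  if (any(df$exac_an <= 0, na.rm = TRUE)) abort("exac_an must be > 0 when present")
  if (anyDuplicated(df$variant_id)) {
    abort("duplicate variant identifiers after normalization")
  }
  df
}

#' Maximum reported minor allele frequency across databases
#'
#' Collapses the per-database frequency annotations (dbSNP, 1000 Genomes,
#' ExAC as AC/AN, National Biobank of Korea) into the single worst-case
#' frequency used for mode-specific rarity thresholds. Absent annotations do
#' not contribute; a variant absent from every database gets 0, so that
#' unobserved alleles are treated as rare rather than discarded.
#'
#' @param variants a variant table (see [as_variant_table()])
#' @return numeric vector in [0, 1], one value per row
#' @export
max_maf <- function(variants) {
  exac <- ifelse(
    !is.na(variants$exac_ac) & !is.na(variants$exac_an),
    variants$exac_ac / variants$exac_an, NA_real_
  )
  m <- pmax(variants$dbsnp_maf, variants$kg_maf, exac, variants$nbk_maf,
            na.rm = TRUE)
  m[!is.finite(m)] <- 0
  pmax(m, 0)
}

#' Count damaging in-silico predictions for each variant
#'
#' A variant collects one "damaging" vote from each tool that calls it
#' deleterious at the conventional tool default: PolyPhen-2 HumVar >= 0.5,
#' MutationTaster "disease_causing", PROVEAN <= -2.5, SIFT <= 0.05. Absent
#' scores are neutral (no vote).
#'
#' @param variants a variant table
#' @param thresholds threshold set, see [default_thresholds()]
#' @return integer vector of damaging-call counts (0-4)
#' @export
damaging_calls <- function(variants, thresholds = default_thresholds()) {
  n <- (!is.na(variants$pp2) & variants$pp2 >= thresholds$pp2_cut) +
    (!is.na(variants$mutation_taster) &
       variants$mutation_taster == "disease_causing") +
    (!is.na(variants$provean) & variants$provean <= thresholds$provean_cut) +
    (!is.na(variants$sift) & variants$sift <= thresholds$sift_cut)
  as.integer(n)
}

# deterministic priority order used for ranking and tie-breaks: more damaging
# votes first, deeper conservation first, rarer first, then lexicographic id
rank_key_order <- function(variants, thresholds = default_thresholds()) {
  order(
    -damaging_calls(variants, thresholds),
    -ifelse(is.na(variants$conservation_depth), 0L, variants$conservation_depth),
    max_maf(variants),
    variants$variant_id
  )
}

#' The species conservation ladder
#'
#' Conservation of the mutated residue is encoded as an ordinal over a fixed
#' species ladder: the rank of the most distant species in which the residue
#' is still conserved (0 = not conserved). The ladder ships as a plain-text
#' config file and can be swapped for another ordering.
#'
#' @param path optional path to a two-column TSV (rank, species)
#' @return tibble with columns `rank` and `species`
#' @export
conservation_ladder <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "conservation_ladder.tsv", package = "nshldx")
  readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(), species = readr::col_character()
  ))
}
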