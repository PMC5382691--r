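#' Read pedigrees from a 6-column PED file
#'
#' Standard PED columns: family, individual, father, mother, sex (1 = male,
#' 2 = female), phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown).
#' Each affected individual becomes one proband record; a parent id is kept
#' only when that parent has their own PED row (i.e. DNA/genotypes are
#' available for segregation), matching the simplex study design where
#' parents are recruited only when available.
#'
#' @param path path to the PED file
#' @return tibble with one row per proband: `family_id`, `proband_id`,
#'   `father_id`, `mother_id` (NA when untyped), `proband_sex`
#'   ("male"/"female"), `trio` (both parents typed)
#' @export
read_pedigrees <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "id", "father", "mother",
                                         "sex", "phenotype"))
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  affected <- ped[ped$phenotype == 2, , drop = FALSE]
  if (nrow(affected) == 0) abort("PED file contains no affected individuals")
  typed <- ped$id
  out <- tibble(
    family_id = affected$family_id,
    proband_id = affected$id,
    father_id = ifelse(affected$father %in% typed, affected$father, NA_character_),
    mother_id = ifelse(affected$mother %in% typed, affected$mother, NA_character_),
    proband_sex = ifelse(affected$sex == 1, "male", "female")
  )
  if (any(out$proband_id == out$father_id, na.rm = TRUE) ||
      any(out$proband_id == out$mother_id, na.rm = TRUE)) {
    abort("proband id equals a parent id")
  }
  out$trio <- !is.na(out$father_id) & !is.na(out$mother_id)
  out
}

# all pedigree member ids that carry genotype data
pedigree_members <- function(pedigrees) {
  unique(stats::na.omit(c(pedigrees$proband_id, pedigrees$father_id,
                          pedigrees$mother_id)))
}

# GT string -> zygosity, given subject sex and locus location
gt_to_zygosity <- function(gt, male, x_nonpar) {
  gt <- sub("\\|", "/", gt)
  alleles <- strsplit(gt, "/", fixed = TRUE)
  vapply(seq_along(gt), function(i) {
    a <- alleles[[i]]
    if (any(a == ".") || length(a) == 0) return("missing")
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) return(NA_character_)  # malformed
    nalt <- sum(a == 1)
    if (male[i] && x_nonpar[i]) {
      return(if (nalt >= 1) "hemizygous" else "hom_ref")
    }
    if (length(a) == 1) return(if (nalt == 1) "hemizygous" else "hom_ref")
    c("hom_ref", "het", "hom_alt")[nalt + 1L]
  }, character(1))
}

#' Read a multi-sample VCF into genotype calls and a variant table
#'
#' Parses a VCF 4.2 file with `vcfR`, decomposes multi-allelic records into
#' one normalized allele per row, extracts the recognised INFO annotation
#' keys (GENE, CDNA, PROT, CSQ, DBSNP_AF, KG_AF, EXAC_AC, EXAC_AN, EXAC_HOM,
#' NBK_AF, PP2, MT, PROVEAN, SIFT, HGMD, CONS), and maps each sample's GT to
#' a zygosity. Heterozygous calls for males on X outside the
#' pseudo-autosomal regions are coerced to hemizygous with a warning, and a
#' genotype whose GT field cannot be parsed is skipped with a warning
#' reporting the skip count.
#'
#' @param path VCF file path
#' @param pedigrees pedigree table from [read_pedigrees()]; every member id
#'   must be a sample in the VCF header
#' @return list with `variants` (validated variant table) and `genotypes`
#'   (tibble subject_id, variant_id, zygosity; hom_ref rows are kept so the
#'   caller can distinguish typed-reference from absent)
#' @export
read_cohort_vcf <- function(path, pedigrees) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  members <- pedigree_members(pedigrees)
  absent <- setdiff(members, samples)
  if (length(absent) > 0) {
    abort(paste0("VCF is missing pedigree member(s): ",
                 paste(absent, collapse = ", ")))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO %||% rep("", nrow(fix))

  info_get <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))

  num <- function(key) suppressWarnings(as.numeric(info_get(key)))[row_idx]
  chr <- function(key) info_get(key)[row_idx]

  variants <- tibble(
    chrom = fix$CHROM[row_idx],
    pos = as.integer(fix$POS)[row_idx],
    ref = fix$REF[row_idx],
    alt = unlist(alts),
    gene = chr("GENE"),
    cdna_change = chr("CDNA"),
    protein_change = chr("PROT"),
    consequence = ifelse(is.na(chr("CSQ")), "other", chr("CSQ")),
    dbsnp_maf = num("DBSNP_AF"),
    kg_maf = num("KG_AF"),
    exac_ac = num("EXAC_AC"),
    exac_an = num("EXAC_AN"),
    exac_hom = num("EXAC_HOM"),
    nbk_maf = num("NBK_AF"),
    pp2 = num("PP2"),
    mutation_taster = chr("MT"),
    provean = num("PROVEAN"),
    sift = num("SIFT"),
    hgmd_listed = c("0" = FALSE, "1" = TRUE)[chr("HGMD")],
    conservation_depth = as.integer(num("CONS"))
  )
  variants$gene[is.na(variants$gene)] <- ""
  variants <- as_variant_table(variants)

  sex <- stats::setNames(pedigrees$proband_sex, pedigrees$proband_id)
  # parents: fathers male, mothers female
  sex[stats::na.omit(pedigrees$father_id)] <- "male"
  sex[stats::na.omit(pedigrees$mother_id)] <- "female"

  gt_raw <- v@gt[, members, drop = FALSE]
  gt_raw[is.na(gt_raw)] <- "./."   # vcfR reads missing genotypes as NA
  gt_only <- sub(":.*$", "", gt_raw)
  xnp <- is_x_nonpar(variants$chrom, variants$pos)

  n_skipped <- 0L
  n_coerced <- 0L
  geno <- lapply(members, function(m) {
    male <- identical(unname(sex[m]), "male")
    gt <- gt_only[row_idx, match(m, members)]
    # for decomposed records, alleles other than the current alt collapse to ref
    gt_dec <- vapply(seq_along(gt), function(i) {
      g <- gsub("\\|", "/", gt[i])
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      k <- as.character(alt_idx[i])
      num <- grepl("^[0-9]+$", a)
      a[num & a != k] <- "0"
      a[num & a == k] <- "1"
      paste(a, collapse = "/")
    }, character(1))
    het_before <- vapply(strsplit(gt_dec, "/"), function(a)
      sum(a == "1") == 1 && length(a) == 2, logical(1))
    z <- gt_to_zygosity(gt_dec, rep(male, length(gt_dec)), xnp)
    n_skipped <<- n_skipped + sum(is.na(z))
    n_coerced <<- n_coerced + sum(z == "hemizygous" & het_before, na.rm = TRUE)
    tibble(subject_id = m, variant_id = variants$variant_id, zygosity = z)
  })
  genotypes <- bind_rows(geno) %>% filter(!is.na(.data$zygosity))
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " genotype record(s) with malformed GT skipped"))
  }
  if (n_coerced > 0) {
    warn(paste0(n_coerced,
                " male X non-PAR heterozygous call(s) coerced to hemizygous"))
  }
  list(variants = variants, genotypes = genotypes)
}

#' Write variants and genotypes as a plain-text VCF 4.2 file
#'
#' Emits annotations as INFO keys (the same vocabulary [read_cohort_vcf()]
#' reads) and one GT column per sample. Output is deterministic: records are
#' sorted by chromosome, position, ref, alt, so identical inputs produce
#' byte-identical files.
#'
#' @param variants variant table
#' @param genotypes tibble (subject_id, variant_id, zygosity); subjects
#'   absent at a variant are written as 0/0
#' @param samples character vector of sample columns, in order
#' @param path output path
#' @return invisibly, `path`
#' @export
write_cohort_vcf <- function(variants, genotypes, samples, path) {
  v <- variants[order(variants$chrom, variants$pos, variants$ref, variants$alt), ]
  fmt <- function(x) ifelse(is.na(x), NA, format(x, scientific = FALSE, trim = TRUE))
  kv <- function(key, val) ifelse(is.na(val), NA, paste0(key, "=", val))
  info_mat <- cbind(
    kv("GENE", ifelse(v$gene == "", NA, v$gene)),
    kv("CDNA", v$cdna_change), kv("PROT", v$protein_change),
    kv("CSQ", v$consequence),
    kv("DBSNP_AF", fmt(v$dbsnp_maf)), kv("KG_AF", fmt(v$kg_maf)),
    kv("EXAC_AC", fmt(v$exac_ac)), kv("EXAC_AN", fmt(v$exac_an)),
    kv("EXAC_HOM", fmt(v$exac_hom)), kv("NBK_AF", fmt(v$nbk_maf)),
    kv("PP2", fmt(v$pp2)), kv("MT", v$mutation_taster),
    kv("PROVEAN", fmt(v$provean)), kv("SIFT", fmt(v$sift)),
    kv("HGMD", ifelse(is.na(v$hgmd_listed), NA, as.integer(v$hgmd_listed))),
    kv("CONS", fmt(v$conservation_depth))
  )
  info <- apply(info_mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })

  zyg_to_gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 hemizygous = "1", missing = "./.")
  gt <- matrix("0/0", nrow = nrow(v), ncol = length(samples),
               dimnames = list(NULL, samples))
  g <- genotypes[genotypes$subject_id %in% samples, ]
  ri <- match(g$variant_id, v$variant_id)
  ci <- match(g$subject_id, samples)
  keep <- !is.na(ri)
  gt[cbind(ri[keep], ci[keep])] <- zyg_to_gt[g$zygosity[keep]]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nshldx",
    paste0("##INFO=<ID=", c("GENE", "CDNA", "PROT", "CSQ", "MT"),
           ",Number=1,Type=String,Description=\"annotation\">"),
    paste0("##INFO=<ID=",
           c("DBSNP_AF", "KG_AF", "EXAC_AC", "EXAC_AN", "EXAC_HOM", "NBK_AF",
             "PP2", "PROVEAN", "SIFT", "HGMD", "CONS"),
           ",Number=1,Type=Float,Description=\"annotation\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sidecar annotation TSV and merge it into a variant table
#'
#' The sidecar is keyed by `chrom:pos:ref:alt` in a `variant_id` column (or
#' by the four coordinate columns); any of the variant-table annotation
#' columns it carries overwrite the corresponding values.
#'
#' @param variants variant table to annotate
#' @param path sidecar TSV path
#' @return the annotated variant table
#' @export
annotate_from_sidecar <- function(variants, path) {
  side <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"variant_id" %in% names(side)) {
    side$variant_id <- variant_id(side$chrom, side$pos, side$ref, side$alt)
  }
  ann_cols <- intersect(names(side),
                        setdiff(names(variant_columns()),
                                c("variant_id", "chrom", "pos", "ref", "alt")))
  i <- match(variants$variant_id, side$variant_id)
  for (col in ann_cols) {
    hit <- !is.na(i)
    variants[[col]][hit] <- side[[col]][i[hit]]
  }
  as_variant_table(variants)
}
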