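#' Find panel exons with insufficient capture coverage
#'
#' Scans a per-exon depth table (one row per panel exon: `gene`,
#' `exon_index`, `chrom`, `start`, `end`, `mean_depth`, `targeted`) and
#' returns the exons whose mean depth is strictly below the threshold,
#' partitioned into "not targeted by the capture design" and "targeted but
#' uncovered". Depth is the per-exon mean; a per-base minimum column
#' (`min_depth`) can be audited instead via `use = "min_depth"`.
#'
#' @param depth_table per-exon depth tibble
#' @param panel optional `nshl_panel`; when given, every panel exon must be
#'   present in the table (a missing exon is an error naming it)
#' @param threshold depth below which an exon counts as uncovered
#'   (default 1, i.e. "read depth < 1")
#' @param use depth column to audit
#' @return list with `uncovered` (the failing rows, plus all-exon context),
#'   `untargeted` and `targeted_uncovered` partitions, and `summary`
#'   (n_uncovered, n_untargeted, n_targeted_uncovered, total, fraction,
#'   n_genes_affected)
#' @export
find_uncovered_exons <- function(depth_table, panel = NULL, threshold = 1,
                                 use = "mean_depth") {
  if (!is.null(panel)) {
    want <- paste(panel$exons$symbol, panel$exons$exon_index)
    have <- paste(depth_table$gene, depth_table$exon_index)
    missing <- setdiff(want, have)
    if (length(missing) > 0) {
      abort(paste0("panel exon(s) missing from depth table: ",
                   paste(utils::head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) " ..."))
    }
  }
  unc <- depth_table[depth_table[[use]] < threshold, , drop = FALSE]
  untargeted <- unc[!unc$targeted, , drop = FALSE]
  targeted_unc <- unc[unc$targeted, , drop = FALSE]
  list(
    uncovered = unc,
    untargeted = untargeted,
    targeted_uncovered = targeted_unc,
    summary = list(
      n_uncovered = nrow(unc),
      n_untargeted = nrow(untargeted),
      n_targeted_uncovered = nrow(targeted_unc),
      total = nrow(depth_table),
      fraction = nrow(unc) / max(nrow(depth_table), 1L),
      n_genes_affected = length(unique(unc$gene))
    )
  )
}

#' Build the orthogonal Sanger sequencing worklist for uncovered exons
#'
#' Two rules decide which uncovered exons need Sanger follow-up: (a) every
#' uncovered exon of a dominant-mode (AD) gene is listed for all subjects,
#' because one missed heterozygous allele could be the whole diagnosis; (b)
#' an uncovered exon of a recessive-mode (AR) gene is listed only for
#' subjects already carrying one heterozygous allele in that gene — the
#' hidden exon could harbour the second hit of a compound heterozygote.
#'
#' @param uncovered result of [find_uncovered_exons()] (or its `uncovered`
#'   tibble)
#' @param panel an `nshl_panel`
#' @param subject_findings tibble of per-subject single-het observations in
#'   AR genes (columns `subject_id`, `gene`; e.g. the `observations` of a
#'   filter trace with `kind == "ar_single_het"`)
#' @return tibble (gene, exon_index, chrom, start, end, rule, subject_id);
#'   `subject_id` is NA for the AD rule (applies to every subject)
#' @export
sanger_worklist <- function(uncovered, panel, subject_findings = NULL) {
  unc <- if (is.list(uncovered) && !is.data.frame(uncovered)) {
    uncovered$uncovered
  } else uncovered
  if (nrow(unc) == 0) {
    return(tibble(gene = character(0), exon_index = integer(0),
                  chrom = character(0), start = integer(0), end = integer(0),
                  rule = character(0), subject_id = character(0)))
  }
  modes <- lapply(unc$gene, panel_modes, panel = panel)
  ad <- vapply(modes, function(m) "AD" %in% m, logical(1))
  ar <- vapply(modes, function(m) "AR" %in% m, logical(1))

  out <- unc[ad, c("gene", "exon_index", "chrom", "start", "end"), drop = FALSE]
  out$rule <- if (nrow(out)) "ad_gene" else character(0)
  out$subject_id <- if (nrow(out)) NA_character_ else character(0)

  if (!is.null(subject_findings) && nrow(subject_findings) > 0) {
    ar_unc <- unc[ar, c("gene", "exon_index", "chrom", "start", "end"),
                  drop = FALSE]
    hits <- dplyr::inner_join(ar_unc,
                              dplyr::distinct(subject_findings,
                                              .data$subject_id, .data$gene),
                              by = "gene", relationship = "many-to-many")
    if (nrow(hits) > 0) {
      hits$rule <- "ar_single_het_carrier"
      out <- bind_rows(out, hits[, names(out)])
    }
  }
  out
}
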