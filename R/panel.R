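#' Load a deafness gene panel from a TSV + BED pair
#'
#' The panel is shipped as two plain-text files: a gene table
#' (`symbol`, `inheritance` as a comma-separated subset of AR/AD/XL) and a
#' BED file of coding exon intervals whose name field is `symbol:exon_index`
#' (an optional fifth score column of 0/1 marks whether the exon is targeted
#' by the capture design; default 1). BED half-open 0-based coordinates are
#' converted to 1-based inclusive on read.
#'
#' @param genes_tsv path to the gene table
#' @param exons_bed path to the exon BED file
#' @return an `nshl_panel` object: a list with tibbles `genes`
#'   (symbol, inheritance) and `exons`
#'   (symbol, exon_index, chrom, start, end, targeted), sorted by symbol
#' @export
load_gene_panel <- function(genes_tsv, exons_bed) {
  genes <- utils::read.delim(genes_tsv, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(genes) == 0) abort("gene panel table is empty")
  if (!all(c("symbol", "inheritance") %in% names(genes))) {
    abort("panel gene table needs 'symbol' and 'inheritance' columns")
  }
  if (anyDuplicated(genes$symbol)) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    abort(paste0("duplicate panel gene symbol(s): ", paste(dup, collapse = ", ")))
  }
  modes <- strsplit(genes$inheritance, ",", fixed = TRUE)
  modes <- lapply(modes, trimws)
  bad <- setdiff(unique(unlist(modes)), INHERITANCE_MODES)
  if (length(bad) > 0 || any(lengths(modes) == 0)) {
    abort(paste0("inheritance modes must be a non-empty subset of ",
                 paste(INHERITANCE_MODES, collapse = "/"),
                 if (length(bad)) paste0("; got: ", paste(bad, collapse = ", "))))
  }

  bed <- utils::read.delim(exons_bed, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) abort("exon BED needs chrom, start, end, name columns")
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  targeted <- if (ncol(bed) >= 5) bed[[5]] != 0 else rep(TRUE, nrow(bed))
  name_parts <- strsplit(bed$name, ":", fixed = TRUE)
  exons <- tibble(
    symbol = vapply(name_parts, `[[`, "", 1L),
    exon_index = as.integer(vapply(name_parts, `[[`, "", 2L)),
    chrom = as.character(bed$chrom),
    start = as.integer(bed$start) + 1L,  # 0-based half-open -> 1-based inclusive
    end = as.integer(bed$end),
    targeted = targeted
  )
  if (any(exons$start > exons$end)) abort("exon interval with start > end")
  missing <- setdiff(genes$symbol, exons$symbol)
  if (length(missing) > 0) {
    abort(paste0("panel gene(s) without exons: ", paste(missing, collapse = ", ")))
  }

  new_panel(
    genes = tibble(symbol = genes$symbol,
                   inheritance = vapply(modes, paste, "", collapse = ",")),
    exons = exons
  )
}

new_panel <- function(genes, exons) {
  # exon intervals must not overlap within a gene
  chk <- exons %>%
    arrange(.data$symbol, .data$start) %>%
    group_by(.data$symbol) %>%
    summarise(ok = all(diff(.data$start) > 0) &&
                all(.data$start[-1] > .data$end[-n()]), .groups = "drop")
  if (!all(chk$ok)) {
    abort(paste0("overlapping exon intervals within gene(s): ",
                 paste(chk$symbol[!chk$ok], collapse = ", ")))
  }
  structure(
    list(
      genes = arrange(genes, .data$symbol),
      exons = arrange(exons, .data$symbol, .data$exon_index)
    ),
    class = "nshl_panel"
  )
}

#' @export
print.nshl_panel <- function(x, ...) {
  cat("<nshl_panel> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " coding exons\n", sep = "")
  tab <- table(unlist(strsplit(x$genes$inheritance, ",")))
  cat("  modes: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write a panel back out as the TSV + BED pair
#'
#' Inverse of [load_gene_panel()]; coordinates are converted back to BED
#' (0-based half-open) on write.
#' @param panel an `nshl_panel`
#' @param genes_tsv,exons_bed output paths
#' @return invisibly, the two paths
#' @export
write_gene_panel <- function(panel, genes_tsv, exons_bed) {
  utils::write.table(panel$genes, genes_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(
    chrom = panel$exons$chrom,
    start = panel$exons$start - 1L,
    end = panel$exons$end,
    name = paste(panel$exons$symbol, panel$exons$exon_index, sep = ":"),
    score = as.integer(panel$exons$targeted)
  )
  utils::write.table(bed, exons_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(genes_tsv, exons_bed))
}

#' Inheritance modes of one panel gene
#' @param panel an `nshl_panel`
#' @param symbol gene symbol
#' @return character vector of modes, or character(0) if not a panel gene
#' @export
panel_modes <- function(panel, symbol) {
  i <- match(symbol, panel$genes$symbol)
  if (is.na(i)) return(character(0))
  strsplit(panel$genes$inheritance[i], ",", fixed = TRUE)[[1]]
}

#' The bundled 72-gene deafness panel
#'
#' A synthetic reconstruction of a 72-gene non-syndromic hearing loss panel
#' (1340 coding exons in total) with per-gene inheritance modes. Gene symbols
#' and per-gene exon counts are realistic, but the exon coordinates are
#' synthesized deterministically (each gene gets an anchored run of 150 bp
#' exons spaced 2 kb apart on its chromosome) because no transcript model is
#' bundled; they are internally consistent and usable for interval logic,
#' not for annotating real data.
#'
#' @return an `nshl_panel` with 72 genes and 1340 exons
#' @export
default_panel <- function() {
  tsv <- system.file("extdata", "panel_genes.tsv", package = "nshldx")
  genes <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    n <- genes$n_exons[i]
    anchor <- 10000000L + i * 1000000L
    start <- anchor + (seq_len(n) - 1L) * 2000L
    tibble(
      symbol = genes$symbol[i], exon_index = seq_len(n),
      chrom = genes$chrom[i], start = start, end = start + 149L,
      targeted = TRUE
    )
  })
  new_panel(
    genes = tibble(symbol = genes$symbol, inheritance = genes$inheritance),
    exons = bind_rows(exons)
  )
}
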