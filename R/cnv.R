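#' Consensus between two read-depth CNV call sets
#'
#' A call set is a tibble (subject_id, caller, chrom, start, end, type,
#' copy_number) with 1-based inclusive coordinates, `type` in
#' deletion/duplication, and copy_number consistent with the type
#' (deletions < 2, duplications > 2). Overlapping same-caller calls of the
#' same type are merged first (with a warning). A consensus call exists
#' wherever a call from each set shares the type and achieves at least
#' `min_reciprocal_overlap` of both intervals; the consensus interval is the
#' intersection and the consensus copy number the minimum of the pair
#' (the more extreme loss wins for deletions).
#'
#' @param setA,setB the two call sets (same subject)
#' @param min_reciprocal_overlap fraction of each interval the overlap must
#'   cover (default 0.5)
#' @return tibble of consensus calls (subject_id, chrom, start, end, type,
#'   copy_number)
#' @export
consensus_calls <- function(setA, setB, min_reciprocal_overlap = 0.5) {
  validate_cnv_set <- function(s, label) {
    if (nrow(s) == 0) return(s)
    if (any(s$start > s$end)) abort(paste0(label, ": start > end"))
    bad <- (s$type == "deletion" & s$copy_number >= 2) |
      (s$type == "duplication" & s$copy_number <= 2)
    if (any(bad)) {
      abort(paste0(label, ": copy_number inconsistent with call type"))
    }
    merge_same_caller(s, label)
  }
  a <- validate_cnv_set(as_tibble(setA), "setA")
  b <- validate_cnv_set(as_tibble(setB), "setB")
  subj <- unique(c(a$subject_id, b$subject_id))
  if (length(subj) > 1) abort("both call sets must come from the same subject")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(subject_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), type = character(0),
                  copy_number = integer(0)))
  }
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j] || a$type[i] != b$type[j]) next
    os <- max(a$start[i], b$start[j])
    oe <- min(a$end[i], b$end[j])
    if (os > oe) next
    olen <- oe - os + 1
    if (olen / (a$end[i] - a$start[i] + 1) >= min_reciprocal_overlap &&
        olen / (b$end[j] - b$start[j] + 1) >= min_reciprocal_overlap) {
      out[[length(out) + 1L]] <- tibble(
        subject_id = subj, chrom = a$chrom[i], start = os, end = oe,
        type = a$type[i],
        copy_number = min(a$copy_number[i], b$copy_number[j])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(subject_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), type = character(0),
                  copy_number = integer(0)))
  }
  distinct(arrange(bind_rows(out), .data$chrom, .data$start, .data$end))
}

# merge overlapping same-type calls within one caller's set, warning once
merge_same_caller <- function(s, label) {
  s <- arrange(s, .data$type, .data$chrom, .data$start)
  merged <- list()
  warned <- FALSE
  for (grp in split(s, paste(s$type, s$chrom))) {
    cur <- grp[1, ]
    if (nrow(grp) > 1) for (i in 2:nrow(grp)) {
      if (grp$start[i] <= cur$end + 1) {
        warned <- TRUE
        cur$end <- max(cur$end, grp$end[i])
        cur$copy_number <- min(cur$copy_number, grp$copy_number[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- grp[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  if (warned) warn(paste0(label, ": overlapping same-caller calls merged"))
  bind_rows(merged)
}

#' Flag bi-allelic (copy-number-0) deletions hitting coding exons
#'
#' A consensus deletion with copy number 0 removes both copies of the
#' region; when it intersects at least one coding exon the gene product is
#' truncated and the call is flagged as a recessive-pattern candidate.
#' Heterozygous deletions (CN 1) and fully intronic/intergenic CN-0
#' deletions are not flagged.
#'
#' @param consensus consensus call tibble from [consensus_calls()]
#' @param gene_exons exon tibble (gene, exon_index, chrom, start, end),
#'   1-based inclusive
#' @return flagged consensus rows with `gene`, `exon_index` (comma-joined
#'   when several exons are hit) and a truncation `note` appended
#' @export
flag_biallelic_deletions <- function(consensus, gene_exons) {
  hits <- list()
  cand <- consensus[consensus$type == "deletion" & consensus$copy_number == 0, ,
                    drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    ov <- gene_exons$chrom == cand$chrom[i] &
      gene_exons$start <= cand$end[i] & gene_exons$end >= cand$start[i]
    if (!any(ov)) next
    row <- cand[i, ]
    row$gene <- paste(unique(gene_exons$gene[ov]), collapse = ",")
    row$exon_index <- paste(gene_exons$exon_index[ov], collapse = ",")
    row$note <- paste0("bi-allelic deletion of coding sequence; predicted ",
                       row$gene, " truncation")
    hits[[length(hits) + 1L]] <- row
  }
  if (length(hits) == 0) {
    out <- consensus[0, , drop = FALSE]
    out$gene <- character(0)
    out$exon_index <- character(0)
    out$note <- character(0)
    return(out)
  }
  bind_rows(hits)
}
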