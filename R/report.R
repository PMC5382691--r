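#' Round half away from zero
#'
#' Percentage reporting uses commercial rounding (half away from zero), so
#' 18/28 prints as 64.3 and 3/13 as 23.1.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Classify one subject through the staged diagnostic triage
#'
#' Reproduces the clinical decision flow: subjects with an enlarged
#' vestibular aqueduct (EVA) on imaging get full SLC26A4 Sanger sequencing;
#' subjects without EVA get GJB2 Sanger sequencing; whoever remains
#' undiagnosed is routed to whole-exome analysis, where the filter cascade
#' and inheritance engine decide between a known-panel-gene diagnosis
#' (`solved_known_gene`), genome-wide candidate findings or a flagged
#' bi-allelic CNV (`candidate_only`), and `unsolved`. Dominant-gene variants
#' carried by an unaffected parent are recorded as non-segregating notes,
#' never as diagnoses. Solved calls in two panel genes are both recorded
#' with a "multilocus" note.
#'
#' @param subject_id proband id
#' @param cohort cohort list; `subjects` must carry `eva` (logical) per
#'   subject, and optionally `cnv_flags` (output of
#'   [flag_biallelic_deletions()] with subject ids)
#' @param thresholds see [default_thresholds()]
#' @return a diagnostic call: list with `subject_id`, `status`, `route`,
#'   `gene`, `mechanism` (tibble rows), `notes`, and the `trace` when WES
#'   ran
#' @export
classify_subject <- function(subject_id, cohort,
                             thresholds = default_thresholds()) {
  sub <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  if (nrow(sub) != 1) abort(paste0("unknown subject ", subject_id))
  ped <- cohort$pedigrees[cohort$pedigrees$proband_id == subject_id, ]
  if (nrow(ped) != 1) abort(paste0("pedigree missing for proband ", subject_id))

  sanger_gene <- if (isTRUE(sub$eva)) "SLC26A4" else "GJB2"
  sanger_route <- if (isTRUE(sub$eva)) "sanger_slc26a4" else "sanger_gjb2"
  gv <- cohort$variants[cohort$variants$gene == sanger_gene, , drop = FALSE]
  bi <- detect_biallelic(gv, cohort$genotypes, ped, thresholds)
  bi_ok <- bi[bi$phase_status != "cis_rejected", , drop = FALSE]
  if (nrow(bi_ok) > 0) {
    return(diagnostic_call(subject_id, "solved_known_gene", sanger_route,
                           sanger_gene, bi_ok[1, ], notes = character(0)))
  }

  trace <- run_cascade(subject_id, cohort, thresholds)
  notes <- character(0)
  obs <- trace$observations
  nonseg <- obs[obs$kind == "ad_singleton" & obs$status == "non_segregating", ]
  for (i in seq_len(nrow(nonseg))) {
    notes <- c(notes, paste0("non-segregating AD variant in ", nonseg$gene[i],
                             " (carried by an unaffected parent)"))
  }
  ar_single <- obs[obs$kind == "ar_single_het", ]
  if (nrow(ar_single) > 0) {
    notes <- c(notes, paste0("single heterozygous AR-gene allele(s): ",
                             paste(unique(ar_single$gene), collapse = ", ")))
  }

  diag <- trace$mechanisms[trace$mechanisms$diagnostic, , drop = FALSE]
  diag <- diag[diag$gene %in% cohort$panel$genes$symbol, , drop = FALSE]
  if (nrow(diag) > 0) {
    if (length(unique(diag$gene)) > 1) notes <- c(notes, "multilocus")
    if (any(diag$mechanism == "de_novo")) {
      notes <- c(notes, "de novo dominant mechanism")
    }
    return(diagnostic_call(subject_id, "solved_known_gene", "wes_panel",
                           paste(unique(diag$gene), collapse = ","),
                           diag, notes, trace))
  }

  cnv <- cohort$cnv_flags
  has_cnv <- !is.null(cnv) && nrow(cnv[cnv$subject_id == subject_id, ]) > 0
  candidates <- trace$retained[!trace$retained$gene %in%
                                 cohort$panel$genes$symbol, , drop = FALSE]
  if (nrow(candidates) > 0 || has_cnv) {
    if (has_cnv) {
      f <- cnv[cnv$subject_id == subject_id, ]
      notes <- c(notes, paste0("bi-allelic exonic deletion (", f$gene[1], ")"))
    }
    if (nrow(candidates) > 0) {
      notes <- c(notes, paste0(nrow(candidates), " candidate variant(s) in ",
                               length(unique(candidates$gene)),
                               " non-panel gene(s)"))
    }
    return(diagnostic_call(subject_id, "candidate_only", "wes_candidate",
                           NA_character_, trace$mechanisms, notes, trace))
  }
  diagnostic_call(subject_id, "unsolved", "wes_candidate", NA_character_,
                  empty_mechanisms(), notes, trace)
}

diagnostic_call <- function(subject_id, status, route, gene, mechanism,
                            notes, trace = NULL) {
  structure(list(subject_id = subject_id, status = status, route = route,
                 gene = gene, mechanism = mechanism, notes = notes,
                 trace = trace),
            class = "nshl_diagnosis")
}

#' @export
print.nshl_diagnosis <- function(x, ...) {
  cat("<nshl_diagnosis> ", x$subject_id, ": ", x$status,
      if (!is.na(x$gene)) paste0(" (", x$gene, ")"), " via ", x$route, "\n",
      sep = "")
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Classify every proband in a cohort
#'
#' @param cohort cohort list
#' @param thresholds see [default_thresholds()]
#' @return list with `calls` (tibble subject_id, status, route, gene,
#'   mechanism, phase_status, notes) and `details` (the per-subject
#'   diagnosis objects, named by subject)
#' @export
classify_cohort <- function(cohort, thresholds = default_thresholds()) {
  details <- lapply(cohort$subjects$subject_id, classify_subject,
                    cohort = cohort, thresholds = thresholds)
  names(details) <- cohort$subjects$subject_id
  calls <- bind_rows(lapply(details, function(d) {
    mech <- if (nrow(d$mechanism) > 0) d$mechanism$mechanism[1] else NA_character_
    phase <- if (nrow(d$mechanism) > 0) d$mechanism$phase_status[1] else NA_character_
    tibble(subject_id = d$subject_id, status = d$status, route = d$route,
           gene = d$gene, mechanism = mech, phase_status = phase,
           notes = paste(d$notes, collapse = "; "))
  }))
  list(calls = calls, details = details)
}

#' Cohort-level diagnostic yield with standard strata
#'
#' Computes the headline yield (solved in a known gene / all probands;
#' candidate-only findings never count) plus the two standard strata:
#' the yield after removing subjects diagnosed through the imaging-directed
#' SLC26A4 Sanger route (numerator and denominator both shrink), and the
#' yield within the subjects routed to whole-exome analysis.
#'
#' @param calls the `calls` tibble from [classify_cohort()]
#' @return list with `n_total`, `n_solved`, `yield_pct`, `per_gene`
#'   (solved-subject counts by gene), `per_route`, and `strata`
#'   (`excl_slc26a4_route`, `wes_only`, each n/solved/yield_pct)
#' @export
cohort_yield <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) abort("no diagnostic calls supplied")
  solved <- calls$status == "solved_known_gene"
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  excl <- calls$route != "sanger_slc26a4"
  wes <- calls$route %in% c("wes_panel", "wes_candidate")
  list(
    n_total = nrow(calls),
    n_solved = sum(solved),
    yield_pct = pct(sum(solved), nrow(calls)),
    per_gene = table(calls$gene[solved]),
    per_route = table(calls$route),
    strata = list(
      excl_slc26a4_route = list(n = sum(excl), solved = sum(solved & excl),
                                yield_pct = pct(sum(solved & excl), sum(excl))),
      wes_only = list(n = sum(wes), solved = sum(solved & wes),
                      yield_pct = pct(sum(solved & wes), sum(wes)))
    )
  )
}

#' Render the cohort report
#'
#' Produces a machine-readable JSON document (subject table, yield, strata,
#' per-subject filter waterfalls) and a markdown summary. The JSON
#' round-trips: parsing it recovers the same values.
#'
#' @param summary output of [cohort_yield()]
#' @param calls the `calls` tibble from [classify_cohort()]
#' @param traces optional named list of filter traces for the waterfall
#'   section
#' @return list with `json` (character scalar) and `markdown` (character
#'   vector of lines)
#' @export
render_report <- function(summary, calls, traces = NULL) {
  payload <- list(
    schema = "nshldx-report/1",
    n_total = summary$n_total,
    n_solved = summary$n_solved,
    yield_pct = summary$yield_pct,
    per_gene = as.list(summary$per_gene),
    per_route = as.list(summary$per_route),
    strata = summary$strata,
    subjects = calls
  )
  if (!is.null(traces)) {
    payload$waterfalls <- lapply(traces, function(t)
      stats::setNames(as.list(t$step_counts$n), t$step_counts$step))
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)

  md <- c(
    "# Molecular diagnosis report",
    "",
    sprintf("Solved: %d / %d subjects (%.1f%%)", summary$n_solved,
            summary$n_total, summary$yield_pct),
    "",
    "## Solved subjects by gene",
    sprintf("- %s: %d", names(summary$per_gene), as.integer(summary$per_gene)),
    "",
    "## Strata",
    sprintf("- excluding SLC26A4 Sanger route: %d/%d (%.1f%%)",
            summary$strata$excl_slc26a4_route$solved,
            summary$strata$excl_slc26a4_route$n,
            summary$strata$excl_slc26a4_route$yield_pct),
    sprintf("- WES-routed subjects: %d/%d (%.1f%%)",
            summary$strata$wes_only$solved, summary$strata$wes_only$n,
            summary$strata$wes_only$yield_pct),
    "",
    "## Subjects",
    sprintf("- %s: %s%s [%s]%s", calls$subject_id, calls$status,
            ifelse(is.na(calls$gene), "", paste0(" (", calls$gene, ")")),
            calls$route,
            ifelse(calls$notes == "", "", paste0(" — ", calls$notes)))
  )
  list(json = as.character(json), markdown = md)
}
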