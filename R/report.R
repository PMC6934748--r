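# High-throughput assay report: failure / ambiguity / assignment /
# morphology-discordance counts with printed-precision percentages.

#' Summarize assay calls into a throughput report
#'
#' Counts and percentages in the shape of a high-throughput HRM summary
#' table: totals and per-sex breakdowns of sample counts, failed
#' amplifications, ambiguous curves, per-species assignments, and
#' discordance with a prior (e.g. morphology-based) species label.
#'
#' Failure and ambiguity percentages use the group's sample count as
#' denominator. Discordance is counted over specimens that have a non-null
#' prior label *and* a successful, unambiguous call, but its percentage
#' denominator is all labelled specimens in the group (so 30 discordant
#' among 279 labelled males reports 10.75% even when some labelled males
#' failed). Percentages are reported half-up at both one and two decimals,
#' the two precisions such tables are quoted at.
#'
#' @param calls Calls tibble from [call_species()] / [classify_curves()].
#' @param metadata Tibble with `specimen_id`, `sex` (e.g. "male" /
#'   "female"), and `prior_label` (NA when unidentified). Must cover every
#'   called specimen.
#' @return An object of class `assay_report`: list with `summary` (one row
#'   per group: total plus each sex) and `assignments` (group x species
#'   counts).
#' @export
summarize_assay <- function(calls, metadata) {
  need <- c("specimen_id", "sex", "prior_label")
  if (!all(need %in% names(metadata))) {
    abort_hrmelt(
      paste0("metadata needs columns: ", paste(need, collapse = ", ")),
      "input_error"
    )
  }
  missing_meta <- setdiff(calls$specimen_id, metadata$specimen_id)
  if (length(missing_meta) > 0) {
    abort_hrmelt(
      sprintf("metadata missing for %d specimen(s)", length(missing_meta)),
      "input_error"
    )
  }
  df <- left_join(calls, metadata, by = "specimen_id")
  species_calls <- setdiff(unique(df$call), c("failed", "ambiguous"))

  one_group <- function(d, label) {
    n <- nrow(d)
    n_failed <- sum(d$call == "failed")
    n_ambiguous <- sum(d$call == "ambiguous")
    labelled <- !is.na(d$prior_label)
    assigned <- d$call %in% species_calls
    n_labelled <- sum(labelled)
    n_discordant <- sum(labelled & assigned & d$call != d$prior_label)
    pct <- function(num, den) if (den > 0) 100 * num / den else 0
    tibble(
      group = label,
      n_samples = n,
      n_successful = n - n_failed,
      n_failed = n_failed,
      pct_failed_1dp = round_half_up(pct(n_failed, n), 1),
      pct_failed_2dp = round_half_up(pct(n_failed, n), 2),
      n_ambiguous = n_ambiguous,
      pct_ambiguous_1dp = round_half_up(pct(n_ambiguous, n), 1),
      pct_ambiguous_2dp = round_half_up(pct(n_ambiguous, n), 2),
      n_labelled = n_labelled,
      n_discordant = n_discordant,
      pct_discordant_1dp = round_half_up(pct(n_discordant, n_labelled), 1),
      pct_discordant_2dp = round_half_up(pct(n_discordant, n_labelled), 2)
    )
  }

  groups <- c(list(total = df), split(df, df$sex))
  summary <- purrr::list_rbind(purrr::imap(groups, function(d, nm) {
    one_group(d, nm)
  }))
  assignments <- purrr::list_rbind(purrr::imap(groups, function(d, nm) {
    tibble(group = nm, species = species_calls) |>
      mutate(n_assigned = purrr::map_int(
        .data$species,
        function(sp) sum(d$call == sp)
      ))
  }))
  structure(
    list(summary = summary, assignments = assignments),
    class = "assay_report"
  )
}

#' @export
print.assay_report <- function(x, ...) {
  cat("High-throughput HRM assay report\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf(
      "  %-8s n=%d  failed %d (%.1f%%)  ambiguous %d (%.1f%%)",
      s$group, s$n_samples, s$n_failed, s$pct_failed_1dp,
      s$n_ambiguous, s$pct_ambiguous_1dp
    ))
    if (s$n_labelled > 0) {
      cat(sprintf(
        "  discordant %d/%d (%.1f%% | %.2f%%)",
        s$n_discordant, s$n_labelled, s$pct_discordant_1dp,
        s$pct_discordant_2dp
      ))
    }
    cat("\n")
    a <- x$assignments[x$assignments$group == s$group, ]
    cat(sprintf(
      "  %-8s assigned: %s\n", "",
      paste(sprintf("%s %d", a$species, a$n_assigned), collapse = ", ")
    ))
  }
  invisible(x)
}

#' @method tidy assay_report
#' @export
tidy.assay_report <- function(x, ...) {
  left_join(
    x$summary,
    tidyr::pivot_wider(x$assignments,
      names_from = "species", values_from = "n_assigned",
      names_prefix = "n_assigned_"
    ),
    by = "group"
  )
}

#' @method glance assay_report
#' @export
glance.assay_report <- function(x, ...) {
  tot <- x$summary[x$summary$group == "total", ]
  tibble(
    n_samples = tot$n_samples,
    n_successful = tot$n_successful,
    n_failed = tot$n_failed,
    pct_failed_1dp = tot$pct_failed_1dp,
    n_ambiguous = tot$n_ambiguous,
    n_discordant = sum(x$summary$n_discordant[x$summary$group != "total"])
  )
}

#' Write an assay report as CSV and plain text
#'
#' @param report An `assay_report`.
#' @param csv_path Wide per-group CSV ([tidy()] output); optional.
#' @param txt_path Human-readable text rendering; optional.
#' @return `report`, invisibly.
#' @export
write_assay_report <- function(report, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(tidy(report), csv_path)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(report)
}
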