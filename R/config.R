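#' Episode-construction configuration
#'
#' Bundles the tunable parameters of the episode builder:
#'
#' * `epsilon_same` — temporal margin (days) for overlaps between
#'   dispensations of the *same* drug. Overlaps of at most this length are
#'   treated as early refills: the later record is shifted forward to abut
#'   the earlier one and the relation is recoded from *overlaps* to *meets*.
#'   Default 7 days.
#' * `epsilon_cross` — temporal margin (days) separating a medication
#'   *transition* from genuine *multitherapy* when different drugs'
#'   coverage overlaps. Co-dispensation of at most this length is read as a
#'   switch (cross-taper, low-dose induction); longer co-dispensation is
#'   concurrent therapy and left untouched. Default 14 days.
#' * `permissible_gaps` — named integer vector of drug-specific maximum
#'   uncovered gaps (days) before therapy counts as discontinued, mapped
#'   onto the *before* relation. Defaults: methadone 5, buprenorphine/
#'   naloxone 6, slow-release oral morphine (SROM) 5, injectable OAT 3 —
#'   reflecting the medications' half-lives and dispensing guidelines.
#' * `bridge_hospitalizations` — whether to treat admission amid an ongoing
#'   episode as continued therapy (outpatient claims omit inpatient
#'   dispensing). Default `TRUE`.
#' * `count_gap_days_in_duration` — whether within-gap uncovered days count
#'   toward episode duration (they always lie inside the episode span).
#'   Kept as a toggle; default `TRUE`.
#'
#' @param epsilon_same,epsilon_cross non-negative integer margins in days.
#' @param permissible_gaps named non-negative integer vector, one entry per
#'   drug class appearing in the data.
#' @param bridge_hospitalizations logical.
#' @param count_gap_days_in_duration logical.
#' @return A list of class `oat_config`.
#' @examples
#' cfg <- episode_config()
#' cfg$permissible_gaps[["ioat"]]
#' @export
episode_config <- function(epsilon_same = 7L,
                           epsilon_cross = 14L,
                           permissible_gaps = c(
                             methadone = 5L, bup_nal = 6L,
                             srom = 5L, ioat = 3L
                           ),
                           bridge_hospitalizations = TRUE,
                           count_gap_days_in_duration = TRUE) {
  epsilon_same <- as.integer(epsilon_same)
  epsilon_cross <- as.integer(epsilon_cross)
  if (epsilon_same < 0L || epsilon_cross < 0L) {
    abort("temporal margins must be non-negative")
  }
  if (is.null(names(permissible_gaps)) || any(!nzchar(names(permissible_gaps)))) {
    abort("permissible_gaps must be a named vector (drug class -> days)")
  }
  gaps <- setNames(as.integer(permissible_gaps), names(permissible_gaps))
  if (any(gaps < 0L)) abort("permissible gaps must be non-negative")
  structure(
    list(
      epsilon_same = epsilon_same,
      epsilon_cross = epsilon_cross,
      permissible_gaps = gaps,
      bridge_hospitalizations = isTRUE(bridge_hospitalizations),
      count_gap_days_in_duration = isTRUE(count_gap_days_in_duration)
    ),
    class = "oat_config"
  )
}

#' @export
print.oat_config <- function(x, ...) {
  cat("<oat_config>\n")
  cat("  epsilon_same:  ", x$epsilon_same, "days\n")
  cat("  epsilon_cross: ", x$epsilon_cross, "days\n")
  cat("  permissible gaps:",
      paste(names(x$permissible_gaps), x$permissible_gaps, sep = "=", collapse = ", "),
      "\n")
  cat("  bridge hospitalizations:", x$bridge_hospitalizations, "\n")
  invisible(x)
}

# gap for one drug, with a clear error when the catalog and config disagree
gap_for <- function(cfg, drug) {
  g <- cfg$permissible_gaps[drug]
  if (anyNA(g)) {
    abort(paste0("no permissible gap configured for drug class '", drug, "'"))
  }
  unname(g)
}
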