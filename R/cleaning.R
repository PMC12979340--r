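#' Cleaning configuration
#'
#' Raw dispensation tables carry pharmacy-workflow artefacts: split doses
#' entered as several same-day rows, keyed quantities that imply an
#' implausible quantity-per-day (QPD), and days-supply values that overrun
#' the next fill. The cleaning stage applies logic-based corrections with a
#' full audit trail; the thresholds here are explicit configuration:
#'
#' * `qpd_deviation_factor` — a row is flagged when its QPD differs from
#'   the median QPD of its adjacency window by more than this multiplicative
#'   factor (ratio or its inverse). Default 2.
#' * `adjacency_window` — records on each side (same person and drug) that
#'   form the reference window. Default 2.
#' * `plausible_supply_range` — days-supply values considered clinically
#'   plausible when re-deriving supply from quantity; OAT is dispensed daily
#'   to monthly (depot buprenorphine is a monthly injection), hence 1–28.
#'
#' @param qpd_deviation_factor multiplicative deviation threshold, > 1.
#' @param adjacency_window integer >= 1 records per side.
#' @param plausible_supply_range length-2 integer vector (min, max days).
#' @return List of class `oat_cleaning_config`.
#' @export
cleaning_config <- function(qpd_deviation_factor = 2,
                            adjacency_window = 2L,
                            plausible_supply_range = c(1L, 28L)) {
  if (qpd_deviation_factor <= 1) abort("qpd_deviation_factor must be > 1")
  if (adjacency_window < 1L) abort("adjacency_window must be >= 1")
  structure(
    list(
      qpd_deviation_factor = qpd_deviation_factor,
      adjacency_window = as.integer(adjacency_window),
      plausible_supply_range = as.integer(plausible_supply_range)
    ),
    class = "oat_cleaning_config"
  )
}

add_flag <- function(flags, new) {
  if_else(is.na(flags) | !nzchar(flags), new, paste(flags, new, sep = ";"))
}

empty_audit <- function() {
  tibble(
    person_id = character(), start = integer(), drug = character(),
    rule = character(), field = character(),
    before = double(), after = double()
  )
}

#' Consolidate split-dose dispensations
#'
#' Same-person, same-drug, same-service-date rows are merged into one:
#' quantities are summed, days supply takes the maximum of the group, and
#' total dispensed quantity is conserved. Groups whose strengths disagree
#' cannot be merged safely (the summed quantity would mix potencies); they
#' are flagged and left unmerged.
#'
#' @param disps dispensation tibble sorted by (person, drug, date).
#' @return List: `dispensations` (consolidated), `audit` (row-level trail).
#' @export
consolidate_split_doses <- function(disps) {
  d <- disps %>% arrange(.data$person_id, .data$drug, .data$start)
  grp <- d %>%
    group_by(.data$person_id, .data$drug, .data$start) %>%
    mutate(.gn = n(), .strength_ok = dplyr::n_distinct(.data$strength) == 1L) %>%
    ungroup()
  conflict <- grp %>% filter(.data$.gn > 1L, !.data$.strength_ok)
  new_conflict <- conflict %>%
    filter(is.na(.data$flags) | !grepl("split_dose_strength_conflict", .data$flags, fixed = TRUE))
  mergeable <- grp %>% filter(.data$.gn > 1L, .data$.strength_ok)
  untouched <- grp %>% filter(.data$.gn == 1L)
  if (nrow(mergeable)) {
    merged <- mergeable %>%
      group_by(.data$person_id, .data$drug, .data$start) %>%
      summarise(
        din = first(.data$din),
        service_date = first(.data$service_date),
        days_supply = max(.data$days_supply),
        quantity = sum(.data$quantity),
        strength = first(.data$strength),
        flags = add_flag(first(.data$flags), "consolidated_split_dose"),
        .groups = "drop"
      )
    audit <- mergeable %>%
      group_by(.data$person_id, .data$drug, .data$start) %>%
      summarise(
        rule = "consolidate_split_dose", field = "quantity",
        before = first(.data$quantity), after = sum(.data$quantity),
        .groups = "drop"
      ) %>%
      select("person_id", "start", "drug", "rule", "field", "before", "after")
  } else {
    merged <- mergeable
    audit <- empty_audit()
  }
  conflict <- conflict %>%
    mutate(flags = if_else(
      is.na(.data$flags) | !grepl("split_dose_strength_conflict", .data$flags, fixed = TRUE),
      add_flag(.data$flags, "split_dose_strength_conflict"), .data$flags
    ))
  conflict_audit <- new_conflict %>%
    distinct(.data$person_id, .data$drug, .data$start) %>%
    mutate(
      rule = "split_dose_strength_conflict", field = "strength",
      before = NA_real_, after = NA_real_
    ) %>%
    select("person_id", "start", "drug", "rule", "field", "before", "after")
  keep_cols <- c(
    "person_id", "din", "drug", "service_date", "start",
    "days_supply", "quantity", "strength", "flags"
  )
  out <- bind_rows(
    untouched %>% select(all_of(keep_cols)),
    merged %>% select(all_of(keep_cols)),
    conflict %>% select(all_of(keep_cols))
  ) %>%
    finish_dispensations()
  list(dispensations = out, audit = bind_rows(audit, conflict_audit))
}

# lower median: conservative tie-break for even windows (avoids inflating dose)
lower_median <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

#' Repair quantity-per-day outliers
#'
#' A row whose QPD deviates from the lower-median QPD of its adjacency
#' window (up to `adjacency_window` records on each side, same person and
#' drug, the row itself excluded) by more than `qpd_deviation_factor` is
#' repaired: first by recalculating days supply as
#' `round(quantity / median QPD)` when that lands in the plausible range,
#' otherwise by resetting quantity to `median QPD * days supply`. Rows with
#' fewer than two neighbours are never altered — there is no reference to
#' judge them against. Every change is flagged and logged.
#'
#' @param disps dispensation tibble.
#' @param config a [cleaning_config()].
#' @return List: `dispensations`, `audit`.
#' @export
repair_qpd_outliers <- function(disps, config = cleaning_config()) {
  d <- disps %>%
    arrange(.data$person_id, .data$drug, .data$start) %>%
    mutate(.row = row_number())
  w <- config$adjacency_window
  fac <- config$qpd_deviation_factor
  lo <- config$plausible_supply_range[1]
  hi <- config$plausible_supply_range[2]
  audit <- list()
  d <- d %>% group_by(.data$person_id, .data$drug)
  idx <- dplyr::group_rows(d)
  d <- ungroup(d)
  qty <- d$quantity
  ds <- d$days_supply
  flags <- d$flags
  for (rows_all in idx) {
    # rows corrected by an earlier pass (QPD repair or supply cap) are neither
    # re-judged nor used as references: corrections are applied once and the
    # reference window is made of untouched records, keeping re-runs stable
    touched <- !is.na(flags[rows_all]) &
      grepl("qpd_|days_supply_capped", flags[rows_all])
    rows <- rows_all[!touched]
    m <- length(rows)
    if (m < 3L) next # fewer than 2 neighbours for every row
    qpd0 <- qty[rows] / ds[rows] # reference QPDs fixed before any repair
    for (j in seq_len(m)) {
      nb <- setdiff(max(1L, j - w):min(m, j + w), j)
      if (length(nb) < 2L) next
      med <- lower_median(qpd0[nb])
      q <- qty[rows[j]] / ds[rows[j]]
      if (med <= 0 || q <= 0) next
      ratio <- max(q / med, med / q)
      if (ratio <= fac) next
      i <- rows[j]
      new_ds <- as.integer(round(qty[i] / med))
      if (new_ds >= lo && new_ds <= hi) {
        audit[[length(audit) + 1L]] <- tibble(
          person_id = d$person_id[i], start = d$start[i], drug = d$drug[i],
          rule = "qpd_repair", field = "days_supply",
          before = as.numeric(ds[i]), after = as.numeric(new_ds)
        )
        ds[i] <- new_ds
        flags[i] <- add_flag(flags[i], "qpd_days_supply_recalculated")
      } else {
        new_q <- med * ds[i]
        audit[[length(audit) + 1L]] <- tibble(
          person_id = d$person_id[i], start = d$start[i], drug = d$drug[i],
          rule = "qpd_repair", field = "quantity",
          before = qty[i], after = new_q
        )
        qty[i] <- new_q
        flags[i] <- add_flag(flags[i], "qpd_quantity_adjusted")
      }
    }
  }
  d$quantity <- qty
  d$days_supply <- ds
  d$flags <- flags
  out <- d %>% select(-".row") %>% finish_dispensations()
  list(
    dispensations = out,
    audit = if (length(audit)) bind_rows(audit) else empty_audit()
  )
}

#' Cap days supply at the time to the next dispensation
#'
#' For consecutive same-person, same-drug rows, a days-supply value that
#' exceeds the time to the next dispensation is reset to match that
#' interval (minimum 1 day). The last record of each person-drug sequence
#' is never capped (there is no next fill to judge against). Quantity is
#' unchanged; the daily dose is recomputed from the shortened supply.
#'
#' @param disps dispensation tibble (split doses already consolidated:
#'   duplicate same-day rows raise an integrity error).
#' @return List: `dispensations`, `audit`.
#' @export
cap_days_supply <- function(disps) {
  d <- disps %>% arrange(.data$person_id, .data$drug, .data$start)
  dup <- d %>%
    group_by(.data$person_id, .data$drug, .data$start) %>%
    filter(n() > 1L)
  if (nrow(dup)) {
    abort("integrity error: same-day duplicate rows; consolidate split doses first")
  }
  d <- d %>%
    group_by(.data$person_id, .data$drug) %>%
    mutate(.to_next = lead(.data$start) - .data$start) %>%
    ungroup()
  hit <- !is.na(d$.to_next) & d$days_supply > d$.to_next
  audit <- if (any(hit)) {
    tibble(
      person_id = d$person_id[hit], start = d$start[hit], drug = d$drug[hit],
      rule = "cap_days_supply", field = "days_supply",
      before = as.numeric(d$days_supply[hit]),
      after = as.numeric(pmax(1L, d$.to_next[hit]))
    )
  } else {
    empty_audit()
  }
  d$days_supply[hit] <- pmax(1L, d$.to_next[hit])
  d$flags[hit] <- add_flag(d$flags[hit], "days_supply_capped")
  out <- d %>% select(-".to_next") %>% finish_dispensations()
  list(dispensations = out, audit = audit)
}

#' Full cleaning pipeline
#'
#' Runs consolidate -> QPD repair -> days-supply cap, in that order:
#' capping must see consolidated dates, and QPD repair should judge the
#' original supplies. The pipeline is idempotent — cleaning a cleaned table
#' changes nothing.
#'
#' @param disps raw dispensation tibble.
#' @param config a [cleaning_config()].
#' @return List of class `oat_cleaning_result`: `dispensations` (corrected),
#'   `report` (counts per rule), `audit` (row-level trail).
#' @export
clean_dispensations <- function(disps, config = cleaning_config()) {
  n_input <- nrow(disps)
  s1 <- consolidate_split_doses(disps)
  s2 <- repair_qpd_outliers(s1$dispensations, config)
  s3 <- cap_days_supply(s2$dispensations)
  audit <- bind_rows(s1$audit, s2$audit, s3$audit)
  per_rule <- audit %>% count(.data$rule, name = "n")
  n_flagged <- nrow(audit)
  n_corrected <- sum(audit$rule != "split_dose_strength_conflict")
  report <- structure(
    list(
      n_input = n_input,
      n_flagged = n_flagged,
      n_corrected = n_corrected,
      per_rule = per_rule
    ),
    class = "oat_cleaning_report"
  )
  structure(
    list(dispensations = s3$dispensations, report = report, audit = audit),
    class = "oat_cleaning_result"
  )
}

#' @export
print.oat_cleaning_report <- function(x, ...) {
  cat("<oat_cleaning_report>\n")
  cat(
    sprintf(
      "  %d input rows; %d flagged (%.2f%%); %d corrected\n",
      x$n_input, x$n_flagged,
      if (x$n_input > 0) 100 * x$n_flagged / x$n_input else 0,
      x$n_corrected
    )
  )
  if (nrow(x$per_rule)) {
    for (i in seq_len(nrow(x$per_rule))) {
      cat(sprintf("  %-28s %d\n", x$per_rule$rule[i], x$per_rule$n[i]))
    }
  }
  invisible(x)
}
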