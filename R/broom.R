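#' Tidy an episode set
#'
#' Returns the episode table as a plain tibble with the drug sequence
#' flattened to a semicolon-joined string (the list-column of dose
#' segments is dropped; use [episode_assignments()] for record-level
#' detail).
#'
#' @param x an `oat_episodes` object.
#' @param ... unused.
#' @return A tibble, one row per episode.
#' @method tidy oat_episodes
#' @export
tidy.oat_episodes <- function(x, ...) {
  as_tibble(x) %>%
    mutate(drug_sequence = purrr::map_chr(.data$drug_sequence, paste, collapse = ";")) %>%
    select(-"dose_segments")
}

#' One-row summary of an episode set
#'
#' @param x an `oat_episodes` object.
#' @param ... unused.
#' @return A one-row tibble: episode and person counts, percentage of each
#'   episode type, switch count, bridged hospital days, and duration
#'   quartiles (Tukey hinges).
#' @method glance oat_episodes
#' @export
glance.oat_episodes <- function(x, ...) {
  ep <- as_tibble(x)
  pct <- function(t) if (nrow(ep)) 100 * sum(ep$type == t) / nrow(ep) else NA_real_
  tibble(
    n_episodes = nrow(ep),
    n_persons = dplyr::n_distinct(ep$person_id),
    pct_monotherapy = pct("monotherapy"),
    pct_transition = pct("transition"),
    pct_multitherapy = pct("multitherapy"),
    pct_transition_multitherapy = pct("transition_multitherapy"),
    n_switches = sum(ep$n_switches),
    bridged_hospital_days = sum(ep$bridged_hospital_days),
    median_duration = if (nrow(ep)) fivenum(ep$duration_days)[3] else NA_real_,
    q1_duration = if (nrow(ep)) fivenum(ep$duration_days)[2] else NA_real_,
    q3_duration = if (nrow(ep)) fivenum(ep$duration_days)[4] else NA_real_
  )
}
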