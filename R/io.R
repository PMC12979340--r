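#' Day-index conversion
#'
#' All temporal logic runs on integer day indices (days since 1970-01-01,
#' the `Date` epoch). Conversion is order-preserving and invertible;
#' time-of-day is discarded because community-pharmacy dispensing is
#' date-resolved.
#'
#' @param x a `Date` (or something `as.Date()` accepts) for `as_day()`;
#'   an integer day index for `day_as_date()`.
#' @return `as_day()`: integer vector. `day_as_date()`: `Date` vector.
#' @export
as_day <- function(x) as.integer(as.Date(x))

#' @rdname as_day
#' @export
day_as_date <- function(x) as.Date(as.integer(x), origin = "1970-01-01")

# Assemble the derived columns every dispensation carries. Coverage is the
# half-open window [start, start + days_supply); daily dose is
# quantity * strength / days_supply (mg/day); qpd is quantity / days_supply.
finish_dispensations <- function(d) {
  d %>%
    mutate(
      days_supply = as.integer(.data$days_supply),
      start = as.integer(.data$start),
      end = .data$start + .data$days_supply,
      daily_dose = .data$quantity * .data$strength / .data$days_supply,
      qpd = .data$quantity / .data$days_supply
    ) %>%
    arrange(.data$person_id, .data$start, .data$drug, .data$end) %>%
    select(
      "person_id", "din", "drug", "service_date", "start", "end",
      "days_supply", "quantity", "strength", "daily_dose", "qpd", "flags",
      dplyr::everything()
    ) %>%
    as_tibble()
}

#' Build a dispensation table in code
#'
#' Convenience constructor for programmatic (test/simulation) use: takes
#' day indices directly and fills in the derived columns
#' (`end`, `daily_dose`, `qpd`, `service_date`).
#'
#' @param person_id,drug,start,days_supply vectors (recycled to a common
#'   length); `start` is an integer day index.
#' @param quantity,strength dispensed units and mg per unit; default to a
#'   100 mg/day dose at unit strength.
#' @param din optional product code.
#' @return A dispensation tibble sorted by (person, start, drug, end).
#' @examples
#' dispensations("p1", "methadone", start = c(0, 7), days_supply = 7)
#' @export
dispensations <- function(person_id, drug, start, days_supply,
                          quantity = days_supply * 100, strength = 1,
                          din = NA_character_) {
  d <- tibble(
    person_id = as.character(person_id), din = as.character(din),
    drug = as.character(drug), start = as.integer(start),
    days_supply = as.integer(days_supply),
    quantity = as.numeric(quantity), strength = as.numeric(strength)
  )
  if (any(d$days_supply < 1L)) abort("days_supply must be >= 1")
  if (any(d$quantity <= 0) || any(d$strength <= 0)) {
    abort("quantity and strength must be positive")
  }
  d$service_date <- day_as_date(d$start)
  d$flags <- NA_character_
  finish_dispensations(d)
}

#' Read dispensation records
#'
#' Parses a delimited-text extract with header columns
#' `person_id,din,date_of_service,days_supply,quantity,strength`
#' (ISO-8601 dates), resolves each product code through the catalog, and
#' computes derived fields (coverage interval, daily dose, quantity per
#' day). Rows that cannot be used — unresolvable `din`, non-positive
#' `days_supply` or `quantity`, unparseable date — are rejected, not
#' silently dropped: they are returned in the `rejected` attribute with row
#' numbers and reasons, and a warning summarises the count.
#'
#' @param path CSV path.
#' @param catalog catalog tibble (see [read_drug_catalog()]).
#' @return Dispensation tibble; attribute `rejected` holds a tibble
#'   (`row`, `reason`, plus the raw columns) of rejected rows.
#' @export
read_dispensations <- function(path, catalog = default_drug_catalog()) {
  catalog <- validate_catalog(catalog)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("person_id", "din", "date_of_service", "days_supply", "quantity", "strength")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste("dispensation file is missing column(s):", paste(missing, collapse = ", ")))
  }
  raw <- raw %>% mutate(row = row_number())
  parsed <- raw %>%
    mutate(
      service_date = suppressWarnings(as.Date(.data$date_of_service, format = "%Y-%m-%d")),
      days_supply_n = suppressWarnings(as.integer(.data$days_supply)),
      quantity_n = suppressWarnings(as.numeric(.data$quantity)),
      strength_n = suppressWarnings(as.numeric(.data$strength))
    ) %>%
    left_join(catalog %>% select("din", "drug_class"), by = "din") %>%
    mutate(reason = case_when(
      is.na(.data$drug_class) ~ paste0("unknown din '", .data$din, "'"),
      is.na(.data$service_date) ~ paste0("unparseable date '", .data$date_of_service, "'"),
      is.na(.data$days_supply_n) | .data$days_supply_n < 1L ~
        paste0("non-positive days_supply '", .data$days_supply, "'"),
      is.na(.data$quantity_n) | .data$quantity_n <= 0 ~
        paste0("non-positive quantity '", .data$quantity, "'"),
      is.na(.data$strength_n) | .data$strength_n <= 0 ~
        paste0("non-positive strength '", .data$strength, "'"),
      TRUE ~ NA_character_
    ))
  rejected <- parsed %>%
    filter(!is.na(.data$reason)) %>%
    select("row", "reason", all_of(need))
  ok <- parsed %>%
    filter(is.na(.data$reason)) %>%
    mutate(
      drug = .data$drug_class,
      start = as_day(.data$service_date),
      days_supply = .data$days_supply_n,
      quantity = .data$quantity_n,
      strength = .data$strength_n,
      flags = NA_character_
    ) %>%
    select(
      "person_id", "din", "drug", "service_date", "start",
      "days_supply", "quantity", "strength", "flags"
    ) %>%
    finish_dispensations()
  if (nrow(rejected)) {
    warn(paste0(
      nrow(rejected), " row(s) rejected while reading ", path,
      " (see attr(., 'rejected'))"
    ))
  }
  attr(ok, "rejected") <- rejected
  ok
}

#' Read hospitalization intervals
#'
#' CSV with header `person_id,admit_date,discharge_date` (ISO-8601).
#' Discharge is exclusive; overlapping or abutting stays of one person are
#' merged, since they represent continuous inpatient time.
#'
#' @param path CSV path.
#' @return Tibble `person_id`, `admit`, `discharge` (integer day indices).
#' @export
read_hospitalizations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("person_id", "admit_date", "discharge_date")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste("hospitalization file is missing column(s):", paste(missing, collapse = ", ")))
  }
  stays <- raw %>%
    mutate(
      admit = as_day(as.Date(.data$admit_date)),
      discharge = as_day(as.Date(.data$discharge_date))
    ) %>%
    select("person_id", "admit", "discharge")
  if (any(stays$discharge <= stays$admit)) {
    abort("hospital stays must satisfy discharge > admit")
  }
  merge_stays(stays)
}

#' Merge overlapping hospital stays per person
#' @param stays tibble `person_id`, `admit`, `discharge`.
#' @return Same shape, disjoint and sorted within person.
#' @export
merge_stays <- function(stays) {
  stays %>%
    arrange(.data$person_id, .data$admit, .data$discharge) %>%
    group_by(.data$person_id) %>%
    mutate(.grp = cumsum(is.na(lag(.data$discharge)) |
      .data$admit > cummax(dplyr::coalesce(lag(.data$discharge), .data$admit)))) %>%
    group_by(.data$person_id, .data$.grp) %>%
    summarise(
      admit = min(.data$admit), discharge = max(.data$discharge),
      .groups = "drop"
    ) %>%
    select(-dplyr::any_of(".grp"))
}

# ---- episode serialisation -------------------------------------------------

serialize_segments <- function(seg_list) {
  purrr::map_chr(seg_list, function(s) {
    if (is.null(s) || nrow(s) == 0) return("")
    paste(sprintf("%d:%d:%s:%.6g", s$start, s$end, s$drug, s$dose), collapse = "|")
  })
}

parse_segments <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(start = integer(), end = integer(), drug = character(), dose = double()))
    }
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(
      start = as.integer(purrr::map_chr(parts, 1)),
      end = as.integer(purrr::map_chr(parts, 2)),
      drug = purrr::map_chr(parts, 3),
      dose = as.numeric(purrr::map_chr(parts, 4))
    )
  })
}

#' Write and read an episode table
#'
#' One CSV row per episode: dates rendered ISO-8601, the drug sequence
#' semicolon-joined, dose segments serialised as
#' `start:end:drug:dose|...` day-index pieces. `read_episodes()` restores
#' the tibble losslessly (round trip is the identity on valid tables).
#'
#' @param episodes an episode tibble from [build_episodes()].
#' @param path output CSV path.
#' @return `write_episodes()`: the path, invisibly. `read_episodes()`: the
#'   episode tibble.
#' @export
write_episodes <- function(episodes, path) {
  ep <- as_tibble(episodes)
  if (nrow(ep)) {
    overlap_check <- ep %>%
      arrange(.data$person_id, .data$start) %>%
      group_by(.data$person_id) %>%
      mutate(bad = !is.na(lag(.data$end)) & .data$start < lag(.data$end)) %>%
      ungroup()
    if (any(overlap_check$bad)) {
      abort("integrity error: overlapping episodes for one person")
    }
  }
  out <- ep %>%
    mutate(
      start_date = format(day_as_date(.data$start)),
      end_date = format(day_as_date(.data$end)),
      drug_sequence = purrr::map_chr(.data$drug_sequence, paste, collapse = ";"),
      dose_segments = serialize_segments(.data$dose_segments)
    ) %>%
    select(
      "person_id", "episode_id", "start_date", "end_date", "type",
      "drug_sequence", "n_dispensations", "duration_days",
      "max_co_dispensation_days", "n_switches", "bridged_hospital_days",
      "dose_segments"
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    episode_id = readr::col_character(),
    start_date = readr::col_date(),
    end_date = readr::col_date(),
    type = readr::col_character(),
    drug_sequence = readr::col_character(),
    n_dispensations = readr::col_integer(),
    duration_days = readr::col_integer(),
    max_co_dispensation_days = readr::col_integer(),
    n_switches = readr::col_integer(),
    bridged_hospital_days = readr::col_integer(),
    dose_segments = readr::col_character()
  ))
  raw %>%
    mutate(
      start = as_day(.data$start_date),
      end = as_day(.data$end_date),
      drug_sequence = purrr::map(.data$drug_sequence, ~ strsplit(.x, ";", fixed = TRUE)[[1]]),
      dose_segments = parse_segments(.data$dose_segments)
    ) %>%
    select(
      "person_id", "episode_id", "start", "end", "type", "drug_sequence",
      "n_dispensations", "duration_days", "max_co_dispensation_days",
      "n_switches", "bridged_hospital_days", "dose_segments"
    )
}

#' Write a relations table
#'
#' @param annotated output of [annotate_relations()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_relations <- function(annotated, path) {
  annotated %>%
    group_by(.data$person_id) %>%
    mutate(index = row_number()) %>%
    ungroup() %>%
    select("person_id", "drug", "index", "label", "gap_days", "overlap_days") %>%
    readr::write_csv(path)
  invisible(path)
}
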