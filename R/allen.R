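#' Allen's interval algebra on dispensation coverage intervals
#'
#' A dispensation covers the half-open integer-day window
#' `[start, start + days_supply)`. Any ordered pair of non-degenerate
#' intervals stands in exactly one of 13 temporal relations: seven base
#' relations (*meets*, *before*, *overlaps*, *starts*, *finishes*,
#' *contains*, *equals*) and their inverses, with *equals* self-inverse.
#' `allen_classify()` is vectorised over the four endpoint vectors and
#' returns, for each pair, the relation label plus the gap length (uncovered
#' days between the intervals, for *before*/*after*) and the overlap length
#' (shared covered days, when at least one day is shared).
#'
#' Under the half-open convention two intervals with `x_end == y_start`
#' share no covered day and no gap: that is *meets*, the natural reading of
#' back-to-back days-supply.
#'
#' @param x_start,x_end,y_start,y_end integer day indices; each interval must
#'   satisfy `end > start`.
#' @return A tibble with one row per pair: `label` (character), `gap_days`
#'   (integer, `NA` unless *before*/*after*), `overlap_days` (integer, `NA`
#'   unless the intervals share at least one covered day).
#' @examples
#' allen_classify(0, 5, 5, 8)   # meets
#' allen_classify(0, 5, 0, 5)   # equals
#' allen_classify(0, 10, 7, 17) # overlaps, 3 shared days
#' @export
allen_classify <- function(x_start, x_end, y_start, y_end) {
  n <- max(length(x_start), length(x_end), length(y_start), length(y_end))
  x_start <- rep_len(as.integer(x_start), n)
  x_end <- rep_len(as.integer(x_end), n)
  y_start <- rep_len(as.integer(y_start), n)
  y_end <- rep_len(as.integer(y_end), n)
  if (any(x_end <= x_start, na.rm = TRUE) || any(y_end <= y_start, na.rm = TRUE)) {
    abort("degenerate interval: every interval must satisfy end > start")
  }
  label <- dplyr::case_when(
    x_end < y_start ~ "before",
    y_end < x_start ~ "after",
    x_end == y_start ~ "meets",
    y_end == x_start ~ "met_by",
    x_start == y_start & x_end == y_end ~ "equals",
    x_start == y_start & x_end < y_end ~ "starts",
    x_start == y_start & x_end > y_end ~ "started_by",
    x_end == y_end & x_start > y_start ~ "finishes",
    x_end == y_end & x_start < y_start ~ "finished_by",
    x_start < y_start & y_end < x_end ~ "contains",
    y_start < x_start & x_end < y_end ~ "during",
    x_start < y_start & y_start < x_end & x_end < y_end ~ "overlaps",
    y_start < x_start & x_start < y_end & y_end < x_end ~ "overlapped_by"
  )
  gap <- dplyr::case_when(
    label == "before" ~ y_start - x_end,
    label == "after" ~ x_start - y_end,
    TRUE ~ NA_integer_
  )
  ov <- pmin(x_end, y_end) - pmax(x_start, y_start)
  ov <- ifelse(!is.na(ov) & ov >= 1L, ov, NA_integer_)
  tibble(label = label, gap_days = as.integer(gap), overlap_days = as.integer(ov))
}

#' The 13 Allen relation labels
#'
#' @return Character vector of the seven base labels followed by their
#'   inverses (*equals* appears once; it is its own inverse).
#' @export
allen_labels <- function() {
  c(
    "meets", "before", "overlaps", "starts", "finishes", "contains", "equals",
    "met_by", "after", "overlapped_by", "started_by", "finished_by", "during"
  )
}

.allen_inverse_map <- c(
  meets = "met_by", met_by = "meets",
  before = "after", after = "before",
  overlaps = "overlapped_by", overlapped_by = "overlaps",
  starts = "started_by", started_by = "starts",
  finishes = "finished_by", finished_by = "finishes",
  contains = "during", during = "contains",
  equals = "equals",
  not_applicable = "not_applicable"
)

.allen_base_map <- c(
  meets = "meets", met_by = "meets",
  before = "before", after = "before",
  overlaps = "overlaps", overlapped_by = "overlaps",
  starts = "starts", started_by = "starts",
  finishes = "finishes", finished_by = "finishes",
  contains = "contains", during = "contains",
  equals = "equals",
  not_applicable = "not_applicable"
)

#' Inverse of an Allen relation label
#'
#' `allen_inverse(label(x, y)) == label(y, x)` for every interval pair;
#' `equals` and the `not_applicable` sentinel are fixed points.
#'
#' @param label character vector of relation labels.
#' @return Character vector of inverse labels.
#' @export
allen_inverse <- function(label) {
  out <- unname(.allen_inverse_map[label])
  if (anyNA(out)) abort("unknown Allen relation label")
  out
}

#' Fold inverse labels onto their base relation
#'
#' Reporting convention used for frequency tables: an inverse label is
#' counted under its base relation, so that e.g. a new record that
#' *finishes* its predecessor's coverage is tabulated as *finishes* even
#' though, read as `label(previous, new)`, the literal label is
#' *finished_by*.
#'
#' @param label character vector of relation labels.
#' @return Character vector of base labels (plus `not_applicable`).
#' @export
allen_base <- function(label) {
  out <- unname(.allen_base_map[label])
  if (anyNA(out)) abort("unknown Allen relation label")
  out
}

#' Annotate a dispensation table with consecutive-pair relations
#'
#' For each person (and each drug class, under `scope = "same_drug"`) the
#' records are taken in chronological order and each record is classified
#' against the immediately preceding record in scope. The first record of
#' each sequence receives the `not_applicable` sentinel. Only
#' consecutive-pair relations are computed, matching the sequential episode
#' construction; relations between non-adjacent records are resolved later
#' by the episode builder's active-thread comparison.
#'
#' @param disps a dispensation tibble with columns `person_id`, `drug`,
#'   `start`, `end` (integer day indices, half-open).
#' @param scope `"same_drug"` chains records within a person-drug pair;
#'   `"cross_drug"` chains all of a person's records regardless of drug.
#' @return The input with columns `label`, `gap_days`, `overlap_days`
#'   appended, rows sorted by (person, start, drug, end).
#' @export
annotate_relations <- function(disps, scope = c("same_drug", "cross_drug")) {
  scope <- match.arg(scope)
  stopifnot(all(c("person_id", "drug", "start", "end") %in% names(disps)))
  grouping <- if (scope == "same_drug") c("person_id", "drug") else "person_id"
  disps %>%
    arrange(.data$person_id, .data$start, .data$drug, .data$end) %>%
    group_by(across(all_of(grouping))) %>%
    mutate(.ps = lag(.data$start), .pe = lag(.data$end)) %>%
    ungroup() %>%
    mutate(.first = is.na(.data$.ps)) %>%
    (function(d) {
      idx <- !d$.first
      rel <- tibble(
        label = rep("not_applicable", nrow(d)),
        gap_days = NA_integer_, overlap_days = NA_integer_
      )
      if (any(idx)) {
        rel[idx, ] <- allen_classify(d$.ps[idx], d$.pe[idx], d$start[idx], d$end[idx])
      }
      dplyr::bind_cols(
        d %>% select(-".ps", -".pe", -".first"),
        rel
      )
    })
}

#' Tabulate relation frequencies by drug class
#'
#' Counts and percentages of consecutive-pair relations per drug, in the
#' eight-category reporting scheme (seven base relations plus
#' `not_applicable`; inverse labels are folded onto their base via
#' [allen_base()]). Percentages are computed within each drug column and sum
#' to 100 up to rounding.
#'
#' @param annotated output of [annotate_relations()] (needs `drug`, `label`).
#' @return Tibble with columns `drug`, `relation`, `n`, `pct`, sorted by drug
#'   then the canonical relation order. Empty input yields an empty tibble.
#' @export
relation_frequencies <- function(annotated) {
  if (nrow(annotated) == 0) {
    return(tibble(drug = character(), relation = character(), n = integer(), pct = double()))
  }
  lev <- c(
    "not_applicable", "meets", "before", "overlaps",
    "starts", "finishes", "contains", "equals"
  )
  annotated %>%
    mutate(relation = factor(allen_base(.data$label), levels = lev)) %>%
    count(.data$drug, .data$relation, .drop = FALSE) %>%
    group_by(.data$drug) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(relation = as.character(.data$relation))
}
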