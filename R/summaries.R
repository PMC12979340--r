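#' Temporal-margin sensitivity of date shifts
#'
#' Recoding a short same-drug overlap as *meets* shifts the later record's
#' service date forward, and shifts cascade along chains of early refills.
#' This report quantifies, for each candidate margin, how far service
#' dates move: it runs the recoding cascade ([recode_overlaps()]) at each
#' `epsilon` and summarises the per-record shift (shifted minus original
#' service date, zero for unshifted records) per drug and overall. With
#' `epsilon = 0` no recoding occurs and all statistics are zero; the mean
#' shift is non-decreasing in `epsilon`.
#'
#' @param disps cleaned dispensation tibble.
#' @param epsilons integer vector of margins (days) to compare.
#' @return Tibble: `epsilon`, `drug` (including `"all"`), `n`, `n_shifted`,
#'   `mean_shift`, `sd_shift`, `median_shift`, `mode_shift`, `max_shift`.
#' @export
margin_sensitivity <- function(disps, epsilons = c(0L, 7L, 14L)) {
  stat_mode <- function(x) {
    tb <- table(x)
    as.numeric(names(tb)[which.max(tb)])
  }
  purrr::map(epsilons, function(eps) {
    rec <- recode_overlaps(disps, epsilon = eps)
    shift <- rec$start - rec$original_start
    per_drug <- tibble(drug = rec$drug, shift = shift) %>%
      group_by(.data$drug) %>%
      summarise(
        n = n(), n_shifted = sum(.data$shift > 0),
        mean_shift = mean(.data$shift), sd_shift = sd(.data$shift),
        median_shift = median(.data$shift), mode_shift = stat_mode(.data$shift),
        max_shift = max(.data$shift), .groups = "drop"
      )
    overall <- tibble(
      drug = "all", n = length(shift), n_shifted = sum(shift > 0),
      mean_shift = mean(shift), sd_shift = sd(shift),
      median_shift = median(shift), mode_shift = stat_mode(shift),
      max_shift = max(shift)
    )
    bind_rows(per_drug, overall) %>% mutate(epsilon = eps, .before = 1)
  }) %>% bind_rows()
}

#' Episode-type distribution
#'
#' Counts, percentages and duration quartiles of episodes, overall and per
#' type. Quartiles are Tukey hinges (the inclusive median-of-halves rule).
#'
#' @param episodes an episode tibble from [build_episodes()].
#' @return Tibble: `type` (including `"all"`), `n`, `pct`,
#'   `median_duration`, `q1_duration`, `q3_duration`. Empty input yields an
#'   empty tibble.
#' @export
episode_type_distribution <- function(episodes) {
  ep <- as_tibble(episodes)
  if (nrow(ep) == 0) {
    return(tibble(
      type = character(), n = integer(), pct = double(),
      median_duration = double(), q1_duration = double(), q3_duration = double()
    ))
  }
  per_type <- ep %>%
    group_by(.data$type) %>%
    summarise(
      n = n(),
      median_duration = fivenum(.data$duration_days)[3],
      q1_duration = fivenum(.data$duration_days)[2],
      q3_duration = fivenum(.data$duration_days)[4],
      .groups = "drop"
    ) %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
  overall <- tibble(
    type = "all", n = nrow(ep), pct = 100,
    median_duration = fivenum(ep$duration_days)[3],
    q1_duration = fivenum(ep$duration_days)[2],
    q3_duration = fivenum(ep$duration_days)[4]
  )
  bind_rows(per_type, overall) %>%
    select(
      "type", "n", "pct", "median_duration", "q1_duration", "q3_duration"
    )
}
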