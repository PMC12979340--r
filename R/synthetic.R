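#' Reference relation mixtures per drug class
#'
#' Observed distribution of consecutive-pair temporal relations between
#' same-type OAT dispensations in a large provincial claims cohort,
#' expressed as proportions over the eight reporting categories
#' (seven base relations plus `not_applicable` for sequence-initial
#' records). The *before* relation dominates every drug; *equals* —
#' same-day co-supply from witnessed ingestion and split dosing — is
#' pronounced for buprenorphine/naloxone and SROM. These are the synthetic
#' generator's default mixtures; all overridable.
#'
#' @return Tibble `drug`, `relation`, `prob` (probabilities sum to 1 within
#'   drug).
#' @export
oat_relation_mixtures <- function() {
  counts <- list(
    methadone = c(
      not_applicable = 1331, meets = 3752, before = 1778136, overlaps = 406,
      starts = 26, finishes = 113, contains = 540, equals = 4091
    ),
    bup_nal = c(
      not_applicable = 529, meets = 466, before = 48452, overlaps = 265,
      starts = 57, finishes = 27, contains = 149, equals = 13647
    ),
    srom = c(
      not_applicable = 690, meets = 1677, before = 159516, overlaps = 2069,
      starts = 140, finishes = 112, contains = 355, equals = 43401
    ),
    ioat = c(
      not_applicable = 175, meets = 80, before = 33528, overlaps = 72,
      starts = 25, finishes = 11, contains = 34, equals = 660
    )
  )
  purrr::imap(counts, function(x, dg) {
    tibble(drug = dg, relation = names(x), prob = as.numeric(x) / sum(x))
  }) %>% bind_rows()
}

#' Synthetic cohort configuration
#'
#' Parameters of the seeded claims generator. Defaults describe a cohort
#' the episode machinery is meant for: per-drug relation mixtures from
#' [oat_relation_mixtures()]; days-supply ranges reflecting dispensing
#' practice (iOAT 1–3 days, methadone and SROM 1–7, buprenorphine/naloxone
#' 7–28 including the monthly depot); occasional long gaps that break
#' episodes; cross-drug transition and multitherapy patterns; error
#' injection (split doses, QPD outliers, supply overruns) at configurable
#' rates; hospital stays.
#'
#' @param n_persons number of persons.
#' @param mean_records mean same-drug records per person (Poisson, min 2).
#' @param drug_weights named sampling weights for each person's drug class.
#' @param mixtures relation-mixture tibble (`drug`, `relation`, `prob`).
#' @param days_supply named list of `c(min, max)` supply ranges per drug.
#' @param gap_range within-gap *before* distances are drawn uniformly from
#'   `1:gap` of the drug; `p_long_gap` of *before* relations instead draw
#'   `gap + sample(long_gap_extra)`, creating genuine discontinuations.
#' @param p_long_gap,long_gap_extra see above.
#' @param transition_rate,multitherapy_rate per-person probabilities of
#'   appending a cross-drug transition / long-co-dispensation tail.
#' @param split_dose_rate,qpd_outlier_rate,supply_overrun_rate per-record
#'   error-injection probabilities.
#' @param hospitalization_rate per-person probability of one hospital stay;
#'   `stay_length` its uniform day range.
#' @param permissible_gaps,epsilon_same drug gaps and same-drug margin the
#'   ground-truth replay assumes (keep in sync with the [episode_config()]
#'   used downstream).
#' @param stay_length length-2 integer range of stay durations.
#' @return List of class `oat_sim_config`.
#' @export
sim_config <- function(n_persons = 150L,
                       mean_records = 12,
                       drug_weights = c(methadone = 0.55, bup_nal = 0.15, srom = 0.2, ioat = 0.1),
                       mixtures = oat_relation_mixtures(),
                       days_supply = list(
                         methadone = c(1L, 7L), bup_nal = c(7L, 28L),
                         srom = c(1L, 7L), ioat = c(1L, 3L)
                       ),
                       p_long_gap = 0.15,
                       long_gap_extra = c(1L, 60L),
                       transition_rate = 0.05,
                       multitherapy_rate = 0.03,
                       split_dose_rate = 0,
                       qpd_outlier_rate = 0,
                       supply_overrun_rate = 0,
                       hospitalization_rate = 0,
                       stay_length = c(3L, 21L),
                       permissible_gaps = c(methadone = 5L, bup_nal = 6L, srom = 5L, ioat = 3L),
                       epsilon_same = 7L) {
  probs <- mixtures %>% group_by(.data$drug) %>% summarise(s = sum(.data$prob))
  if (any(abs(probs$s - 1) > 1e-9)) abort("relation mixtures must sum to 1 per drug")
  rates <- c(
    transition_rate, multitherapy_rate, split_dose_rate,
    qpd_outlier_rate, supply_overrun_rate, hospitalization_rate, p_long_gap
  )
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  structure(
    list(
      n_persons = as.integer(n_persons), mean_records = mean_records,
      drug_weights = drug_weights, mixtures = mixtures,
      days_supply = days_supply, p_long_gap = p_long_gap,
      long_gap_extra = as.integer(long_gap_extra),
      transition_rate = transition_rate, multitherapy_rate = multitherapy_rate,
      split_dose_rate = split_dose_rate, qpd_outlier_rate = qpd_outlier_rate,
      supply_overrun_rate = supply_overrun_rate,
      hospitalization_rate = hospitalization_rate,
      stay_length = as.integer(stay_length),
      permissible_gaps = permissible_gaps,
      epsilon_same = as.integer(epsilon_same)
    ),
    class = "oat_sim_config"
  )
}

# uniform integer draw from lo:hi
rint <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))

#' Realize an interval satisfying a given Allen relation
#'
#' The constructive inverse of [allen_classify()]: returns an interval `y`
#' such that `allen_classify(prev, y)$label` equals `label`, with the free
#' lengths (duration, gap, overlap, extensions) drawn uniformly from the
#' supplied ranges, restricted to the sub-range the label admits. Labels
#' that are structurally infeasible for the given previous interval (e.g.
#' `contains` when the previous interval spans fewer than 3 days, or
#' `starts` when no admissible duration exceeds it) raise an error.
#'
#' @param label one of the 13 Allen labels (`not_applicable` is not
#'   realizable).
#' @param prev_start,prev_end the reference interval.
#' @param dur_range length-2 integer range for the new interval's duration;
#'   lengths are drawn uniformly from the sub-range the label admits.
#' @param gap_range length-2 integer range for *before*/*after* gaps.
#' @return Named integer vector `c(start, end)`.
#' @export
realize_relation <- function(label, prev_start, prev_end,
                             dur_range = c(1L, 28L), gap_range = c(1L, 14L)) {
  ps <- as.integer(prev_start)
  pe <- as.integer(prev_end)
  D <- pe - ps
  lo <- dur_range[1]
  hi <- dur_range[2]
  # durations are drawn uniformly from the admissible sub-range of
  # [lo, hi]; an empty sub-range means the label is infeasible here
  draw_between <- function(a, b) {
    a <- max(a, lo)
    b <- min(b, hi)
    if (a > b) {
      abort(paste0("cannot realize '", label, "': no admissible duration in range"))
    }
    rint(1L, a, b)
  }
  res <- switch(label,
    equals = c(ps, pe),
    meets = {
      L <- rint(1L, lo, hi)
      c(pe, pe + L)
    },
    met_by = {
      L <- rint(1L, lo, hi)
      c(ps - L, ps)
    },
    before = {
      g <- rint(1L, gap_range[1], gap_range[2])
      L <- rint(1L, lo, hi)
      c(pe + g, pe + g + L)
    },
    after = {
      g <- rint(1L, gap_range[1], gap_range[2])
      L <- rint(1L, lo, hi)
      c(ps - g - L, ps - g)
    },
    overlaps = {
      if (D < 2L || hi < 2L) abort("cannot realize 'overlaps': intervals too short")
      ov <- rint(1L, 1L, min(D - 1L, hi - 1L))
      L <- draw_between(ov + 1L, hi)
      c(pe - ov, pe - ov + L)
    },
    overlapped_by = {
      if (D < 2L || hi < 2L) abort("cannot realize 'overlapped_by': intervals too short")
      ov <- rint(1L, 1L, min(D - 1L, hi - 1L))
      L <- draw_between(ov + 1L, hi)
      c(ps + ov - L, ps + ov)
    },
    starts = {
      L <- draw_between(D + 1L, hi)
      c(ps, ps + L)
    },
    started_by = {
      if (D < 2L) abort("cannot realize 'started_by': previous interval too short")
      L <- draw_between(1L, D - 1L)
      c(ps, ps + L)
    },
    finishes = {
      L <- draw_between(D + 1L, hi)
      c(pe - L, pe)
    },
    finished_by = {
      if (D < 2L) abort("cannot realize 'finished_by': previous interval too short")
      L <- draw_between(1L, D - 1L)
      c(pe - L, pe)
    },
    contains = {
      if (D < 3L) abort("cannot realize 'contains': previous interval too short")
      L <- draw_between(1L, D - 2L)
      ys <- rint(1L, ps + 1L, pe - L - 1L)
      c(ys, ys + L)
    },
    during = {
      L <- draw_between(D + 2L, hi)
      ext <- rint(1L, 1L, L - D - 1L)
      c(ps - ext, ps - ext + L)
    },
    abort(paste0("unknown or unrealizable label '", label, "'"))
  )
  c(start = res[1], end = res[2])
}

# category (eight-scheme) -> literal label realized against the previous
# record so that folding the re-classified label recovers the category
category_to_label <- c(
  meets = "meets", before = "before", overlaps = "overlaps",
  starts = "starts", finishes = "finished_by", contains = "contains",
  equals = "equals"
)

# can `cat` be realized against a previous interval of duration D?
category_feasible <- function(cat, D, lo, hi) {
  switch(cat,
    meets = TRUE, before = TRUE, equals = TRUE,
    overlaps = D >= 2L && hi >= 2L,
    starts = hi > D,
    finishes = D >= 2L && lo < D,
    contains = D >= 3L && lo <= D - 2L,
    FALSE
  )
}

#' Simulate a stream of same-drug dispensations from a relation mixture
#'
#' Draws `n` relation categories from an eight-category mixture
#' (`not_applicable` starts a new person's sequence), realizes each
#' interval against the immediately preceding record with
#' [realize_relation()], and returns the resulting dispensation table.
#' Because realization is chained record-to-record, re-annotating the
#' stream with [annotate_relations()] recovers the sampled categories
#' exactly; the only randomness in recovered frequencies is the multinomial
#' draw itself. Categories infeasible against a too-short previous record
#' are redrawn from the mixture (bounded retries, then *before*).
#'
#' @param n number of records.
#' @param mixture named probability vector over the eight categories, or a
#'   drug name to take the column from [oat_relation_mixtures()].
#' @param drug drug-class label for the emitted records.
#' @param dur_range,gap_range length ranges passed to [realize_relation()].
#' @return Dispensation tibble with a `category` column (the sampled
#'   category of each record).
#' @export
simulate_relation_stream <- function(n, mixture, drug = "methadone",
                                     dur_range = c(1L, 7L),
                                     gap_range = c(1L, 14L)) {
  if (is.character(mixture) && length(mixture) == 1L) {
    mx <- oat_relation_mixtures() %>% filter(.data$drug == mixture)
    if (nrow(mx) == 0) abort(paste0("no reference mixture for drug '", mixture, "'"))
    mixture <- setNames(mx$prob, mx$relation)
  }
  cats <- names(mixture)
  sampled <- sample(cats, n, replace = TRUE, prob = mixture)
  sampled[1] <- "not_applicable" # a stream necessarily opens a sequence
  lo <- dur_range[1]
  hi <- dur_range[2]
  person <- integer(n)
  st <- integer(n)
  en <- integer(n)
  pid <- 0L
  ps <- NA_integer_
  pe <- NA_integer_
  base_day <- as_day(as.Date("2015-01-01"))
  for (i in seq_len(n)) {
    cat_i <- sampled[i]
    if (cat_i == "not_applicable" || pid == 0L) {
      pid <- pid + 1L
      s <- base_day + (pid - 1L) * 4000L # sequences far apart
      L <- rint(1L, lo, hi)
      st[i] <- s
      en[i] <- s + L
      sampled[i] <- "not_applicable"
    } else {
      D <- pe - ps
      tries <- 0L
      while (!category_feasible(cat_i, D, lo, hi) && tries < 20L) {
        cat_i <- sample(setdiff(cats, "not_applicable"), 1L,
          prob = mixture[setdiff(cats, "not_applicable")]
        )
        tries <- tries + 1L
      }
      if (!category_feasible(cat_i, D, lo, hi)) cat_i <- "before"
      sampled[i] <- cat_i
      y <- realize_relation(
        category_to_label[[cat_i]], ps, pe,
        dur_range = dur_range, gap_range = gap_range
      )
      st[i] <- y[["start"]]
      en[i] <- y[["end"]]
    }
    person[i] <- pid
    ps <- st[i]
    pe <- en[i]
  }
  ds <- en - st
  tibble(
    person_id = sprintf("s%06d", person), din = NA_character_, drug = drug,
    service_date = day_as_date(st), start = st, days_supply = ds,
    quantity = as.numeric(ds) * 100, strength = 1,
    flags = NA_character_, category = sampled
  ) %>%
    finish_dispensations()
}

# ground-truth replay of the same-drug linking rules for one person's chain:
# a plain linear pass (frontier interval, shift rule, permissible gap) kept
# deliberately simple so it can serve as the reference the full state
# machine is tested against
truth_replay <- function(st, en, gap_max, eps_same) {
  n <- length(st)
  ep_start <- st[1]
  fs <- st[1]
  fe <- en[1]
  cov_end <- en[1]
  ep_first <- 1L
  eps_list <- list()
  for (i in seq_len(n)[-1]) {
    ys <- st[i]
    ye <- en[i]
    if (ys > cov_end + gap_max) {
      eps_list[[length(eps_list) + 1L]] <- c(ep_start, cov_end, i - ep_first)
      ep_start <- ys
      ep_first <- i
      fs <- ys
      fe <- ye
      cov_end <- ye
      next
    }
    if (ys > fs && ys < fe && ye > fe) { # overlaps the frontier
      ov <- fe - ys
      if (ov <= eps_same) {
        ys <- ys + ov
        ye <- ye + ov
        st[i] <- ys
        en[i] <- ye
      }
    }
    if (ye >= cov_end) {
      fs <- ys
      fe <- ye
      cov_end <- ye
    }
  }
  eps_list[[length(eps_list) + 1L]] <- c(ep_start, cov_end, n + 1L - ep_first)
  list(episodes = eps_list, st = st, en = en)
}

#' Generate a synthetic dispensation cohort with ground truth
#'
#' Per person: draws a drug class, a chain of same-drug relation
#' categories from the drug's mixture, realizes the intervals
#' record-to-record, optionally appends a cross-drug tail (a transition
#' within the previous drug's permissible gap, or a long co-dispensation
#' opening a multitherapy), draws hospital stays, and finally injects
#' errors (split doses, QPD outliers, supply overruns) at the configured
#' rates. Ground truth — episode list with types and boundaries, sampled
#' relation categories, injected-error ledger — is emitted alongside the
#' (possibly corrupted) table. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed fixing all randomness.
#' @return List of class `oat_sim`: `dispensations` (after injection),
#'   `clean_dispensations` (before injection), `truth_episodes`,
#'   `truth_relations`, `injected_errors`, `stays`, `config`, `seed`.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  disp_rows <- list()
  truth_rows <- list()
  stay_rows <- list()
  drugs <- names(cfg$drug_weights)
  dose_range <- c(
    methadone = 100, bup_nal = 16, srom = 200, ioat = 150
  )
  for (p in seq_len(cfg$n_persons)) {
    pid <- sprintf("p%05d", p)
    drug <- sample(drugs, 1L, prob = cfg$drug_weights)
    dr <- cfg$days_supply[[drug]]
    lo <- dr[1]
    hi <- dr[2]
    gmax <- unname(cfg$permissible_gaps[[drug]])
    mx <- cfg$mixtures %>% filter(.data$drug == .env$drug)
    probs <- setNames(mx$prob, mx$relation)
    probs <- probs[setdiff(names(probs), "not_applicable")]
    probs <- probs / sum(probs)
    n_rec <- max(2L, rpois(1L, cfg$mean_records))
    st <- integer(n_rec)
    en <- integer(n_rec)
    cat_seq <- character(n_rec)
    st[1] <- as_day(as.Date("2014-01-01")) + rint(1L, 0L, 1500L)
    en[1] <- st[1] + rint(1L, lo, hi)
    cat_seq[1] <- "not_applicable"
    for (i in seq_len(n_rec)[-1]) {
      D <- en[i - 1] - st[i - 1]
      cat_i <- sample(names(probs), 1L, prob = probs)
      tries <- 0L
      while (!category_feasible(cat_i, D, lo, hi) && tries < 20L) {
        cat_i <- sample(names(probs), 1L, prob = probs)
        tries <- tries + 1L
      }
      if (!category_feasible(cat_i, D, lo, hi)) cat_i <- "before"
      if (cat_i == "before") {
        long <- runif(1) < cfg$p_long_gap
        g <- if (long) {
          gmax + rint(1L, cfg$long_gap_extra[1], cfg$long_gap_extra[2])
        } else {
          rint(1L, 1L, max(1L, gmax))
        }
        L <- rint(1L, lo, hi)
        st[i] <- en[i - 1] + g
        en[i] <- st[i] + L
      } else {
        y <- realize_relation(
          category_to_label[[cat_i]], st[i - 1], en[i - 1],
          dur_range = c(lo, hi), gap_range = c(1L, max(1L, gmax))
        )
        st[i] <- y[["start"]]
        en[i] <- y[["end"]]
      }
      cat_seq[i] <- cat_i
    }
    tr <- truth_replay(st, en, gmax, cfg$epsilon_same)
    person_eps <- purrr::map(tr$episodes, function(e) {
      tibble(
        person_id = pid, start = e[1], end = e[2], type = "monotherapy",
        n_dispensations = e[3], n_switches = 0L,
        drug_sequence = list(drug)
      )
    }) %>% bind_rows()
    extra <- NULL
    u <- runif(1)
    if (u < cfg$transition_rate) {
      # transition tail: second drug within the first drug's grace period
      other <- sample(setdiff(drugs, drug), 1L)
      odr <- cfg$days_supply[[other]]
      last_end <- person_eps$end[nrow(person_eps)]
      g <- rint(1L, 0L, gmax)
      bs <- last_end + g
      be <- bs + rint(1L, odr[1], odr[2])
      extra <- tibble(person_id = pid, drug = other, start = bs, end = be)
      k <- nrow(person_eps)
      person_eps$end[k] <- be
      person_eps$type[k] <- "transition"
      person_eps$n_dispensations[k] <- person_eps$n_dispensations[k] + 1L
      person_eps$n_switches[k] <- 1L
      person_eps$drug_sequence[[k]] <- c(drug, other)
    } else if (u < cfg$transition_rate + cfg$multitherapy_rate) {
      # multitherapy tail: a long fill of the first drug, co-dispensed with
      # a second drug for more than the cross-drug margin
      other <- sample(setdiff(drugs, drug), 1L)
      last_end <- person_eps$end[nrow(person_eps)]
      a2s <- last_end
      a2e <- a2s + rint(1L, 30L, 42L)
      ov <- rint(1L, 15L, 25L)
      bs <- a2e - ov
      be <- a2e + rint(1L, 5L, 15L)
      extra <- tibble(
        person_id = pid, drug = c(drug, other),
        start = c(a2s, bs), end = c(a2e, be)
      )
      k <- nrow(person_eps)
      person_eps$end[k] <- be
      person_eps$type[k] <- "multitherapy"
      person_eps$n_dispensations[k] <- person_eps$n_dispensations[k] + 2L
      person_eps$drug_sequence[[k]] <- c(drug, other)
    }
    base <- tibble(
      person_id = pid, drug = drug,
      start = st, end = en, category = cat_seq
    )
    if (!is.null(extra)) {
      extra$category <- "cross_drug"
      base <- bind_rows(base, extra)
    }
    disp_rows[[p]] <- base
    truth_rows[[p]] <- person_eps
    if (runif(1) < cfg$hospitalization_rate) {
      admit <- rint(1L, min(base$start), max(base$end))
      stay_rows[[length(stay_rows) + 1L]] <- tibble(
        person_id = pid, admit = admit,
        discharge = admit + rint(1L, cfg$stay_length[1], cfg$stay_length[2])
      )
    }
  }
  all_rows <- bind_rows(disp_rows)
  doses <- dose_range[all_rows$drug]
  clean_tbl <- tibble(
    person_id = all_rows$person_id, din = NA_character_, drug = all_rows$drug,
    service_date = day_as_date(all_rows$start), start = all_rows$start,
    days_supply = all_rows$end - all_rows$start,
    quantity = as.numeric((all_rows$end - all_rows$start)) * doses,
    strength = 1, flags = NA_character_, category = all_rows$category
  ) %>% finish_dispensations()
  injected <- inject_errors(clean_tbl, cfg)
  truth_eps <- bind_rows(truth_rows) %>%
    mutate(duration_days = .data$end - .data$start) %>%
    arrange(.data$person_id, .data$start)
  structure(
    list(
      dispensations = injected$dispensations %>% select(-dplyr::any_of("category")),
      clean_dispensations = clean_tbl %>% select(-dplyr::any_of("category")),
      truth_episodes = truth_eps,
      truth_relations = clean_tbl %>% select("person_id", "drug", "start", "end", "category"),
      injected_errors = injected$ledger,
      stays = if (length(stay_rows)) bind_rows(stay_rows) else
        tibble(person_id = character(), admit = integer(), discharge = integer()),
      config = cfg, seed = seed
    ),
    class = "oat_sim"
  )
}

inject_errors <- function(d, cfg) {
  ledger <- list()
  n <- nrow(d)
  # split doses: one record becomes two same-day rows with half quantity each
  split_idx <- which(runif(n) < cfg$split_dose_rate)
  # supply overrun: a non-terminal record's supply overshoots the next fill
  d2 <- d %>%
    group_by(.data$person_id, .data$drug) %>%
    mutate(.next = lead(.data$start)) %>%
    ungroup()
  overrun_ok <- which(!is.na(d2$.next) & d2$.next > d2$start &
    runif(n) < cfg$supply_overrun_rate)
  overrun_ok <- setdiff(overrun_ok, split_idx)
  qpd_idx <- which(runif(n) < cfg$qpd_outlier_rate)
  qpd_idx <- setdiff(qpd_idx, c(split_idx, overrun_ok))
  out <- d
  if (length(overrun_ok)) {
    gap_to_next <- d2$.next[overrun_ok] - d2$start[overrun_ok]
    out$days_supply[overrun_ok] <- as.integer(gap_to_next + rint(length(overrun_ok), 3L, 10L))
    ledger[[length(ledger) + 1L]] <- tibble(
      person_id = d$person_id[overrun_ok], drug = d$drug[overrun_ok],
      start = d$start[overrun_ok], error = "supply_overrun"
    )
  }
  if (length(qpd_idx)) {
    out$quantity[qpd_idx] <- out$quantity[qpd_idx] * 10
    ledger[[length(ledger) + 1L]] <- tibble(
      person_id = d$person_id[qpd_idx], drug = d$drug[qpd_idx],
      start = d$start[qpd_idx], error = "qpd_outlier"
    )
  }
  if (length(split_idx)) {
    halves <- out[split_idx, ]
    out$quantity[split_idx] <- out$quantity[split_idx] / 2
    halves$quantity <- halves$quantity / 2
    out <- bind_rows(out, halves)
    ledger[[length(ledger) + 1L]] <- tibble(
      person_id = d$person_id[split_idx], drug = d$drug[split_idx],
      start = d$start[split_idx], error = "split_dose"
    )
  }
  list(
    dispensations = out %>% finish_dispensations(),
    ledger = if (length(ledger)) bind_rows(ledger) else
      tibble(person_id = character(), drug = character(), start = integer(), error = character())
  )
}
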