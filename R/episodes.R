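#' Episode construction from dispensation records
#'
#' The episode builder sweeps each person's dispensations chronologically,
#' maintaining a set of *active drug threads* (one per drug class currently
#' in use). Same-drug links apply the monotherapy rules: *meets* and
#' within-gap *before* continue the thread, short overlaps (<=
#' `epsilon_same`) are recoded to *meets* by shifting the later record
#' forward, long overlaps are retained, nested relations are aggregated
#' (doses summed over the shared period). Cross-drug links apply the
#' transition/multitherapy rules with the `epsilon_cross` margin. An
#' episode closes when every active thread has been silent for longer than
#' its drug's permissible gap.
#'
#' @name episode_construction
NULL

# ---- link decisions (single source of truth for pairwise rules) -----------

# Same-drug rule between an active thread's frontier interval [fs, fe) and
# the next record [ys, ye). Requires ys >= fs (chronological input).
same_link_decision <- function(fs, fe, ys, ye, gap_max, eps_same) {
  if (ys < fs) {
    # a prior recode shifted the frontier past this record's start; the
    # record is aggregated into coverage (no shift is defined leftward)
    return(list(decision = "continue", relation = "aggregate", shift = 0L, gap = 0L))
  }
  if (ys >= fe) {
    gap <- ys - fe
    if (gap == 0L) {
      return(list(decision = "continue", relation = "meets", shift = 0L, gap = 0L))
    }
    if (gap <= gap_max) {
      return(list(decision = "continue", relation = "before", shift = 0L, gap = gap))
    }
    return(list(decision = "discontinue", relation = "before", shift = 0L, gap = gap))
  }
  ov <- min(fe, ye) - max(fs, ys)
  if (ys > fs && ye > fe) { # overlaps
    if (ov <= eps_same) {
      return(list(decision = "continue", relation = "meets", shift = ov, gap = 0L))
    }
    return(list(decision = "continue", relation = "overlaps", shift = 0L, gap = 0L))
  }
  # starts / finishes / contains / equals (or inverses): aggregate
  list(decision = "continue", relation = "aggregate", shift = 0L, gap = 0L)
}

# Cross-drug rule between the latest active thread's frontier [fs, fe)
# (drug A, permissible gap gap_prev) and a new record [ys, ye) of drug B.
cross_link_decision <- function(fs, fe, ys, ye, gap_prev, eps_cross) {
  if (ys < fs) {
    # frontier shifted past this record's start by an earlier recode:
    # short co-dispensation is absorbed, long co-dispensation opens
    # multitherapy, mirroring the nested branches below
    ov <- max(0L, min(fe, ye) - max(fs, ys))
    if (ov <= eps_cross) {
      return(list(decision = "absorb", mechanism = NA_character_, shift = 0L, co_disp = ov))
    }
    return(list(decision = "multitherapy_open", mechanism = NA_character_, shift = 0L, co_disp = ov))
  }
  if (ys >= fe) {
    gap <- ys - fe
    if (gap == 0L) {
      return(list(decision = "transition", mechanism = "meets", shift = 0L, co_disp = 0L))
    }
    if (gap <= gap_prev) {
      return(list(
        decision = "transition", mechanism = "within_gap_before",
        shift = 0L, co_disp = 0L
      ))
    }
    return(list(decision = "new_episode", mechanism = NA_character_, shift = 0L, co_disp = 0L))
  }
  ov <- min(fe, ye) - max(fs, ys)
  if (ys == fs && ye == fe) { # equals
    if (ov <= eps_cross) {
      return(list(decision = "exclude", mechanism = NA_character_, shift = 0L, co_disp = ov))
    }
    return(list(decision = "multitherapy_open", mechanism = NA_character_, shift = 0L, co_disp = ov))
  }
  if (ye <= fe) { # new record nested in frontier: contains / started_by / finished_by
    if (ov <= eps_cross) {
      return(list(decision = "absorb", mechanism = NA_character_, shift = 0L, co_disp = ov))
    }
    return(list(decision = "multitherapy_open", mechanism = NA_character_, shift = 0L, co_disp = ov))
  }
  if (ys == fs) { # new record encompasses frontier: starts
    if (ov <= eps_cross) {
      return(list(
        decision = "absorb_takeover", mechanism = "short_overlap_recode",
        shift = 0L, co_disp = ov
      ))
    }
    return(list(decision = "multitherapy_open", mechanism = NA_character_, shift = 0L, co_disp = ov))
  }
  # genuine partial overlap
  if (ov <= eps_cross) {
    return(list(
      decision = "transition", mechanism = "short_overlap_recode",
      shift = ov, co_disp = ov
    ))
  }
  list(decision = "multitherapy_open", mechanism = NA_character_, shift = 0L, co_disp = ov)
}

#' Pairwise same-drug link decision
#'
#' Applies the monotherapy linking rules to two same-drug dispensations:
#' *meets* and *before* within the permissible gap continue the episode,
#' *before* beyond it discontinues, short overlaps are recoded to *meets*
#' (the later record shifted forward), nested relations are aggregated.
#'
#' @param x,y one-row dispensation tibbles (same person and drug), `x`
#'   first.
#' @param config an [episode_config()].
#' @return List: `decision` (`"continue"`/`"discontinue"`), `relation`
#'   (effective relation after any recoding), `gap` (uncovered days, for
#'   *before*), `y_adjusted` (`y`, shifted when a short overlap was
#'   recoded).
#' @export
link_same_drug <- function(x, y, config = episode_config()) {
  if (x$drug != y$drug) abort("link_same_drug requires two records of the same drug class")
  d <- same_link_decision(
    x$start, x$end, y$start, y$end,
    gap_for(config, x$drug), config$epsilon_same
  )
  y_adj <- y
  if (d$shift > 0L) {
    y_adj$start <- y$start + d$shift
    y_adj$end <- y$end + d$shift
    if ("service_date" %in% names(y_adj)) y_adj$service_date <- day_as_date(y_adj$start)
  }
  list(decision = d$decision, relation = d$relation, gap = d$gap, y_adjusted = y_adj)
}

#' Pairwise cross-drug link decision
#'
#' Applies the transition/multitherapy rules to the last record of an
#' active drug thread and a new record of a different drug. The previous
#' drug's permissible gap serves as the grace period for *before*; the
#' `epsilon_cross` margin separates short co-dispensation (transition,
#' absorption, exclusion) from genuine multitherapy.
#'
#' @param x one-row tibble: last record of the active thread.
#' @param y one-row tibble: the new record (different drug class).
#' @param config an [episode_config()].
#' @return List: `decision` (one of `"transition"`, `"multitherapy_open"`,
#'   `"absorb"`, `"absorb_takeover"`, `"exclude"`, `"new_episode"`),
#'   `mechanism` (switch mechanism where applicable), `co_dispensation_days`,
#'   `y_adjusted`.
#' @export
link_cross_drug <- function(x, y, config = episode_config()) {
  if (x$drug == y$drug) abort("link_cross_drug requires two different drug classes")
  d <- cross_link_decision(
    x$start, x$end, y$start, y$end,
    gap_for(config, x$drug), config$epsilon_cross
  )
  y_adj <- y
  if (d$shift > 0L) {
    y_adj$start <- y$start + d$shift
    y_adj$end <- y$end + d$shift
    if ("service_date" %in% names(y_adj)) y_adj$service_date <- day_as_date(y_adj$start)
  }
  list(
    decision = d$decision, mechanism = d$mechanism,
    co_dispensation_days = d$co_disp, y_adjusted = y_adj
  )
}

#' Recode short same-drug overlaps as meets
#'
#' The standalone overlap-recoding cascade: within each person-drug
#' sequence, a record overlapping the running coverage frontier by at most
#' `epsilon` days is shifted forward (start and end together; days supply
#' preserved) so the relation becomes *meets*. Shifts cascade: subsequent
#' records are compared against the shifted frontier, so a chain of early
#' refills accumulates shift. Longer overlaps are left untouched. With
#' `epsilon = 0` no recoding occurs; recoding is idempotent.
#'
#' @param disps dispensation tibble.
#' @param epsilon same-drug temporal margin in days (default 7).
#' @return The input, sorted, with `start`/`end` updated and columns
#'   `original_start` and `shift_days` appended.
#' @export
recode_overlaps <- function(disps, epsilon = 7L) {
  d <- disps %>%
    arrange(.data$person_id, .data$start, .data$drug, .data$end) %>%
    mutate(original_start = .data$start, shift_days = 0L)
  key <- paste(d$person_id, d$drug, sep = "\r")
  st <- d$start
  en <- d$end
  for (rows in split(seq_len(nrow(d)), key)) {
    fs <- st[rows[1]]
    fe <- en[rows[1]]
    for (i in rows[-1]) {
      ys <- st[i]
      ye <- en[i]
      if (ys > fs && ys < fe && ye > fe) {
        ov <- fe - ys
        if (ov <= epsilon) {
          st[i] <- ys + ov
          en[i] <- ye + ov
          d$shift_days[i] <- ov
        }
      }
      if (en[i] >= fe) {
        fs <- st[i]
        fe <- en[i]
      }
    }
  }
  d$start <- st
  d$end <- en
  if ("service_date" %in% names(d)) d$service_date <- day_as_date(d$start)
  d
}

#' Aggregate a nested same-drug pair into dose segments
#'
#' For *starts*, *finishes*, *contains*, *equals* (or inverse) relations
#' between same-drug dispensations, the pair is merged over the union of
#' the two coverage windows and the daily dose is summed over the nested
#' (shared) period; the outer dose applies alone elsewhere. Total dispensed
#' milligrams are conserved.
#'
#' @param x,y one-row dispensation tibbles (same person and drug) whose
#'   intervals share a boundary-or-containment relation.
#' @return Tibble of dose segments (`start`, `end`, `drug`, `dose`).
#' @export
aggregate_nested <- function(x, y) {
  lab <- allen_classify(x$start, x$end, y$start, y$end)$label
  if (!lab %in% c(
    "starts", "started_by", "finishes", "finished_by",
    "contains", "during", "equals"
  )) {
    abort(paste0("aggregate_nested requires a nested relation, got '", lab, "'"))
  }
  dose_sweep(
    tibble(
      start = c(x$start, y$start), end = c(x$end, y$end),
      drug = c(x$drug, y$drug), dose = c(x$daily_dose, y$daily_dose)
    )
  )
}

# Piecewise-constant dose profile of a set of records of one drug (or any
# set): elementary segments between breakpoints, dose = sum of covering
# records, zero-coverage segments dropped, adjacent equal-dose runs merged.
dose_sweep <- function(recs) {
  if (nrow(recs) == 0) {
    return(tibble(start = integer(), end = integer(), drug = character(), dose = double()))
  }
  out <- list()
  for (dg in unique(recs$drug)) {
    r <- recs[recs$drug == dg, ]
    bp <- sort(unique(c(r$start, r$end)))
    if (length(bp) < 2) next
    s <- bp[-length(bp)]
    e <- bp[-1]
    dose <- vapply(seq_along(s), function(k) {
      sum(r$dose[r$start <= s[k] & r$end >= e[k]])
    }, numeric(1))
    keep <- dose > 0
    s <- s[keep]
    e <- e[keep]
    dose <- dose[keep]
    if (!length(s)) next
    # merge adjacent segments with identical dose
    run <- cumsum(c(TRUE, !(s[-1] == e[-length(e)] & dose[-1] == dose[-length(dose)])))
    out[[length(out) + 1L]] <- tibble(
      start = as.integer(tapply(s, run, min)),
      end = as.integer(tapply(e, run, max)),
      drug = dg,
      dose = as.numeric(tapply(dose, run, first))
    )
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), drug = character(), dose = double()))
  }
  bind_rows(out) %>% arrange(.data$start, .data$drug)
}

# ---- the per-person sweep --------------------------------------------------

build_person <- function(d, cfg) {
  n <- nrow(d)
  st <- d$start
  en <- d$end
  drug <- d$drug
  dd <- d$daily_dose
  assigned <- drug
  excluded <- rep(FALSE, n)
  epno <- rep(NA_integer_, n)
  shift <- rep(0L, n)
  flag_add <- rep(NA_character_, n)
  switches <- list()
  threads <- list() # per drug: f_start, f_end (frontier), cov_end, f_rid, rids
  cur_ep <- 0L

  open_thread <- function(i) {
    threads[[drug[i]]] <<- list(
      f_start = st[i], f_end = en[i], cov_end = en[i], f_rid = i, rids = i
    )
  }
  refresh_thread <- function(dg) {
    t <- threads[[dg]]
    keep <- t$rids[!excluded[t$rids]]
    if (!length(keep)) {
      threads[[dg]] <<- NULL
      return(invisible(NULL))
    }
    f <- keep[which.max(en[keep])]
    threads[[dg]] <<- list(
      f_start = st[f], f_end = en[f], cov_end = max(en[keep]), f_rid = f, rids = keep
    )
  }

  for (i in seq_len(n)) {
    yd <- drug[i]
    ys <- st[i]
    ye <- en[i]
    if (length(threads)) {
      alive <- purrr::keep(names(threads), function(dg) {
        ys <= threads[[dg]]$cov_end + gap_for(cfg, dg)
      })
      threads <- threads[alive]
    }
    if (!length(threads)) {
      cur_ep <- cur_ep + 1L
      epno[i] <- cur_ep
      open_thread(i)
      next
    }
    epno[i] <- cur_ep
    if (yd %in% names(threads)) {
      t <- threads[[yd]]
      dec <- same_link_decision(
        t$f_start, t$f_end, ys, ye,
        gap_for(cfg, yd), cfg$epsilon_same
      )
      # discontinue cannot occur here: the aliveness filter already enforced
      # ys <= cov_end + gap, and the frontier end equals cov_end
      if (dec$shift > 0L) {
        st[i] <- ys + dec$shift
        en[i] <- ye + dec$shift
        shift[i] <- dec$shift
        flag_add[i] <- "same_drug_overlap_recoded"
      } else if (dec$relation == "overlaps") {
        flag_add[i] <- "long_same_drug_overlap_retained"
      }
      t$rids <- c(t$rids, i)
      if (en[i] >= t$cov_end) {
        t$cov_end <- en[i]
        t$f_start <- st[i]
        t$f_end <- en[i]
        t$f_rid <- i
      }
      threads[[yd]] <- t
    } else {
      # cross-drug: compare against the alive thread with the latest coverage
      cov_ends <- vapply(threads, function(t) t$cov_end, numeric(1))
      t0d <- names(threads)[which.max(cov_ends)]
      t0 <- threads[[t0d]]
      dec <- cross_link_decision(
        t0$f_start, t0$f_end, ys, ye,
        gap_for(cfg, t0d), cfg$epsilon_cross
      )
      if (dec$decision == "transition") {
        if (dec$shift > 0L) {
          st[i] <- ys + dec$shift
          en[i] <- ye + dec$shift
          shift[i] <- dec$shift
          flag_add[i] <- "cross_drug_overlap_recoded"
        }
        switches[[length(switches) + 1L]] <- tibble(
          episode_no = cur_ep, day = st[i], from_drug = t0d, to_drug = yd,
          mechanism = dec$mechanism
        )
        threads[[t0d]] <- NULL
        open_thread(i)
      } else if (dec$decision == "multitherapy_open") {
        open_thread(i)
      } else if (dec$decision == "absorb") {
        assigned[i] <- t0d
        flag_add[i] <- "absorbed_nested_co_dispensation"
        t0$rids <- c(t0$rids, i)
        if (en[i] >= t0$cov_end) {
          t0$cov_end <- en[i]
          t0$f_start <- st[i]
          t0$f_end <- en[i]
          t0$f_rid <- i
        }
        threads[[t0d]] <- t0
      } else if (dec$decision == "absorb_takeover") {
        frid <- t0$f_rid
        assigned[frid] <- yd
        flag_add[frid] <- "absorbed_nested_co_dispensation"
        t0$rids <- setdiff(t0$rids, frid)
        had_history <- length(t0$rids) > 0L
        if (had_history) {
          threads[[t0d]] <- t0
          refresh_thread(t0d)
          switches[[length(switches) + 1L]] <- tibble(
            episode_no = cur_ep, day = ys, from_drug = t0d, to_drug = yd,
            mechanism = dec$mechanism
          )
        } else {
          threads[[t0d]] <- NULL
        }
        threads[[yd]] <- list(
          f_start = ys, f_end = ye, cov_end = ye, f_rid = i, rids = c(frid, i)
        )
      } else if (dec$decision == "exclude") {
        frid <- t0$f_rid
        excluded[i] <- TRUE
        excluded[frid] <- TRUE
        flag_add[i] <- "excluded_equals_co_dispensation"
        flag_add[frid] <- "excluded_equals_co_dispensation"
        refresh_thread(t0d)
      } else { # new_episode (cannot occur: aliveness filter) — defensive
        cur_ep <- cur_ep + 1L
        epno[i] <- cur_ep
        threads <- list()
        open_thread(i)
      }
    }
  }

  sw <- if (length(switches)) bind_rows(switches) else {
    tibble(
      episode_no = integer(), day = integer(), from_drug = character(),
      to_drug = character(), mechanism = character()
    )
  }

  # assemble episodes from retained records, dropping emptied episode numbers
  eps <- list()
  recs_out <- list()
  new_no <- 0L
  for (ep in seq_len(cur_ep)) {
    R <- which(epno == ep & !excluded)
    if (!length(R)) next
    new_no <- new_no + 1L
    ord <- R[order(st[R], en[R])]
    ep_start <- min(st[R])
    ep_end <- max(en[R])
    dseq <- unique(assigned[ord])
    co <- co_disp_sweep(assigned[R], st[R], en[R])
    nsw <- sum(sw$episode_no == ep)
    ndrug <- length(dseq)
    has_multi <- co$max_days > cfg$epsilon_cross
    has_switch <- nsw >= 1L
    type <- if (ndrug == 1L) {
      "monotherapy"
    } else if (has_switch && has_multi) {
      "transition_multitherapy"
    } else if (has_switch) {
      "transition"
    } else {
      "multitherapy"
    }
    closing <- R[order(en[R], st[R])][length(R)] # last medication dispensed
    segs <- dose_sweep(tibble(
      start = st[R], end = en[R], drug = assigned[R], dose = dd[R]
    ))
    eps[[new_no]] <- tibble(
      person_id = d$person_id[1],
      episode_no = new_no,
      start = ep_start, end = ep_end, type = type,
      drug_sequence = list(dseq),
      n_dispensations = length(R),
      duration_days = ep_end - ep_start,
      max_co_dispensation_days = co$max_days,
      n_switches = as.integer(nsw),
      bridged_hospital_days = 0L,
      closing_drug = assigned[closing],
      dose_segments = list(segs)
    )
    recs_out[[new_no]] <- tibble(rid = ord, episode_no = new_no)
    sw$episode_no[sw$episode_no == ep] <- -new_no # mark renumbered
  }
  sw <- sw %>%
    filter(.data$episode_no < 0L) %>%
    mutate(episode_no = -.data$episode_no, person_id = d$person_id[1])

  rec_map <- if (length(recs_out)) bind_rows(recs_out) else tibble(rid = integer(), episode_no = integer())
  records <- tibble(
    person_id = d$person_id,
    drug = drug,
    assigned_drug = assigned,
    original_start = d$start,
    start = st, end = en,
    shift_days = shift,
    excluded = excluded,
    flag = flag_add,
    daily_dose = dd,
    quantity = d$quantity,
    strength = d$strength,
    rid = seq_len(n)
  ) %>%
    left_join(rec_map, by = "rid") %>%
    select(-"rid")

  list(
    episodes = if (length(eps)) bind_rows(eps) else NULL,
    records = records,
    switches = sw
  )
}

# maximal segments where >= 2 distinct (assigned) drugs are covered
co_disp_sweep <- function(drugs, starts, ends) {
  udrugs <- unique(drugs)
  if (length(udrugs) < 2L) {
    return(list(max_days = 0L, total_days = 0L, segments = NULL))
  }
  bp <- sort(unique(c(starts, ends)))
  s <- bp[-length(bp)]
  e <- bp[-1]
  ndrug <- vapply(seq_along(s), function(k) {
    length(unique(drugs[starts <= s[k] & ends >= e[k]]))
  }, integer(1))
  multi <- ndrug >= 2L
  if (!any(multi)) {
    return(list(max_days = 0L, total_days = 0L, segments = NULL))
  }
  # merge contiguous multi segments
  run <- cumsum(c(TRUE, !(multi[-1] & multi[-length(multi)] & s[-1] == e[-length(e)])))
  seg <- tibble(start = s, end = e, multi = multi, run = run) %>%
    filter(.data$multi) %>%
    group_by(.data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  list(
    max_days = as.integer(max(seg$end - seg$start)),
    total_days = as.integer(sum(seg$end - seg$start)),
    segments = seg
  )
}

#' Build OAT treatment episodes
#'
#' The package's core operation: maps the state-machine sweep (see
#' [episode_construction]) over persons and returns one row per episode.
#' Episode typing: `monotherapy` when a single drug class is used;
#' otherwise `transition` when at least one switch event occurred and no
#' co-dispensation exceeded `epsilon_cross`, `multitherapy` when the
#' converse holds, and `transition_multitherapy` when both occurred.
#' Right-censoring of the final record uses the permissible gap of the last
#' drug dispensed in the episode.
#'
#' @param disps a cleaned dispensation tibble (see [clean_dispensations()];
#'   columns `person_id`, `drug`, `start`, `end`, `days_supply`,
#'   `quantity`, `strength`, `daily_dose`).
#' @param config an [episode_config()].
#' @param stays optional hospitalization tibble (`person_id`, `admit`,
#'   `discharge`); when supplied and `config$bridge_hospitalizations` is
#'   `TRUE`, episodes are bridged across stays via [bridge_episodes()].
#' @return A tibble of class `oat_episodes`, one row per episode, sorted by
#'   (person, start), with list-columns `drug_sequence` and
#'   `dose_segments`. Attributes: `switches` (switch-event tibble),
#'   `dispensations` (record-level assignment: shifted interval, assigned
#'   drug, episode id, exclusion flag), `config`.
#' @examples
#' d <- dispensations("p1", "methadone", start = c(0, 7, 18), days_supply = 7)
#' build_episodes(d)
#' @export
build_episodes <- function(disps, config = episode_config(), stays = NULL) {
  stopifnot(all(c(
    "person_id", "drug", "start", "end", "quantity", "strength", "daily_dose"
  ) %in% names(disps)))
  unknown <- setdiff(unique(disps$drug), names(config$permissible_gaps))
  if (length(unknown)) {
    abort(paste(
      "no permissible gap configured for drug class(es):",
      paste(unknown, collapse = ", ")
    ))
  }
  d <- disps %>% arrange(.data$person_id, .data$start, .data$drug, .data$end)
  parts <- split(seq_len(nrow(d)), d$person_id)
  built <- purrr::map(parts, function(ix) build_person(d[ix, , drop = FALSE], config))
  episodes <- purrr::compact(purrr::map(built, "episodes"))
  episodes <- if (length(episodes)) bind_rows(episodes) else empty_episode_tbl()
  switches <- bind_rows(purrr::map(built, "switches"))
  records <- bind_rows(purrr::map(built, "records"))
  episodes <- episodes %>%
    mutate(episode_id = paste0(.data$person_id, "-", .data$episode_no)) %>%
    select(
      "person_id", "episode_id", "start", "end", "type", "drug_sequence",
      "n_dispensations", "duration_days", "max_co_dispensation_days",
      "n_switches", "bridged_hospital_days", "closing_drug", "dose_segments"
    ) %>%
    arrange(.data$person_id, .data$start)
  if (nrow(records)) {
    records <- records %>%
      mutate(episode_id = if_else(
        is.na(.data$episode_no), NA_character_,
        paste0(.data$person_id, "-", .data$episode_no)
      )) %>%
      select(-"episode_no")
  }
  if (nrow(switches)) {
    switches <- switches %>%
      mutate(episode_id = paste0(.data$person_id, "-", .data$episode_no)) %>%
      select("person_id", "episode_id", "day", "from_drug", "to_drug", "mechanism")
  } else {
    switches <- tibble(
      person_id = character(), episode_id = character(), day = integer(),
      from_drug = character(), to_drug = character(), mechanism = character()
    )
  }
  out <- new_oat_episodes(episodes, switches, records, config)
  if (!is.null(stays) && config$bridge_hospitalizations) {
    out <- bridge_episodes(out, stays, config)
  }
  out
}

empty_episode_tbl <- function() {
  tibble(
    person_id = character(), episode_no = integer(), start = integer(),
    end = integer(), type = character(), drug_sequence = list(),
    n_dispensations = integer(), duration_days = integer(),
    max_co_dispensation_days = integer(), n_switches = integer(),
    bridged_hospital_days = integer(), closing_drug = character(),
    dose_segments = list()
  )
}

new_oat_episodes <- function(episodes, switches, records, config) {
  structure(
    episodes,
    switches = switches,
    dispensations = records,
    config = config,
    class = c("oat_episodes", class(tibble()))
  )
}

#' Switch events of an episode set
#' @param episodes an `oat_episodes` object.
#' @return Tibble of switch events (person, episode, day, from/to drug,
#'   mechanism).
#' @export
switch_events <- function(episodes) attr(episodes, "switches")

#' Record-level episode assignment
#' @param episodes an `oat_episodes` object.
#' @return Tibble with one row per input dispensation: adjusted interval,
#'   shift, assigned drug, episode id (`NA` for excluded records).
#' @export
episode_assignments <- function(episodes) attr(episodes, "dispensations")

#' @export
print.oat_episodes <- function(x, ...) {
  cat(sprintf(
    "<oat_episodes: %d episode(s), %d person(s)>\n",
    nrow(x), dplyr::n_distinct(x$person_id)
  ))
  NextMethod()
}

#' Co-dispensation patterns across drug classes
#'
#' Detects, per person, the maximal periods during which two or more
#' drugs' coverage overlaps, labels each by the surrounding therapy —
#' `OAT1 -> (OAT1+OAT2) -> OAT1` (return to the initial therapy) or
#' `OAT1 -> (OAT1+OAT2) -> OAT2` (switch to the second therapy), `other`
#' when more than two drugs are involved or neither/both continue — and
#' summarises the durations of each labelled sequence.
#'
#' @param disps dispensation tibble.
#' @return Tibble: `sequence`, `pattern` (`return`/`switch`/`other`), `n`,
#'   `median`, `q1`, `q3` (Tukey hinges), `mean`, `sd`, `min`, `max` of
#'   co-dispensation durations (days). The per-segment detail is attached
#'   as attribute `segments`.
#' @export
co_dispensation_patterns <- function(disps) {
  empty <- tibble(
    sequence = character(), pattern = character(), n = integer(),
    median = double(), q1 = double(), q3 = double(), mean = double(),
    sd = double(), min = double(), max = double()
  )
  if (nrow(disps) == 0) return(empty)
  segs <- disps %>%
    group_by(.data$person_id) %>%
    dplyr::group_map(function(g, key) {
      person_co_disp_segments(g) %>% mutate(person_id = key$person_id[1])
    }) %>%
    bind_rows()
  if (nrow(segs) == 0) {
    attr(empty, "segments") <- segs
    return(empty)
  }
  out <- segs %>%
    group_by(.data$sequence, .data$pattern) %>%
    summarise(
      n = n(),
      median = fivenum(.data$duration)[3],
      q1 = fivenum(.data$duration)[2],
      q3 = fivenum(.data$duration)[4],
      mean = mean(.data$duration),
      sd = sd(.data$duration),
      min = min(.data$duration),
      max = max(.data$duration),
      .groups = "drop"
    ) %>%
    arrange(.data$pattern, desc(.data$n))
  attr(out, "segments") <- segs
  out
}

person_co_disp_segments <- function(g) {
  empty <- tibble(
    sequence = character(), pattern = character(),
    start = integer(), end = integer(), duration = integer()
  )
  drugs <- unique(g$drug)
  if (length(drugs) < 2L) return(empty)
  covered <- function(dg, day) {
    any(g$start[g$drug == dg] <= day & g$end[g$drug == dg] > day)
  }
  bp <- sort(unique(c(g$start, g$end)))
  s <- bp[-length(bp)]
  e <- bp[-1]
  segdrugs <- purrr::map(seq_along(s), function(k) {
    unique(g$drug[g$start <= s[k] & g$end >= e[k]])
  })
  ncov <- lengths(segdrugs)
  multi <- ncov >= 2L
  if (!any(multi)) return(empty)
  run <- cumsum(c(TRUE, !(multi[-1] & multi[-length(multi)] & s[-1] == e[-length(e)])))
  res <- list()
  for (r in unique(run[multi])) {
    k <- which(run == r & multi)
    seg_s <- min(s[k])
    seg_e <- max(e[k])
    dset <- unique(unlist(segdrugs[k]))
    if (length(dset) != 2L) {
      lab <- "other"
      seq_lab <- paste0("other(", paste(sort(dset), collapse = "+"), ")")
    } else {
      before_set <- dset[vapply(dset, covered, logical(1), day = seg_s - 1L)]
      after_set <- dset[vapply(dset, covered, logical(1), day = seg_e)]
      if (length(before_set) == 1L && length(after_set) == 1L) {
        a <- before_set
        b <- setdiff(dset, a)
        if (after_set == a) {
          lab <- "return"
          seq_lab <- sprintf("%s -> (%s+%s) -> %s", a, a, b, a)
        } else {
          lab <- "switch"
          seq_lab <- sprintf("%s -> (%s+%s) -> %s", a, a, b, after_set)
        }
      } else {
        lab <- "other"
        seq_lab <- paste0("other(", paste(sort(dset), collapse = "+"), ")")
      }
    }
    res[[length(res) + 1L]] <- tibble(
      sequence = seq_lab, pattern = lab,
      start = seg_s, end = seg_e, duration = seg_e - seg_s
    )
  }
  bind_rows(res)
}
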