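#' Bridge episodes across hospitalizations
#'
#' Community-pharmacy claims omit inpatient dispensing, so a hospital stay
#' can interrupt the record of an ongoing episode. When a stay's admission
#' falls inside an episode's span — or inside the closing drug's
#' permissible gap after the episode's coverage end — therapy is assumed to
#' continue through the stay: the discontinuation clock restarts at
#' discharge, and a dispensation of any OAT drug within the closing drug's
#' permissible gap after discharge merges the would-be-separate episodes
#' into one. A drug change across the bridge is a switch event. Stays with
#' no adjacent episode have no effect; overlapping stays are merged first.
#'
#' @param episodes an `oat_episodes` object (or compatible tibble) from
#'   [build_episodes()].
#' @param stays tibble `person_id`, `admit`, `discharge` (integer days,
#'   discharge exclusive).
#' @param config the [episode_config()] used to build the episodes.
#' @return The episodes object with merged rows where bridging applied and
#'   `bridged_hospital_days` accumulated; switch-event and record
#'   assignment attributes updated.
#' @export
bridge_episodes <- function(episodes, stays, config = episode_config()) {
  if (!config$bridge_hospitalizations || is.null(stays) || nrow(stays) == 0) {
    return(episodes)
  }
  stays <- merge_stays(as_tibble(stays))
  ep <- as_tibble(episodes) %>% arrange(.data$person_id, .data$start)
  switches <- attr(episodes, "switches")
  records <- attr(episodes, "dispensations")
  for (p in unique(stays$person_id)) {
    pst <- stays %>% filter(.data$person_id == p) %>% arrange(.data$admit)
    for (k in seq_len(nrow(pst))) {
      admit <- pst$admit[k]
      discharge <- pst$discharge[k]
      idx <- which(ep$person_id == p)
      if (length(idx) < 2) next
      pe <- ep[idx, ]
      g <- vapply(pe$closing_drug, function(dg) gap_for(config, dg), integer(1))
      j <- which(pe$start <= admit & admit < pe$end + g)
      if (!length(j)) next
      j <- max(j)
      if (j >= nrow(pe)) next
      nxt <- pe[j + 1L, ]
      if (nxt$start > discharge + g[j]) next
      a <- pe[j, ]
      cross <- a$closing_drug != nxt$drug_sequence[[1]][1]
      merged <- a
      merged$end <- max(a$end, nxt$end)
      merged$drug_sequence <- list(unique(c(a$drug_sequence[[1]], nxt$drug_sequence[[1]])))
      merged$n_dispensations <- a$n_dispensations + nxt$n_dispensations
      merged$duration_days <- merged$end - merged$start
      merged$max_co_dispensation_days <- max(
        a$max_co_dispensation_days, nxt$max_co_dispensation_days
      )
      merged$n_switches <- a$n_switches + nxt$n_switches + as.integer(cross)
      merged$bridged_hospital_days <- a$bridged_hospital_days +
        nxt$bridged_hospital_days + (discharge - admit)
      merged$closing_drug <- nxt$closing_drug
      merged$dose_segments <- list(bind_rows(a$dose_segments[[1]], nxt$dose_segments[[1]]))
      ndrug <- length(merged$drug_sequence[[1]])
      has_multi <- merged$max_co_dispensation_days > config$epsilon_cross
      has_switch <- merged$n_switches >= 1L
      merged$type <- if (ndrug == 1L) {
        "monotherapy"
      } else if (has_switch && has_multi) {
        "transition_multitherapy"
      } else if (has_switch) {
        "transition"
      } else {
        "multitherapy"
      }
      if (cross) {
        switches <- bind_rows(switches, tibble(
          person_id = p, episode_id = a$episode_id, day = nxt$start,
          from_drug = a$closing_drug, to_drug = nxt$drug_sequence[[1]][1],
          mechanism = "within_gap_before"
        ))
      }
      # remap ids of the absorbed episode, then replace the two rows
      if (!is.null(switches) && nrow(switches)) {
        switches$episode_id[switches$episode_id == nxt$episode_id] <- a$episode_id
      }
      if (!is.null(records) && nrow(records)) {
        records$episode_id[!is.na(records$episode_id) &
          records$episode_id == nxt$episode_id] <- a$episode_id
      }
      ep <- bind_rows(
        ep[-(idx[c(j, j + 1L)]), , drop = FALSE],
        merged
      ) %>% arrange(.data$person_id, .data$start)
    }
  }
  new_oat_episodes(ep, switches, records, config)
}
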