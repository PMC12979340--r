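cfg <- episode_config()

test_that("short same-drug overlaps recode to meets with a forward shift", {
  x <- dispensations("p1", "methadone", start = 0, days_supply = 10)
  y <- dispensations("p1", "methadone", start = 7, days_supply = 10)
  res <- link_same_drug(x, y, cfg)
  expect_equal(res$decision, "continue")
  expect_equal(res$relation, "meets")
  expect_equal(res$y_adjusted$start, 10L)
  expect_equal(res$y_adjusted$end, 20L)
  expect_equal(res$y_adjusted$days_supply, 10L)

  y_long <- dispensations("p1", "methadone", start = 2, days_supply = 18)
  res2 <- link_same_drug(x, y_long, cfg)
  expect_equal(res2$relation, "overlaps") # overlap 8 > 7: untouched
  expect_equal(res2$y_adjusted$start, 2L)
})

test_that("overlap-recoding shifts cascade along chains of early refills", {
  # refills 3 days early against the original schedule: each shift adds 3,
  # so the k-th record accumulates 3(k-1) days while the relation against
  # the shifted frontier remains a short overlap
  for (k in c(3L, 4L)) {
    d <- dispensations("p1", "methadone",
      start = seq(0, by = 7, length.out = k), days_supply = 10
    )
    rec <- recode_overlaps(d, epsilon = 14)
    expect_equal(rec$start - rec$original_start, 3L * (seq_len(k) - 1L))
    ann <- annotate_relations(rec)
    expect_true(all(ann$label[-1] == "meets"))
  }
  # epsilon = 0 means no recoding and zero shifts
  d <- dispensations("p1", "methadone", start = c(0, 7), days_supply = 10)
  expect_equal(recode_overlaps(d, epsilon = 0)$shift_days, c(0L, 0L))
  # idempotence
  once <- recode_overlaps(d, epsilon = 7)
  twice <- recode_overlaps(once %>% dplyr::select(-original_start, -shift_days), epsilon = 7)
  expect_equal(twice$start, once$start)
  expect_equal(twice$shift_days, c(0L, 0L))
})

test_that("nested same-drug pairs aggregate with dose summed over the shared period", {
  eq <- aggregate_nested(
    dispensations("p", "srom", start = 0, days_supply = 5, quantity = 250),
    dispensations("p", "srom", start = 0, days_supply = 5, quantity = 150)
  )
  expect_equal(as.data.frame(eq[, c("start", "end", "dose")]),
    data.frame(start = 0L, end = 5L, dose = 80))

  cont <- aggregate_nested(
    dispensations("p", "srom", start = 0, days_supply = 10, quantity = 500),
    dispensations("p", "srom", start = 2, days_supply = 3, quantity = 90)
  )
  expect_equal(as.data.frame(cont[, c("start", "end", "dose")]),
    data.frame(start = c(0L, 2L, 5L), end = c(2L, 5L, 10L), dose = c(50, 80, 50)))
  expect_equal(sum((cont$end - cont$start) * cont$dose), 500 + 90)

  st <- aggregate_nested(
    dispensations("p", "srom", start = 0, days_supply = 3, quantity = 120),
    dispensations("p", "srom", start = 0, days_supply = 8, quantity = 320)
  )
  expect_equal(as.data.frame(st[, c("start", "end", "dose")]),
    data.frame(start = c(0L, 3L), end = c(3L, 8L), dose = c(80, 40)))

  expect_error(
    aggregate_nested(
      dispensations("p", "srom", start = 0, days_supply = 3),
      dispensations("p", "srom", start = 10, days_supply = 3)
    ),
    "nested relation"
  )
})

test_that("permissible-gap boundaries are exact for every drug", {
  gaps <- cfg$permissible_gaps
  for (drug in names(gaps)) {
    g_max <- gaps[[drug]]
    for (g in 0:(g_max + 3L)) {
      d <- dispensations("p1", drug, start = c(0, 10 + g), days_supply = 10)
      n_ep <- nrow(build_episodes(d, cfg))
      expect_equal(n_ep, if (g <= g_max) 1L else 2L,
        info = sprintf("%s gap %d", drug, g)
      )
    }
  }
})

test_that("cross-drug links implement the transition/multitherapy rules", {
  # short cross-drug overlap: shifted to meets, a transition
  x <- dispensations("p1", "srom", start = 0, days_supply = 20)
  y <- dispensations("p1", "methadone", start = 14, days_supply = 16)
  res <- link_cross_drug(x, y, cfg)
  expect_equal(res$decision, "transition")
  expect_equal(res$mechanism, "short_overlap_recode")
  expect_equal(res$y_adjusted$start, 20L)
  expect_equal(res$y_adjusted$end, 36L)

  # long co-dispensation: multitherapy, intervals untouched
  x2 <- dispensations("p1", "methadone", start = 0, days_supply = 30)
  y2 <- dispensations("p1", "srom", start = 5, days_supply = 20)
  res2 <- link_cross_drug(x2, y2, cfg)
  expect_equal(res2$decision, "multitherapy_open")
  expect_equal(res2$co_dispensation_days, 20L)
  expect_equal(res2$y_adjusted$start, 5L)

  # nested short co-dispensation absorbs into the encompassing drug
  y3 <- dispensations("p1", "bup_nal", start = 10, days_supply = 5)
  res3 <- link_cross_drug(x2, y3, cfg)
  expect_equal(res3$decision, "absorb")

  # equals within the margin excludes both records
  x4 <- dispensations("p1", "methadone", start = 0, days_supply = 10)
  y4 <- dispensations("p1", "srom", start = 0, days_supply = 10)
  expect_equal(link_cross_drug(x4, y4, cfg)$decision, "exclude")
  # equals beyond the margin is multitherapy
  x5 <- dispensations("p1", "methadone", start = 0, days_supply = 20)
  y5 <- dispensations("p1", "srom", start = 0, days_supply = 20)
  expect_equal(link_cross_drug(x5, y5, cfg)$decision, "multitherapy_open")

  # before beyond the previous drug's grace opens a new episode
  y6 <- dispensations("p1", "srom", start = 40, days_supply = 7)
  expect_equal(link_cross_drug(x2, y6, cfg)$decision, "new_episode")
  # within the grace it is a transition
  y7 <- dispensations("p1", "srom", start = 33, days_supply = 7)
  expect_equal(link_cross_drug(x2, y7, cfg)$decision, "transition")
  expect_equal(link_cross_drug(x2, y7, cfg)$mechanism, "within_gap_before")
})

test_that("episode building matches the link rules on worked examples", {
  mono <- build_episodes(
    dispensations("p1", "methadone", start = c(0, 7, 18), days_supply = 7)
  )
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$type, "monotherapy")
  expect_equal(c(mono$start, mono$end, mono$duration_days), c(0L, 25L, 25L))

  trans <- build_episodes(dplyr::bind_rows(
    dispensations("p1", "methadone", start = 0, days_supply = 10),
    dispensations("p1", "bup_nal", start = 13, days_supply = 7)
  ))
  expect_equal(nrow(trans), 1L)
  expect_equal(trans$type, "transition")
  expect_equal(trans$drug_sequence[[1]], c("methadone", "bup_nal"))
  expect_equal(trans$n_switches, 1L)

  multi <- build_episodes(dplyr::bind_rows(
    dispensations("p1", "methadone", start = 0, days_supply = 40),
    dispensations("p1", "srom", start = 10, days_supply = 30)
  ))
  expect_equal(nrow(multi), 1L)
  expect_equal(multi$type, "multitherapy")
  expect_equal(multi$max_co_dispensation_days, 30L)
  expect_equal(multi$n_switches, 0L)
})

test_that("a return pattern through short co-dispensation types as transition with two switches", {
  d <- dplyr::bind_rows(
    dispensations("p1", "methadone", start = 0, days_supply = 10),
    dispensations("p1", "bup_nal", start = 10, days_supply = 7),
    dispensations("p1", "methadone", start = 17, days_supply = 10)
  )
  ep <- build_episodes(d)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$type, "transition")
  expect_equal(ep$n_switches, 2L)
  sw <- switch_events(ep)
  expect_equal(sw$from_drug, c("methadone", "bup_nal"))
  expect_equal(sw$to_drug, c("bup_nal", "methadone"))
})

test_that("excluded equals pairs are flagged and drop out of episodes", {
  d <- dplyr::bind_rows(
    dispensations("p1", "methadone", start = c(0, 10), days_supply = 10),
    dispensations("p1", "srom", start = 10, days_supply = 10)
  )
  ep <- build_episodes(d)
  rec <- episode_assignments(ep)
  expect_equal(sum(rec$excluded), 2L)
  expect_true(all(is.na(rec$episode_id[rec$excluded])))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$n_dispensations, 1L)
})

test_that("episodes are disjoint and every retained record maps to exactly one", {
  for (seed in c(101, 102)) {
    sim <- generate_cohort(sim_config(n_persons = 40), seed = seed)
    ep <- build_episodes(sim$clean_dispensations)
    rec <- episode_assignments(ep)
    expect_true(all(!rec$excluded | is.na(rec$episode_id)))
    retained <- rec[!rec$excluded, ]
    expect_false(anyNA(retained$episode_id))
    # each retained record lies inside its episode's span
    joined <- dplyr::left_join(
      retained, tibble::as_tibble(ep)[, c("episode_id", "start", "end")],
      by = "episode_id", suffix = c("", "_ep")
    )
    expect_true(all(joined$start >= joined$start_ep & joined$end <= joined$end_ep))
    # per-person episode spans never overlap
    spans <- tibble::as_tibble(ep) %>%
      dplyr::arrange(person_id, start) %>%
      dplyr::group_by(person_id) %>%
      dplyr::mutate(ok = is.na(dplyr::lag(end)) | start >= dplyr::lag(end)) %>%
      dplyr::ungroup()
    expect_true(all(spans$ok))
  }
})

test_that("dispensed milligrams are conserved through episode construction", {
  sim <- generate_cohort(sim_config(n_persons = 40), seed = 103)
  d <- sim$clean_dispensations
  ep <- build_episodes(d)
  rec <- episode_assignments(ep)
  mg_excluded <- sum(rec$quantity[rec$excluded] * rec$strength[rec$excluded])
  expect_equal(segment_mg(ep) + mg_excluded, total_mg(d), tolerance = 1e-8)
})

test_that("episode count is monotone non-increasing in the permissible gap", {
  sim <- generate_cohort(sim_config(n_persons = 40), seed = 104)
  d <- sim$clean_dispensations
  counts <- vapply(c(0L, 2L, 5L, 10L, 20L), function(g) {
    cfg_g <- episode_config(permissible_gaps = c(
      methadone = g, bup_nal = g, srom = g, ioat = g
    ))
    nrow(build_episodes(d, cfg_g))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("raising the cross-drug margin never turns a transition into multitherapy", {
  d <- dplyr::bind_rows(
    dispensations("p1", "srom", start = 0, days_supply = 20),
    dispensations("p1", "methadone", start = 12, days_supply = 20)
  )
  t14 <- build_episodes(d, episode_config(epsilon_cross = 14L))$type
  t20 <- build_episodes(d, episode_config(epsilon_cross = 20L))$type
  expect_equal(t14, "transition")
  expect_equal(t20, "transition")
})

test_that("co-dispensation patterns label return and switch sequences", {
  d <- dplyr::bind_rows(
    dispensations("q1", "ioat", start = 0, days_supply = 30),
    dispensations("q1", "srom", start = 10, days_supply = 4),
    dispensations("q2", "srom", start = 0, days_supply = 20),
    dispensations("q2", "methadone", start = 15, days_supply = 25)
  )
  pat <- co_dispensation_patterns(d)
  ret <- pat[pat$pattern == "return", ]
  expect_equal(ret$sequence, "ioat -> (ioat+srom) -> ioat")
  expect_equal(ret$median, 4)
  sw <- pat[pat$pattern == "switch", ]
  expect_equal(sw$sequence, "srom -> (srom+methadone) -> methadone")
  expect_equal(sw$median, 5)

  none <- co_dispensation_patterns(
    dispensations("q3", "methadone", start = c(0, 10), days_supply = 7)
  )
  expect_equal(nrow(none), 0L)
})
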