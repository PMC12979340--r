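test_that("split doses are consolidated with quantity conserved", {
  d <- dispensations("p1", "methadone",
    start = c(0, 0), days_supply = 1, quantity = c(50, 50)
  )
  out <- consolidate_split_doses(d)
  expect_equal(nrow(out$dispensations), 1L)
  expect_equal(out$dispensations$quantity, 100)

  d3 <- dispensations("p1", "methadone",
    start = c(5, 5, 5), days_supply = 1, quantity = c(10, 20, 30)
  )
  out3 <- consolidate_split_doses(d3)
  expect_equal(out3$dispensations$quantity, 60)
  expect_equal(total_mg(out3$dispensations), total_mg(d3))

  single <- dispensations("p1", "methadone", start = 0, days_supply = 7)
  expect_equal(
    as.data.frame(consolidate_split_doses(single)$dispensations %>% dplyr::select(-flags)),
    as.data.frame(single %>% dplyr::select(-flags))
  )
})

test_that("discordant strengths block merging and are flagged", {
  d <- dispensations("p1", "methadone",
    start = c(0, 0), days_supply = 1, quantity = 50, strength = c(1, 10)
  )
  out <- consolidate_split_doses(d)
  expect_equal(nrow(out$dispensations), 2L)
  expect_true(all(grepl("strength_conflict", out$dispensations$flags)))
  expect_equal(out$audit$rule, "split_dose_strength_conflict")
})

test_that("a QPD outlier is repaired against the adjacency-window median", {
  # four steady records at QPD 10 around one keyed tenfold: recalculated
  # days supply (70) is implausible, so the quantity is reset to 10/day
  d <- dispensations("p1", "methadone",
    start = c(0, 7, 14, 21, 28), days_supply = 7,
    quantity = c(70, 70, 700, 70, 70)
  )
  out <- repair_qpd_outliers(d)
  fixed <- out$dispensations
  expect_equal(fixed$quantity[3], 70)
  expect_equal(fixed$days_supply[3], 7L)
  expect_match(fixed$flags[3], "qpd_quantity_adjusted")
  expect_equal(nrow(out$audit), 1L)

  # when recalculating days supply lands in the plausible range it is preferred
  d2 <- dispensations("p1", "methadone",
    start = c(0, 7, 14, 40, 47), days_supply = c(7, 7, 7, 7, 7),
    quantity = c(70, 70, 210, 70, 70)
  )
  out2 <- repair_qpd_outliers(d2)
  expect_equal(out2$dispensations$days_supply[3], 21L)
  expect_equal(out2$dispensations$quantity[3], 210)
})

test_that("rows matching their neighbours, or lacking them, are untouched", {
  steady <- dispensations("p1", "methadone",
    start = seq(0, 28, by = 7), days_supply = 7, quantity = 70
  )
  expect_equal(nrow(repair_qpd_outliers(steady)$audit), 0L)

  lone <- dispensations("p1", "methadone", start = 0, days_supply = 7, quantity = 9999)
  out <- repair_qpd_outliers(lone)
  expect_equal(out$dispensations$quantity, 9999)
  expect_equal(nrow(out$audit), 0L)
})

test_that("days supply is capped at the time to the next dispensation", {
  d <- dispensations("p1", "methadone", start = c(0, 10), days_supply = c(30, 10))
  out <- cap_days_supply(d)
  expect_equal(out$dispensations$days_supply, c(10L, 10L))
  expect_equal(out$dispensations$quantity, d$quantity) # quantity unchanged
  expect_equal(out$dispensations$daily_dose[1], d$quantity[1] / 10)

  ok <- dispensations("p1", "methadone", start = c(0, 10), days_supply = c(5, 10))
  expect_equal(cap_days_supply(ok)$dispensations$days_supply, c(5L, 10L))

  # every non-terminal overshoot in a chain is capped, pairwise left-to-right
  chain <- dispensations("p1", "methadone", start = c(0, 10, 25), days_supply = c(30, 30, 30))
  capped <- cap_days_supply(chain)$dispensations
  expect_equal(capped$days_supply, c(10L, 15L, 30L))
})

test_that("capping never increases supply and duplicates are an integrity error", {
  d <- dispensations("p1", "methadone", start = c(0, 3, 9, 30), days_supply = c(10, 2, 40, 7))
  out <- cap_days_supply(d)$dispensations
  expect_true(all(out$days_supply <= d$days_supply))
  dup <- dispensations("p1", "methadone", start = c(0, 0), days_supply = 7)
  expect_error(cap_days_supply(dup), "integrity")
})

test_that("the full pipeline is idempotent and flags nothing on clean tables", {
  cfg <- sim_config(
    n_persons = 40, mixtures = continuity_mixture(),
    split_dose_rate = 0.02, supply_overrun_rate = 0.02, qpd_outlier_rate = 0.01,
    transition_rate = 0, multitherapy_rate = 0
  )
  for (seed in c(11, 12, 13)) {
    sim <- generate_cohort(cfg, seed = seed)
    once <- clean_dispensations(sim$dispensations)
    twice <- clean_dispensations(once$dispensations)
    expect_equal(twice$report$n_flagged, 0L)
    expect_equal(
      as.data.frame(dplyr::select(twice$dispensations, -flags)),
      as.data.frame(dplyr::select(once$dispensations, -flags))
    )
  }
  clean0 <- generate_cohort(
    sim_config(
      n_persons = 30, mixtures = continuity_mixture(),
      transition_rate = 0, multitherapy_rate = 0
    ),
    seed = 21
  )
  expect_equal(clean_dispensations(clean0$dispensations)$report$n_flagged, 0L)
})

test_that("injected split-dose and supply-overrun errors are all recovered", {
  cfg <- sim_config(
    n_persons = 50, mixtures = continuity_mixture(),
    split_dose_rate = 0.03, supply_overrun_rate = 0.03,
    transition_rate = 0, multitherapy_rate = 0
  )
  sim <- generate_cohort(cfg, seed = 31)
  res <- clean_dispensations(sim$dispensations)
  inj <- sim$injected_errors
  splits <- inj[inj$error == "split_dose", ]
  caught_splits <- res$audit[res$audit$rule == "consolidate_split_dose", ]
  expect_equal(
    nrow(dplyr::semi_join(splits, caught_splits, by = c("person_id", "drug", "start"))),
    nrow(splits)
  )
  overruns <- inj[inj$error == "supply_overrun", ]
  caught_over <- res$audit[res$audit$rule %in% c("cap_days_supply", "qpd_repair"), ]
  expect_equal(
    nrow(dplyr::semi_join(overruns, caught_over, by = c("person_id", "drug", "start"))),
    nrow(overruns)
  )
  expect_lte(res$report$n_corrected, res$report$n_flagged)
  expect_lte(res$report$n_flagged, res$report$n_input)
})

test_that("consolidation conserves total quantity per person-drug-day", {
  cfg <- sim_config(
    n_persons = 30, mixtures = continuity_mixture(), split_dose_rate = 0.05,
    transition_rate = 0, multitherapy_rate = 0
  )
  sim <- generate_cohort(cfg, seed = 41)
  before <- sim$dispensations %>%
    dplyr::group_by(person_id, drug, start) %>%
    dplyr::summarise(q = sum(quantity), .groups = "drop")
  after <- consolidate_split_doses(sim$dispensations)$dispensations %>%
    dplyr::group_by(person_id, drug, start) %>%
    dplyr::summarise(q = sum(quantity), .groups = "drop")
  expect_equal(as.data.frame(after), as.data.frame(before))
})
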