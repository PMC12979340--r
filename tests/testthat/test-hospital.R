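cfg <- episode_config()

two_part_person <- function() {
  dplyr::bind_rows(
    dispensations("p1", "methadone", start = c(0, 7, 14), days_supply = 7),
    dispensations("p1", "methadone", start = 43, days_supply = 7)
  )
}

test_that("a stay inside the grace window bridges two episodes into one", {
  # coverage ends day 21 (G = 5); admitted day 23, discharged day 40,
  # refill day 43 (3 days after discharge, within the gap): one episode
  ep <- build_episodes(two_part_person())
  expect_equal(nrow(ep), 2L)
  stays <- tibble::tibble(person_id = "p1", admit = 23L, discharge = 40L)
  bridged <- bridge_episodes(ep, stays, cfg)
  expect_equal(nrow(bridged), 1L)
  expect_equal(bridged$start, 0L)
  expect_equal(bridged$end, 50L)
  expect_equal(bridged$bridged_hospital_days, 17L)
  expect_equal(bridged$type, "monotherapy")
})

test_that("admission after the grace window expires does not bridge", {
  ep <- build_episodes(two_part_person())
  stays <- tibble::tibble(person_id = "p1", admit = 30L, discharge = 40L)
  bridged <- bridge_episodes(ep, stays, cfg)
  expect_equal(nrow(bridged), 2L)
  expect_equal(bridged$bridged_hospital_days, c(0L, 0L))
})

test_that("a refill too long after discharge does not bridge", {
  d <- dplyr::bind_rows(
    dispensations("p1", "methadone", start = c(0, 7, 14), days_supply = 7),
    dispensations("p1", "methadone", start = 50, days_supply = 7)
  )
  ep <- build_episodes(d)
  stays <- tibble::tibble(person_id = "p1", admit = 23L, discharge = 40L)
  expect_equal(nrow(bridge_episodes(ep, stays, cfg)), 2L)
})

test_that("no stays and disabled bridging are both the identity", {
  ep <- build_episodes(two_part_person())
  none <- tibble::tibble(person_id = character(), admit = integer(), discharge = integer())
  expect_equal(nrow(bridge_episodes(ep, none, cfg)), 2L)
  off <- episode_config(bridge_hospitalizations = FALSE)
  stays <- tibble::tibble(person_id = "p1", admit = 23L, discharge = 40L)
  expect_equal(nrow(bridge_episodes(ep, stays, off)), 2L)
})

test_that("a drug change across the bridge becomes a switch and types as transition", {
  d <- dplyr::bind_rows(
    dispensations("p1", "methadone", start = c(0, 7, 14), days_supply = 7),
    dispensations("p1", "srom", start = 43, days_supply = 7)
  )
  ep <- build_episodes(d)
  expect_equal(nrow(ep), 2L)
  stays <- tibble::tibble(person_id = "p1", admit = 23L, discharge = 40L)
  bridged <- bridge_episodes(ep, stays, cfg)
  expect_equal(nrow(bridged), 1L)
  expect_equal(bridged$type, "transition")
  expect_equal(bridged$n_switches, 1L)
  sw <- switch_events(bridged)
  expect_equal(sw$from_drug, "methadone")
  expect_equal(sw$to_drug, "srom")
})

test_that("bridging through build_episodes(stays=) matches calling bridge_episodes", {
  d <- two_part_person()
  stays <- tibble::tibble(person_id = "p1", admit = 23L, discharge = 40L)
  a <- build_episodes(d, cfg, stays = stays)
  b <- bridge_episodes(build_episodes(d, cfg), stays, cfg)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("bridging never splits episodes on simulated cohorts", {
  sim <- generate_cohort(sim_config(n_persons = 40, hospitalization_rate = 0.4), seed = 17)
  ep <- build_episodes(sim$clean_dispensations)
  bridged <- bridge_episodes(ep, sim$stays, episode_config())
  expect_lte(nrow(bridged), nrow(ep))
  expect_gte(nrow(bridged), nrow(ep) - nrow(sim$stays))
})
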