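arena <- mcsf_default()

test_that("zone descriptors follow their definitions by hand arithmetic", {
  v <- make_visits(c("dcr", "dcr"), c(10, 100), c(25, 130))
  d <- compute_zone_descriptors(v, arena)
  dcr <- d[d$zone_id == "dcr", ]
  expect_equal(dcr$lat, 10)
  expect_equal(dcr$frq, 2L)
  expect_equal(dcr$dur, 45)
  expect_equal(dcr$durfrq, 22.5)
  # never-visited zone: LAT missing, FRQ 0, DUR 0
  ctr <- d[d$zone_id == "center", ]
  expect_true(is.na(ctr$lat))
  expect_equal(ctr$frq, 0L)
  expect_equal(ctr$dur, 0)
  expect_true(is.na(ctr$durfrq))
  # a visit spanning the whole session
  v2 <- make_visits("center", 0, 1800)
  d2 <- compute_zone_descriptors(v2, arena)
  expect_equal(d2$dur[d2$zone_id == "center"], 1800)
  expect_equal(d2$durfrq[d2$zone_id == "center"], 1800)
  # mixed rats rejected
  v3 <- rbind(make_visits("dcr", 0, 10), make_visits("dcr", 0, 10, rat_id = "r2"))
  expect_error(compute_zone_descriptors(v3, arena), "one rat-trial")
})

test_that("aggregates sum members, with LAT as the minimum member latency", {
  v <- make_visits(c("corr_a", "corr_b", "corr_c", "corr_a", "dcr"),
                   c(5, 20, 40, 60, 80), c(10, 30, 50, 70, 90))
  d <- compute_aggregates(compute_zone_descriptors(v, arena), arena)
  tc <- d[d$zone_id == "total_corr", ]
  expect_equal(tc$frq, 4L)
  expect_equal(tc$lat, 5)
  expect_equal(tc$dur, 5 + 10 + 10 + 10)
  ar <- d[d$zone_id == "arena", ]
  expect_equal(ar$frq, 5L)       # TOTAL ACT = visits to all zones
  # velocity of aggregate = summed distance over summed duration
  expect_equal(tc$vel, sum(v$distance[v$zone_id != "dcr"]) / tc$dur)
})

test_that("percent measures normalize as defined and sum to 100", {
  v <- make_visits(rep(c("dcr", "center"), c(5, 45)),
                   seq(0, by = 30, length.out = 50),
                   seq(0, by = 30, length.out = 50) + 20)
  d <- compute_relative_measures(
    compute_aggregates(compute_zone_descriptors(v, arena), arena))
  expect_equal(d$pct_frq[d$zone_id == "dcr"], 100 * 5 / 50)
  zone_rows <- !d$zone_id %in% c("total_corr", "arena")
  expect_equal(sum(d$pct_frq[zone_rows]), 100)
  expect_equal(sum(d$pct_dur[zone_rows]), 100)  # total_visits_time denominator
  # trial-time denominator: DUR center 180 of an 1800 s session -> 10 %
  v2 <- make_visits(c("center", "dcr"), c(0, 200), c(180, 1700))
  d2 <- compute_relative_measures(
    compute_aggregates(compute_zone_descriptors(v2, arena), arena),
    denominator_mode = "trial_time")
  expect_equal(d2$pct_dur[d2$zone_id == "center"], 10)
})

test_that("indexes reproduce hand arithmetic, symmetry zeros and NA rules", {
  desc <- function(frq_dcr = 0, frq_corr_a = 0, lat_slope = NA,
                   lat_bridge = NA, dur_bridge = 0, dur_dcr = 0,
                   frq_bridge = 0) {
    data.frame(
      zone_id = c("dcr", "corr_a", "slope", "bridge"),
      lat = c(NA, NA, lat_slope, lat_bridge),
      frq = c(frq_dcr, frq_corr_a, 1, frq_bridge),
      dur = c(dur_dcr, 0, 0, dur_bridge),
      stringsAsFactors = FALSE)
  }
  # symmetry zero
  i1 <- compute_indexes(desc(frq_dcr = 7, frq_corr_a = 7))
  expect_equal(unname(i1["idx_shelter_corridor"]), 0)
  # hand arithmetic
  i2 <- compute_indexes(desc(frq_dcr = 2, frq_corr_a = 6))
  expect_equal(unname(i2["idx_shelter_corridor"]), -0.5)
  i3 <- compute_indexes(desc(lat_slope = 100, lat_bridge = 150))
  expect_equal(unname(i3["idx_slope_bridge"]), -0.5)
  i4 <- compute_indexes(desc(lat_slope = 120, lat_bridge = 120))
  expect_equal(unname(i4["idx_slope_bridge"]), 0)
  i5 <- compute_indexes(desc(dur_bridge = 30, dur_dcr = 90))
  expect_equal(unname(i5["idx_risk_shelter_dur"]), -0.5)
  i6 <- compute_indexes(desc(frq_bridge = 9, frq_dcr = 3))
  expect_equal(unname(i6["idx_risk_shelter_frq"]), 0.5)
  # zero denominators and missing inputs -> missing, never 0 or +/-1
  i0 <- compute_indexes(desc())
  expect_true(is.na(i0["idx_shelter_corridor"]))
  expect_true(is.na(i0["idx_slope_bridge"]))
  expect_true(is.na(i0["idx_risk_shelter_dur"]))
  expect_true(is.na(i0["idx_risk_shelter_frq"]))
  # ratio indexes bounded in [-1, 1] over random descriptors
  set.seed(9)
  for (k in 1:50) {
    ii <- compute_indexes(desc(frq_dcr = rpois(1, 5), frq_corr_a = rpois(1, 5),
                               lat_slope = runif(1, 1, 1800),
                               lat_bridge = runif(1, 1, 1800),
                               dur_bridge = runif(1, 0, 900),
                               dur_dcr = runif(1, 0, 900),
                               frq_bridge = rpois(1, 5)))
    ratio <- ii[c("idx_shelter_corridor", "idx_risk_shelter_dur",
                  "idx_risk_shelter_frq")]
    expect_true(all(is.na(ratio) | (ratio >= -1 & ratio <= 1)))
  }
})

test_that("missing rules are mode-pure and idempotent", {
  v <- rbind(make_visits(c("center", "corr_a"), c(0, 60), c(50, 90)),
             make_visits(c("center", "dcr"), c(0, 60), c(50, 90),
                         rat_id = "r2"))
  tab <- parameter_table(v, arena)
  wt <- apply_missing_rules(tab, "within_trial", 1800)
  # r1 never visited the DCR
  expect_true(is.na(wt$LAT_dcr[wt$rat_id == "r1"]))
  expect_true(is.na(wt$FRQ_dcr[wt$rat_id == "r1"]))
  expect_true(is.na(wt$DUR_dcr[wt$rat_id == "r1"]))
  bt <- apply_missing_rules(tab, "between_trial", 1800)
  expect_equal(bt$LAT_dcr[bt$rat_id == "r1"], 1800)
  expect_equal(bt$FRQ_dcr[bt$rat_id == "r1"], 0)
  expect_equal(bt$DUR_dcr[bt$rat_id == "r1"], 0)
  # visited zones unchanged in both modes
  expect_equal(wt$LAT_center, tab$LAT_center)
  expect_equal(bt$LAT_center, tab$LAT_center)
  # within_trial never writes the imputation value
  expect_false(any(wt == 1800 & is.na(tab), na.rm = TRUE))
  # idempotent
  expect_equal(apply_missing_rules(wt, "within_trial", 1800), wt)
  expect_equal(apply_missing_rules(bt, "between_trial", 1800), bt)
})

test_that("occurrence counts rats with positive values per group", {
  tab <- random_table(n = 12, params = "FRQ_bridge", seed = 4)
  tab$FRQ_bridge <- c(rep(1, 9), rep(0, 3), rep(1, 6), rep(0, 6))
  occ <- compute_occurrence(tab, "FRQ_bridge")
  expect_equal(occ$occurrence, c(9, 6))
  expect_equal(occ$n, c(12, 12))
  tab$FRQ_bridge <- 0
  expect_equal(compute_occurrence(tab, "FRQ_bridge")$occurrence, c(0, 0))
  expect_error(compute_occurrence(tab, "nope"), "unknown parameter")
})

test_that("parameter table DUR(arena) never exceeds the session duration", {
  cfg <- simulation_config(n_per_group = 3, trials = 1, seed = 21,
                           include = "mcsf")
  coh <- simulate_cohort(cfg)
  tab <- parameter_table(coh$visits, arena)
  expect_true(all(tab$DUR_arena <= 1800 + 1e-6))
  expect_equal(tab$TOTAL_ACT, tab$FRQ_arena)
})
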