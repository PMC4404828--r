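arena <- mcsf_default()

test_that("simulated sessions are deterministic given a seed", {
  prof <- group_profile()
  s1 <- simulate_mcsf_session(prof, arena, 600, seed = 42, emit_track = TRUE)
  s2 <- simulate_mcsf_session(prof, arena, 600, seed = 42, emit_track = TRUE)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$track, s2$track)
  s3 <- simulate_mcsf_session(prof, arena, 600, seed = 43)
  expect_false(identical(s1$visits$t_exit, s3$visits$t_exit))
})

test_that("the zone walk respects the adjacency graph and starts in center", {
  prof <- group_profile()
  adj_ok <- function(v) {
    from <- v$zone_id[-nrow(v)]; to <- v$zone_id[-1]
    all(vapply(seq_along(from), function(i)
      to[i] %in% zone_neighbors(arena, from[i]), TRUE))
  }
  for (sd in 1:5) {
    v <- simulate_mcsf_session(prof, arena, 900, seed = sd)$visits
    expect_equal(v$zone_id[1], "center")
    expect_true(adj_ok(v))
    # visits tile the session without overlap
    expect_equal(v$t_enter[-1], v$t_exit[-nrow(v)])
    expect_equal(v$t_exit[nrow(v)], 900)
  }
  # degenerate profile: only transition kept returns to corr_a's neighbours
  prof2 <- group_profile(transition = list(center = c(corr_a = 1),
                                           corr_a = c(center = 1)))
  v2 <- simulate_mcsf_session(prof2, arena, 300, seed = 9)$visits
  expect_true(all(v2$zone_id %in% c("center", "corr_a")))
  # transitions to non-adjacent zones are a config error
  expect_error(
    simulate_mcsf_session(group_profile(
      transition = list(center = c(bridge = 1))), arena, 60, seed = 1),
    "non-adjacent")
})

test_that("visit counts follow the renewal-theory expectation", {
  # uniform 30 s mean dwell, no habituation: ~ 1 + 1800/30 visits expected
  prof <- group_profile(
    dwell_mean = structure(rep(30, 10), names = zone_ids(arena)),
    habituation = 1)
  n_vis <- vapply(1:200, function(sd)
    nrow(simulate_mcsf_session(prof, arena, 1800, seed = sd)$visits), 0L)
  expected <- 1 + 1800 / 30
  se <- stats::sd(n_vis) / sqrt(length(n_vis))
  expect_lt(abs(mean(n_vis) - expected), 3 * se + 0.1)
})

test_that("dwell-time means converge to the configured values", {
  prof <- group_profile(habituation = 1)
  vis <- do.call(rbind, lapply(1:100, function(sd)
    simulate_mcsf_session(prof, arena, 1800, seed = sd)$visits))
  # drop final truncated visits (censored dwells)
  vis <- vis[vis$t_exit < 1800, ]
  for (z in c("center", "dcr", "corr_a")) {
    d <- vis$duration[vis$zone_id == z]
    mu <- prof$dwell_mean[[z]]
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - mu), 3 * se + 0.5)
  }
})

test_that("gamma dwell times keep the configured mean", {
  prof <- group_profile(habituation = 1, dwell_dist = "gamma",
                        dwell_shape = 2)
  vis <- do.call(rbind, lapply(1:80, function(sd)
    simulate_mcsf_session(prof, arena, 1800, seed = 700 + sd)$visits))
  vis <- vis[vis$t_exit < 1800, ]
  d <- vis$duration[vis$zone_id == "center"]
  mu <- prof$dwell_mean[["center"]]
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 3 * se + 0.5)
})

test_that("habituation depresses per-bin activity within a session", {
  prof <- group_profile(habituation = 0.6)
  vis <- do.call(rbind, lapply(1:60, function(sd)
    simulate_mcsf_session(prof, arena, 1800, seed = 300 + sd)$visits))
  bins <- bin_visit_measures(vis, 1800)
  per_bin <- tapply(bins$n_visits, bins$bin, mean)
  expect_true(all(diff(per_bin) < 0))
})

test_that("bout logs are seed-stable with rate-proportional composition", {
  rates <- c(freezing = 1, walking = 3)
  bm <- c(freezing = 4, walking = 4)
  l1 <- simulate_bout_log(rates, bm, duration = 300, seed = 5)
  l2 <- simulate_bout_log(rates, bm, duration = 300, seed = 5)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  # empirical relative frequency over 500 logs within 3 SE of 0.75
  fr <- vapply(1:500, function(sd) {
    l <- simulate_bout_log(rates, bm, duration = 300, seed = sd)
    mean(l$behavior == "walking")
  }, 0)
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.75), 3 * se)
  # single-behavior log pipelines to a pure reactive score
  nc <- ethogram_default("novel_cage")
  lm <- simulate_bout_log(c(motionless = 1), c(motionless = 8),
                          duration = 300, seed = 3)
  cs <- category_scores(lm, nc)$scores
  expect_equal(cs$rel_freq_score[cs$category == "reactive"], 1)
  expect_error(simulate_bout_log(c(a = 0, b = 0), c(a = 1, b = 1)),
               "all bout rates")
})

test_that("cohorts are pure functions of configuration and master seed", {
  cfg <- simulation_config(n_per_group = 3, trials = 2, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$sidecar, c2$sidecar)
  expect_identical(lapply(c1$novel_logs, as.data.frame),
                   lapply(c2$novel_logs, as.data.frame))
  expect_identical(lapply(c1$home_logs, as.data.frame),
                   lapply(c2$home_logs, as.data.frame))
  c3 <- simulate_cohort(simulation_config(n_per_group = 3, trials = 2,
                                          seed = 12))
  expect_false(identical(c1$visits, c3$visits))
  # structure: 2 groups x 3 rats x 2 trials
  expect_equal(length(unique(c1$visits$rat_id)), 6)
  expect_equal(nrow(c1$sidecar), 12)
  # odd group size: the last rat has no cage mate, hence no home-cage log
  expect_equal(length(c1$home_logs), 4)
})

test_that("effect multipliers shift the targeted behavior in expectation", {
  base <- simulation_config(n_per_group = 6, trials = 1, seed = 50,
                            include = "mcsf")
  eff <- simulation_config(n_per_group = 6, trials = 1, seed = 50,
                           include = "mcsf",
                           effect_multipliers = list("attract.dcr" = 0.25))
  mean_frq_dcr <- function(cfg, reps) {
    m <- vapply(seq_len(reps), function(i) {
      cfg$seed <- cfg$seed + i
      coh <- simulate_cohort(cfg)
      v <- coh$visits
      g2 <- v$group == "g2"
      c(sum(v$zone_id == "dcr" & !g2), sum(v$zone_id == "dcr" & g2))
    }, c(0, 0))
    rowMeans(m)
  }
  m <- mean_frq_dcr(eff, 40)
  expect_lt(m[2], m[1] * 0.8)   # group 2 visits the shelter far less
  # multipliers on point rates double the sidecar counts in expectation
  eff2 <- simulation_config(n_per_group = 12, trials = 1, seed = 60,
                            include = "mcsf",
                            effect_multipliers = list("point_rates.saps" = 2))
  coh <- simulate_cohort(eff2)
  tab <- merge(coh$sidecar,
               unique(coh$visits[, c("rat_id", "group")]), by = "rat_id")
  expect_gt(mean(tab$saps[tab$group == "g2"]),
            mean(tab$saps[tab$group == "g1"]))
  expect_error(apply_effect_multipliers(group_profile(), list(nope = 2)),
               "unknown profile field")
})

test_that("home cage pairing injects complementary submissive bouts", {
  prof <- group_profile()
  prof$home_cage$pairing <- 1   # every dominant bout elicits a response
  pair <- simulate_home_cage_pair(prof, 600, seed = 7,
                                  rat_ids = c("a", "b"))
  dominant <- c("head_tail", "nose_genitals", "following", "approaching",
                "nuzzling", "mount1", "mount2", "chasing", "fight")
  submissive <- c("avoiding", "crawling_under", "submissive_posture")
  n_dom_a <- sum(pair[[1]]$behavior %in% dominant)
  n_sub_b <- sum(pair[[2]]$behavior %in% submissive)
  expect_gte(n_sub_b, n_dom_a)   # own submissive bouts + paired responses
  expect_equal(attr(pair[[1]], "partner_id"), "b")
})
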