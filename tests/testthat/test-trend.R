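test_that("rank_parameter produces pooled mid-ranks with direction control", {
  expect_equal(rank_parameter(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_parameter(c(3, 1, 2), inverse = TRUE), c(1, 3, 2))
  expect_equal(rank_parameter(rep(7, 4)), rep(2.5, 4))
  expect_equal(rank_parameter(c(5, 5, 1)), c(2.5, 2.5, 1))
  r <- rank_parameter(c(4, NA, 2, 9))
  expect_true(is.na(r[2]))
  expect_equal(r[!is.na(r)], c(2, 1, 3))
  expect_error(rank_parameter(c(1, NA, NA)), "degenerate")
})

test_that("category scores equal summed ranks and match the oracle", {
  map <- structure(list(
    one = data.frame(parameter = "a", inverse = FALSE),
    two = data.frame(parameter = c("a", "a"), inverse = c(FALSE, FALSE)),
    mix = data.frame(parameter = c("a", "b"), inverse = c(FALSE, TRUE))
  ), class = "mcsf_category_map")
  tab <- random_table(n = 2, params = c("a", "b"), seed = 11)
  sc <- trend_scores(tab, map)
  s1 <- sc$score[sc$category == "one"]
  expect_equal(s1, rank_parameter(tab$a))
  expect_equal(sc$score[sc$category == "two"], 2 * s1)
  # independent spreadsheet-style recomputation on a hand-built table
  tab4 <- random_table(n = 2, params = c("a", "b"), seed = 5)
  tab4$a[2] <- NA
  osc <- oracle_trend_scores(tab4, map)
  msc <- trend_scores(tab4, map)
  for (cat in colnames(osc)) {
    expect_equal(msc$score[msc$category == cat], unname(osc[, cat]),
                 info = cat)
  }
  expect_error(trend_scores(tab, structure(list(
    x = data.frame(parameter = "nope", inverse = FALSE)),
    class = "mcsf_category_map")), "unmapped")
})

test_that("rank sums conserve m(m+1)/2 and scores are monotone-invariant", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(4:16, 1)
    v <- sample(c(rnorm(n), rep(1.5, n %/% 2)))[seq_len(n)]  # forced ties
    v[sample(n, sample(0:2, 1))] <- NA
    if (sum(!is.na(v)) < 2) next
    r <- rank_parameter(v)
    m <- sum(!is.na(r))
    expect_equal(sum(r, na.rm = TRUE), m * (m + 1) / 2)
  }
  # invariance under strictly monotone transforms
  map <- structure(list(
    c1 = data.frame(parameter = c("a", "b"), inverse = c(FALSE, TRUE))),
    class = "mcsf_category_map")
  tab <- random_table(n = 5, params = c("a", "b"), seed = 7)
  base <- trend_scores(tab, map)
  tab2 <- tab; tab2$a <- exp(tab2$a)          # strictly increasing
  tab3 <- tab; tab3$b <- tab3$b^3 + 5 * tab3$b # strictly increasing
  expect_equal(trend_scores(tab2, map)$score, base$score)
  expect_equal(trend_scores(tab3, map)$score, base$score)
  # monotonicity: raising one rat's non-inverse value never lowers its score
  tab4 <- tab; tab4$a[3] <- tab4$a[3] + 10
  expect_gte(trend_scores(tab4, map)$score[3], base$score[3])
})

test_that("trend tests recover planted group and interaction structure", {
  map <- structure(list(
    c1 = data.frame(parameter = "a", inverse = FALSE)),
    class = "mcsf_category_map")
  # identical groups: t = 0, p = 1
  tab <- random_table(n = 6, params = "a", seed = 13)
  tab$a <- rep(tab$a[1:6], 2)
  sc <- trend_scores(tab, map)
  tt <- trend_tests(sc)
  row <- tt[tt$effect == "t_trial_1", ]
  expect_equal(row$statistic, 0, tolerance = 1e-12)
  expect_equal(row$p, 1)
  # constant shift in both trials: group main effect, no interaction
  tab2 <- random_table(n = 4, params = "a", seed = 17, trials = 2)
  tab2$a[tab2$group == "g2"] <- tab2$a[tab2$group == "g2"] + 50
  sc2 <- trend_scores(tab2, map)
  tt2 <- trend_tests(sc2)
  expect_lt(tt2$p[tt2$effect == "anova_group"], 0.001)
  expect_gt(tt2$p[tt2$effect == "anova_interaction"], 0.05)
  # trial-2 shift in one group only: interaction detected (power over
  # 200 replicated tables well above the nominal level)
  int_p <- vapply(seq_len(200), function(s) {
    tab3 <- random_table(n = 6, params = "a", seed = 1000 + s, trials = 2)
    sel <- tab3$group == "g2" & tab3$trial == "2"
    tab3$a[sel] <- tab3$a[sel] + 100
    tt3 <- trend_tests(trend_scores(tab3, map))
    tt3$p[tt3$effect == "anova_interaction"]
  }, 0)
  expect_gt(mean(int_p <= 0.05), 0.5)
  # repeated-measures df follow the two-group, paired-trial design (n-2)
  tab3 <- random_table(n = 6, params = "a", seed = 19, trials = 2)
  tt3 <- trend_tests(trend_scores(tab3, map))
  expect_equal(tt3$df2[tt3$effect == "anova_group"], 10)
})

test_that("unbalanced repeated designs drop incomplete rats with a warning", {
  map <- structure(list(
    c1 = data.frame(parameter = "a", inverse = FALSE)),
    class = "mcsf_category_map")
  tab <- random_table(n = 4, params = "a", seed = 23, trials = 2)
  tab <- tab[!(tab$rat_id == "r01" & tab$trial == "2"), ]
  sc <- trend_scores(tab, map)
  expect_warning(tt <- trend_tests(sc), "listwise")
  expect_equal(tt$df2[tt$effect == "anova_group"], 5)  # 7 rats - 2
})

test_that("per-trial pooling ranks each trial separately", {
  map <- structure(list(
    c1 = data.frame(parameter = "a", inverse = FALSE)),
    class = "mcsf_category_map")
  tab <- random_table(n = 3, params = "a", seed = 41, trials = 2)
  pooled <- trend_scores(tab, map, pooling = "pooled")
  per <- trend_scores(tab, map, pooling = "per_trial")
  # per-trial ranks run 1..6 within each trial
  for (tr in c("1", "2")) {
    expect_setequal(per$score[per$trial == tr], 1:6)
  }
  # pooled ranks run 1..12 over both trials
  expect_setequal(pooled$score, 1:12)
})

test_that("the bundled category map covers the five functional categories", {
  map <- trend_categories_default()
  expect_setequal(names(map),
                  c("general_activity", "exploratory_activity",
                    "shelter_seeking", "risk_assessment", "risk_taking"))
  expect_true(all(vapply(map, function(m) is.logical(m$inverse), TRUE)))
  # inverse flags sit exactly on the inverted duration parameters
  ga <- map$general_activity
  expect_true(ga$inverse[ga$parameter == "DURFRQ_total_corr"])
  ea <- map$exploratory_activity
  expect_equal(sort(ea$parameter[ea$inverse]),
               c("DUR_center", "DUR_total_corr"))
})
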