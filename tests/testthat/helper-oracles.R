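# Independent oracles used across the suite.  Each is a deliberately
# brute-force reimplementation, kept free of the package's own code paths.

# -- frame-by-frame run-length scan: the visit-extraction oracle -----------
# Counts maximal runs of constant zone assignment over the samples of a
# track with no missing frames (min_visit_duration = 0 case).  Interval and
# step i are credited to the zone of sample i.
oracle_frame_scan <- function(trk, arena) {
  z <- locate_zones(trk$x, trk$y, arena)
  t <- trk$t
  n <- length(t)
  visits <- list()
  cur <- NULL
  for (i in seq_len(n)) {
    if (is.null(cur) || z[i] != cur$zone) {
      if (!is.null(cur)) {
        cur$t_exit <- t[i]
        visits[[length(visits) + 1L]] <- cur
      }
      cur <- list(zone = z[i], t_enter = t[i], duration = 0, distance = 0)
    }
    if (i < n) {
      cur$duration <- cur$duration + (t[i + 1] - t[i])
      cur$distance <- cur$distance +
        sqrt((trk$x[i + 1] - trk$x[i])^2 + (trk$y[i + 1] - trk$y[i])^2)
    }
  }
  cur$t_exit <- t[n]
  visits[[length(visits) + 1L]] <- cur
  out <- do.call(rbind, lapply(visits, as.data.frame))
  # a zone entered only at the final frame carries no measurable time
  out[out$zone != "unassigned" & out$duration > 0, , drop = FALSE]
}

# random exploratory track: a coarse random walk that wanders across zones
# and occasionally out of bounds (stressing "unassigned" handling)
random_track <- function(n = 2000, seed = 1, dt = 0.2, step_sd = 6) {
  set.seed(seed)
  x <- cumsum(c(stats::runif(1, 5, 95), stats::rnorm(n - 1, 0, step_sd)))
  y <- cumsum(c(stats::runif(1, 5, 95), stats::rnorm(n - 1, 0, step_sd)))
  # reflect into a slightly padded box so some points fall outside the arena
  wrap <- function(v) {
    v <- abs(v)
    ifelse(v %% 220 > 110, 220 - v %% 220, v %% 220) - 5
  }
  track(seq(0, by = dt, length.out = n), wrap(x), wrap(y),
        rat_id = paste0("r", seed), session_duration = n * dt)
}

# -- exact-test enumeration oracles ---------------------------------------
# Mann-Whitney: all choose(n1+n2, n1) rank assignments (tie-free data)
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  w_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Wilcoxon signed rank: all 2^n sign patterns (tie-free nonzero differences)
oracle_wsr_p <- function(x, y) {
  d <- (y - x)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-9), mean(v_all >= v_obs - 1e-9)))
}

# Fisher 2x2 two-sided: hypergeometric enumeration with fixed margins,
# summing probabilities <= the observed one (relative slack as in R)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, supp) * choose(r2, c1 - supp) / choose(N, c1)
  p_obs <- pr[match(a, supp)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# -- trend-analysis spreadsheet oracle ------------------------------------
# re-rank a table by explicit sorting loops and sum per category
oracle_trend_scores <- function(tab, map) {
  score <- matrix(0, nrow(tab), length(map),
                  dimnames = list(NULL, names(map)))
  for (ci in seq_along(map)) {
    for (k in seq_len(nrow(map[[ci]]))) {
      v <- tab[[map[[ci]]$parameter[k]]]
      if (map[[ci]]$inverse[k]) v <- -v
      ok <- !is.na(v)
      m <- sum(ok)
      rk <- rep((m + 1) / 2, length(v))      # midrank imputation
      # mid-ranks by counting comparisons
      for (i in which(ok)) {
        rk[i] <- sum(v[ok] < v[i]) + (sum(v[ok] == v[i]) + 1) / 2
      }
      score[, ci] <- score[, ci] + rk
    }
  }
  score
}

# -- tiny fixtures ---------------------------------------------------------
# hand-built visits for a single rat-trial
make_visits <- function(zone, t_enter, t_exit, rat_id = "r1", group = "g1",
                        trial = "1", distance = NA_real_) {
  structure(
    data.frame(rat_id = rat_id, group = group, trial = trial,
               zone_id = zone, t_enter = t_enter, t_exit = t_exit,
               duration = t_exit - t_enter,
               distance = if (all(is.na(distance)))
                 (t_exit - t_enter) * 10 else distance,
               stringsAsFactors = FALSE),
    session_duration = 1800,
    class = c("mcsf_visits", "data.frame"))
}

# parameter table with known structure: n rats per group x p parameters
random_table <- function(n = 6, params = c("a", "b", "c"), seed = 1,
                         trials = 1) {
  set.seed(seed)
  rows <- expand.grid(rat = seq_len(2 * n), trial = seq_len(trials))
  tab <- data.frame(
    rat_id = sprintf("r%02d", rows$rat),
    group = rep(c("g1", "g2"), each = n)[rows$rat],
    trial = as.character(rows$trial),
    stringsAsFactors = FALSE)
  for (p in params) tab[[p]] <- stats::rnorm(nrow(tab))
  class(tab) <- c("mcsf_parameter_table", "data.frame")
  tab
}
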