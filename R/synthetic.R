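#' Group behavioral profile for the simulator
#'
#' A profile holds everything the semi-Markov zone walk and the bout
#' generators need for one experimental group: per-zone mean dwell times
#' (s) and mean speeds (cm/s), transition weights on the arena adjacency
#' graph, point-behavior rates (events/min), ethogram bout rates and mean
#' bout lengths for the novel cage and home cage tests, and a
#' per-10-min-bin multiplicative habituation factor (< 1 means activity
#' declines within a session).
#'
#' The defaults are arbitrary but realistic test fixtures: an active rat
#' making on the order of 100 zone visits per 30-min session, with the
#' shelter dwelled in longest and the exposed bridge briefly.
#'
#' @param dwell_mean Named numeric, mean dwell per zone (s).
#' @param speed Named numeric, mean speed per zone (cm/s).
#' @param transition Named list: zone -> named weights over adjacent zones
#'   (NULL = uniform over the arena adjacency).
#' @param point_rates Named numeric, manually-scored behavior rates
#'   (events/min): rearings, saps, grooming, nose_pokes.
#' @param marking_means Named numeric, per-session Poisson means for urine
#'   spots and fecal boli.
#' @param novel_cage,home_cage Lists with `rates` (bouts/min), `bout_mean`
#'   (s; 0 marks a point event), `gap_mean` (s).
#' @param habituation Multiplicative rate drift per 10-min bin (> 0).
#' @param dwell_dist `"exp"` (default) or `"gamma"`.
#' @param dwell_shape Gamma shape when `dwell_dist = "gamma"`.
#' @return A list of class `mcsf_group_profile`.
#' @export
group_profile <- function(
    dwell_mean = c(center = 12, ctrci = 6, corr_a = 18, corr_b = 18,
                   corr_c = 18, dcr = 30, hurdle = 12, slope = 7, be = 5,
                   bridge = 10),
    speed = c(center = 14, ctrci = 10, corr_a = 12, corr_b = 12,
              corr_c = 12, dcr = 4, hurdle = 8, slope = 10, be = 10,
              bridge = 8),
    transition = NULL,
    point_rates = c(rearings = 2, saps = 1, grooming = 0.5,
                    nose_pokes = 1.5),
    marking_means = c(urine_spots = 4, fecal_boli = 3),
    novel_cage = list(
      rates = c(stretched_approach = 0.5, sap = 0.8, grooming = 0.6,
                freezing = 0.4, motionless = 0.6, free_rearing = 1.2,
                investigating = 2.0, wall_rearing = 1.0, walking = 1.5),
      bout_mean = c(stretched_approach = 3, sap = 2, grooming = 8,
                    freezing = 5, motionless = 10, free_rearing = 3,
                    investigating = 6, wall_rearing = 4, walking = 4),
      gap_mean = 2),
    home_cage = list(
      rates = c(head_head = 0.6, nose_side = 0.8, nose_nose = 0.6,
                passing = 0.8, head_tail = 0.4, nose_genitals = 0.3,
                following = 0.4, approaching = 0.6, nuzzling = 0.5,
                mount1 = 0.2, mount2 = 0.1, chasing = 0.15, fight = 0.15,
                avoiding = 0.4, crawling_under = 0.2,
                submissive_posture = 0.2, burrowing = 0.5),
      bout_mean = c(head_head = 2, nose_side = 3, nose_nose = 2,
                    passing = 0, head_tail = 2, nose_genitals = 2,
                    following = 4, approaching = 3, nuzzling = 4,
                    mount1 = 3, mount2 = 4, chasing = 3, fight = 5,
                    avoiding = 3, crawling_under = 3,
                    submissive_posture = 5, burrowing = 6),
      gap_mean = 3,
      pairing = 0.3),
    habituation = 0.8,
    dwell_dist = c("exp", "gamma"),
    dwell_shape = 2) {
  dwell_dist <- match.arg(dwell_dist)
  prof <- structure(list(
    dwell_mean = dwell_mean, speed = speed, transition = transition,
    point_rates = point_rates, marking_means = marking_means,
    novel_cage = novel_cage, home_cage = home_cage,
    habituation = habituation, dwell_dist = dwell_dist,
    dwell_shape = dwell_shape
  ), class = "mcsf_group_profile")
  if (any(dwell_mean <= 0) || any(speed <= 0) || habituation <= 0 ||
      any(point_rates < 0)) {
    stop("profile config error: rates, means and habituation must be positive")
  }
  prof
}

# uniform transition weights over the arena adjacency graph
default_transitions <- function(arena) {
  ids <- zone_ids(arena)
  out <- lapply(ids, function(z) {
    nb <- zone_neighbors(arena, z)
    stats::setNames(rep(1, length(nb)), nb)
  })
  stats::setNames(out, ids)
}

validate_profile_against_arena <- function(profile, arena) {
  ids <- zone_ids(arena)
  miss <- setdiff(ids, names(profile$dwell_mean))
  if (length(miss)) {
    stop("profile config error: dwell_mean missing zone(s) ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(profile$transition)) {
    for (z in names(profile$transition)) {
      nb <- zone_neighbors(arena, z)
      bad <- setdiff(names(profile$transition[[z]]), nb)
      if (length(bad)) {
        stop("profile config error: transition from '", z,
             "' to non-adjacent zone(s) ", paste(bad, collapse = ", "))
      }
    }
  }
  invisible(profile)
}

#' Apply named effect multipliers to a group profile
#'
#' Multiplier names are dotted paths into the profile
#' (`"point_rates.saps"`, `"dwell_mean.dcr"`,
#' `"novel_cage.rates.walking"`); the special form `"attract.<zone>"`
#' scales every transition weight into that zone.
#'
#' @param profile An `mcsf_group_profile`.
#' @param multipliers Named list/vector of positive factors.
#' @param arena Arena (needed to materialize default transitions for
#'   `attract.*`).
#' @return The modified profile.
#' @export
apply_effect_multipliers <- function(profile, multipliers, arena = NULL) {
  for (nm in names(multipliers)) {
    f <- multipliers[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "attract") {
      if (is.null(profile$transition)) {
        if (is.null(arena)) stop("config error: attract.* needs an arena")
        profile$transition <- default_transitions(arena)
      }
      target <- parts[2]
      for (z in names(profile$transition)) {
        hit <- names(profile$transition[[z]]) == target
        profile$transition[[z]][hit] <- profile$transition[[z]][hit] * f
      }
    } else {
      profile <- modify_path(profile, parts, f)
    }
  }
  profile
}

modify_path <- function(lst, parts, f) {
  if (is.null(lst[[parts[1]]])) {
    stop("config error: unknown profile field '", parts[1], "'")
  }
  if (length(parts) == 1L) {
    lst[[parts[1]]] <- lst[[parts[1]]] * f
  } else {
    lst[[parts[1]]] <- modify_path(lst[[parts[1]]], parts[-1], f)
  }
  lst
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_per_group Rats per group (>= 2).
#' @param trials Number of MCSF trials (1 or 2).
#' @param seed Master seed; with the seed fixed the whole cohort is a pure
#'   function of the configuration.
#' @param group_names Two group labels.
#' @param profile Baseline `mcsf_group_profile` (group 1).
#' @param effect_multipliers Named multipliers applied to group 2's profile
#'   ([apply_effect_multipliers()]); empty list = exchangeable groups.
#' @param mcsf_duration,novel_duration,home_duration Session lengths (s).
#' @param frame_rate Track sampling rate (Hz).
#' @param tracks Emit frame-level tracks for MCSF sessions?
#' @param include Which tests to simulate.
#' @return A list of class `mcsf_simulation_config`.
#' @export
simulation_config <- function(n_per_group = 12L, trials = 2L, seed = 1L,
                              group_names = c("g1", "g2"),
                              profile = group_profile(),
                              effect_multipliers = list(),
                              mcsf_duration = 1800, novel_duration = 300,
                              home_duration = 600, frame_rate = 5,
                              tracks = FALSE,
                              include = c("mcsf", "novel_cage",
                                          "home_cage")) {
  if (n_per_group < 2L) stop("config error: n_per_group must be >= 2")
  if (!trials %in% 1:2) stop("config error: trials must be 1 or 2")
  structure(list(
    n_per_group = as.integer(n_per_group), trials = as.integer(trials),
    seed = as.integer(seed), group_names = group_names, profile = profile,
    effect_multipliers = effect_multipliers,
    mcsf_duration = mcsf_duration, novel_duration = novel_duration,
    home_duration = home_duration, frame_rate = frame_rate,
    tracks = tracks, include = include
  ), class = "mcsf_simulation_config")
}

# dwell draw with mean mu (floor keeps every visit resolvable at the track
# frame rate)
draw_dwell <- function(mu, profile, floor_s) {
  d <- if (profile$dwell_dist == "exp") {
    stats::rexp(1, rate = 1 / mu)
  } else {
    stats::rgamma(1, shape = profile$dwell_shape,
                  scale = mu / profile$dwell_shape)
  }
  max(d, floor_s)
}

#' Simulate one MCSF session as a semi-Markov walk on the zone graph
#'
#' Starting in the center (where the animal is released), the walk draws a
#' zone dwell time (exponential by default, gamma optional), then moves to
#' an adjacent zone with probability proportional to the profile's
#' transition weights.  The habituation factor scales dwell and behavior
#' rates per 10-min bin.  Dwell draws are floored at two frame intervals so
#' every generated visit is resolvable in the emitted track.
#'
#' @param profile An `mcsf_group_profile`.
#' @param arena An `mcsf_arena`.
#' @param duration Session length (s).
#' @param seed Integer seed.
#' @param frame_rate Track sampling rate (Hz).
#' @param emit_track Also build the frame-level track (bounded random walk
#'   within each zone's geometry at the profile speed)?
#' @param rat_id,group,trial Labels stamped on the outputs.
#' @return A list with `visits` (`mcsf_visits`) and `track` (`mcsf_track`
#'   or NULL).  When a track is emitted, per-visit distances are the path
#'   step sums, so visits and track agree.
#' @export
simulate_mcsf_session <- function(profile, arena, duration = 1800, seed = 1L,
                                  frame_rate = 5, emit_track = FALSE,
                                  rat_id = "rat", group = "g1", trial = "1") {
  validate_profile_against_arena(profile, arena)
  trans <- profile$transition
  if (is.null(trans)) trans <- default_transitions(arena)
  set.seed(seed)
  floor_s <- 2 / frame_rate
  bin_w <- 600
  z <- "center"; t <- 0
  zs <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  while (t < duration) {
    hab <- profile$habituation^(floor(t / bin_w))
    dw <- draw_dwell(profile$dwell_mean[[z]] / hab, profile, floor_s)
    t_exit <- min(t + dw, duration)
    zs <- c(zs, z); t0 <- c(t0, t); t1 <- c(t1, t_exit)
    t <- t_exit
    if (duration - t < floor_s) {
      # absorb a sub-frame remainder so every visit is track-resolvable
      t1[length(t1)] <- duration
      break
    }
    w <- trans[[z]]
    z <- if (length(w) == 1L) names(w) else sample(names(w), 1L, prob = w)
  }
  dur_v <- t1 - t0
  trk <- NULL
  if (emit_track) {
    n_frames <- floor(duration * frame_rate)
    tf <- (seq_len(n_frames) - 1L) / frame_rate
    vi <- findInterval(tf, t0)          # visit index per frame
    xs <- numeric(n_frames); ys <- numeric(n_frames)
    last <- c(50, 50)
    dist_v <- numeric(length(zs))
    ids <- zone_ids(arena)
    zone_defs <- stats::setNames(arena$zones, ids)
    children_of <- lapply(ids, function(z) {
      kids <- ids[vapply(arena$zones, function(k)
        identical(k$parent_zone, z), TRUE)]
      zone_defs[kids]
    })
    names(children_of) <- ids
    for (v in seq_along(zs)) {
      idx <- which(vi == v)
      if (!length(idx)) next
      path <- random_path_in_zone(zone_defs[[zs[v]]], length(idx),
                                  profile$speed[[zs[v]]] / frame_rate, last,
                                  exclude = children_of[[zs[v]]])
      xs[idx] <- path[, 1]; ys[idx] <- path[, 2]
      last <- path[nrow(path), ]
    }
    step <- sqrt(diff(xs)^2 + diff(ys)^2)
    dist_v <- vapply(seq_along(zs), function(v) {
      idx <- which(vi == v)
      sum(step[idx[idx < n_frames]])
    }, 0)
    trk <- track(tf, xs, ys, rat_id = rat_id, group = group, trial = trial,
                 frame_rate = frame_rate, session_duration = duration)
  } else {
    dist_v <- profile$speed[zs] * dur_v * exp(stats::rnorm(length(zs), 0, 0.15))
  }
  visits <- structure(
    data.frame(rat_id = rat_id, group = group, trial = as.character(trial),
               zone_id = zs, t_enter = t0, t_exit = t1, duration = dur_v,
               distance = unname(dist_v), stringsAsFactors = FALSE),
    session_duration = duration,
    class = c("mcsf_visits", "data.frame"))
  list(visits = visits, track = trk)
}

# persistent random walk confined to a zone's geometry; enters near `from`
# and stays out of any nested child zones in `exclude`
random_path_in_zone <- function(zone, n, step, from, exclude = list()) {
  clamp <- function(pt) {
    if (zone$shape == "rect") {
      eps <- 1e-6
      pt <- c(min(max(pt[1], zone$xlim[1] + eps), zone$xlim[2] - eps),
              min(max(pt[2], zone$ylim[1] + eps), zone$ylim[2] - eps))
    } else {
      d <- pt - zone$center
      r <- sqrt(sum(d^2))
      if (r >= zone$radius) {
        pt <- zone$center + d / max(r, 1e-9) * (zone$radius - 1e-6)
      }
    }
    for (child in exclude) {
      if (child$shape == "circle") {
        d <- pt - child$center
        r <- sqrt(sum(d^2))
        if (r < child$radius) {
          if (r < 1e-9) { d <- c(1, 0); r <- 1 }
          pt <- child$center + d / r * (child$radius + 1e-6)
        }
      } else if (pt[1] >= child$xlim[1] && pt[1] < child$xlim[2] &&
                 pt[2] >= child$ylim[1] && pt[2] < child$ylim[2]) {
        # push out across the nearest rect edge
        dists <- c(pt[1] - child$xlim[1], child$xlim[2] - pt[1],
                   pt[2] - child$ylim[1], child$ylim[2] - pt[2])
        side <- which.min(dists)
        if (side == 1) pt[1] <- child$xlim[1] - 1e-6
        if (side == 2) pt[1] <- child$xlim[2] + 1e-6
        if (side == 3) pt[2] <- child$ylim[1] - 1e-6
        if (side == 4) pt[2] <- child$ylim[2] + 1e-6
      }
    }
    pt
  }
  out <- matrix(0, n, 2)
  pos <- clamp(from)
  ang <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    out[i, ] <- pos
    ang <- ang + stats::rnorm(1, 0, 0.6)
    cand <- pos + step * c(cos(ang), sin(ang))
    cl <- clamp(cand)
    if (!isTRUE(all.equal(cl, cand))) ang <- ang + pi / 2
    pos <- cl
  }
  out
}

#' Simulate an ethogram bout log by alternating renewal
#'
#' Bouts alternate with exponential inter-bout gaps; each bout's behavior
#' is drawn with probability proportional to its rate and its length is
#' exponential at the behavior's mean (a zero mean marks a point event).
#' The expected relative frequency of a behavior equals its normalized
#' rate.
#'
#' @param rates Named bout rates (bouts/min), at least one positive.
#' @param bout_mean Named mean bout lengths (s).
#' @param gap_mean Mean inter-bout gap (s).
#' @param duration Session length (s).
#' @param seed Integer seed.
#' @param rat_id,group,partner_id Labels.
#' @param def Optional ethogram for validation.
#' @return An `mcsf_bout_log`.
#' @export
simulate_bout_log <- function(rates, bout_mean, gap_mean = 2, duration = 300,
                              seed = 1L, rat_id = "rat", group = "g1",
                              partner_id = NA_character_, def = NULL) {
  if (all(rates <= 0)) stop("config error: all bout rates are zero")
  rates <- rates[rates > 0]
  set.seed(seed)
  t <- 0
  beh <- character(0); t_start <- numeric(0); t_stop <- numeric(0)
  repeat {
    t <- t + stats::rexp(1, rate = 1 / gap_mean)
    if (t >= duration) break
    b <- if (length(rates) == 1L) names(rates) else
      sample(names(rates), 1L, prob = rates)
    mu <- bout_mean[[b]]
    len <- if (is.null(mu) || mu <= 0) 0 else stats::rexp(1, rate = 1 / mu)
    stop_t <- min(t + len, duration)
    beh <- c(beh, b); t_start <- c(t_start, t); t_stop <- c(t_stop, stop_t)
    t <- stop_t
  }
  if (!length(beh)) {
    # guarantee a non-degenerate log: force one bout of the most likely
    # behavior at session start
    b <- names(rates)[which.max(rates)]
    beh <- b; t_start <- 0
    t_stop <- min(max(bout_mean[[b]], 1), duration)
  }
  bout_log(beh, t_start, t_stop, rat_id = rat_id, group = group,
           partner_id = partner_id, def = def)
}

#' Simulate a full synthetic cohort
#'
#' Generates the complete dataset for two groups: MCSF zone visits (and
#' optionally tracks) per rat and trial, manually-scored sidecar counts,
#' per-10-min-bin behavior counts, novel cage bout logs, and jointly
#' generated home cage bout logs for cage pairs (with a configurable
#' probability that a dominant/aggressive bout elicits the partner's
#' complementary submissive response).  Per-session seeds are derived
#' deterministically from the master seed, and group 2's profile is group
#' 1's with the configured effect multipliers applied.  Cage pairs are
#' formed within group in rat order; with an odd group size the last rat
#' has no cage mate and gets no home-cage log.
#'
#' @param config An `mcsf_simulation_config`.
#' @param arena An `mcsf_arena` (default [mcsf_default()]).
#' @return A list of class `mcsf_cohort`: `visits`, `sidecar`,
#'   `bin_counts`, `tracks` (list or NULL), `novel_logs`, `home_logs`,
#'   `config`, `arena`.
#' @export
simulate_cohort <- function(config, arena = mcsf_default()) {
  stopifnot(inherits(config, "mcsf_simulation_config"))
  profiles <- list(config$profile,
                   apply_effect_multipliers(config$profile,
                                            config$effect_multipliers, arena))
  n <- config$n_per_group
  rats <- data.frame(
    rat_id = c(sprintf("%s_r%02d", config$group_names[1], seq_len(n)),
               sprintf("%s_r%02d", config$group_names[2], seq_len(n))),
    group = rep(config$group_names, each = n),
    gi = rep(1:2, each = n), stringsAsFactors = FALSE)
  n_rats <- nrow(rats)
  set.seed(config$seed)
  pool <- sample.int(2147483646L, n_rats * (config$trials + 2L))
  seed_of <- function(r, slot) pool[(r - 1L) * (config$trials + 2L) + slot]

  visits <- list(); tracks <- list(); sidecar <- list(); bins <- list()
  novel_logs <- list(); home_logs <- list()
  n_bins <- ceiling(config$mcsf_duration / 600)

  if ("mcsf" %in% config$include) {
    for (r in seq_len(n_rats)) {
      prof <- profiles[[rats$gi[r]]]
      for (tr in seq_len(config$trials)) {
        s <- seed_of(r, tr)
        ses <- simulate_mcsf_session(prof, arena, config$mcsf_duration,
                                     seed = s, frame_rate = config$frame_rate,
                                     emit_track = config$tracks,
                                     rat_id = rats$rat_id[r],
                                     group = rats$group[r], trial = tr)
        visits[[length(visits) + 1L]] <- ses$visits
        if (config$tracks) tracks[[paste0(rats$rat_id[r], "_t", tr)]] <- ses$track
        # point behaviors and markings (seed stream continues from session)
        pr <- prof$point_rates
        cnt <- matrix(0, n_bins, length(pr),
                      dimnames = list(NULL, names(pr)))
        for (b in seq_len(n_bins)) {
          lambda <- pr * 10 * prof$habituation^(b - 1)
          cnt[b, ] <- stats::rpois(length(pr), lambda)
        }
        marks <- stats::rpois(length(prof$marking_means), prof$marking_means)
        sidecar[[length(sidecar) + 1L]] <- data.frame(
          rat_id = rats$rat_id[r], trial = as.character(tr),
          as.list(colSums(cnt)),
          as.list(stats::setNames(marks, names(prof$marking_means))),
          stringsAsFactors = FALSE)
        bins[[length(bins) + 1L]] <- data.frame(
          rat_id = rats$rat_id[r], group = rats$group[r],
          trial = as.character(tr), bin = seq_len(n_bins), cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if ("novel_cage" %in% config$include) {
    for (r in seq_len(n_rats)) {
      prof <- profiles[[rats$gi[r]]]
      novel_logs[[rats$rat_id[r]]] <- simulate_bout_log(
        prof$novel_cage$rates, prof$novel_cage$bout_mean,
        prof$novel_cage$gap_mean, config$novel_duration,
        seed = seed_of(r, config$trials + 1L),
        rat_id = rats$rat_id[r], group = rats$group[r])
    }
  }
  if ("home_cage" %in% config$include) {
    # cage pairs within group: (1,2), (3,4), ...
    for (g in 1:2) {
      idx <- which(rats$gi == g)
      for (k in seq(1, length(idx) - 1, by = 2)) {
        r1 <- idx[k]; r2 <- idx[k + 1]
        pair <- simulate_home_cage_pair(
          profiles[[g]], config$home_duration,
          seed = seed_of(r1, config$trials + 2L),
          rat_ids = rats$rat_id[c(r1, r2)], group = rats$group[r1])
        home_logs[[rats$rat_id[r1]]] <- pair[[1]]
        home_logs[[rats$rat_id[r2]]] <- pair[[2]]
      }
    }
  }
  structure(list(
    visits = if (length(visits)) {
      out <- do.call(rbind, visits)
      class(out) <- c("mcsf_visits", "data.frame")
      out
    } else NULL,
    sidecar = if (length(sidecar)) do.call(rbind, sidecar) else NULL,
    bin_counts = if (length(bins)) do.call(rbind, bins) else NULL,
    tracks = if (config$tracks) tracks else NULL,
    novel_logs = novel_logs, home_logs = home_logs,
    config = config, arena = arena
  ), class = "mcsf_cohort")
}

#' @rdname simulate_cohort
#' @param profile Group profile shared by the pair.
#' @param duration Session length (s).
#' @param seed Integer seed.
#' @param rat_ids Character vector of the two cage mates' ids.
#' @param group Group label.
#' @export
simulate_home_cage_pair <- function(profile, duration = 600, seed = 1L,
                                    rat_ids = c("r1", "r2"), group = "g1") {
  hc <- profile$home_cage
  logs <- list(
    simulate_bout_log(hc$rates, hc$bout_mean, hc$gap_mean, duration,
                      seed = seed, rat_id = rat_ids[1], group = group,
                      partner_id = rat_ids[2]),
    simulate_bout_log(hc$rates, hc$bout_mean, hc$gap_mean, duration,
                      seed = seed + 1L, rat_id = rat_ids[2], group = group,
                      partner_id = rat_ids[1]))
  # complementary pairing: a dominant/aggressive bout of one rat elicits a
  # submissive response from the partner with probability `pairing`
  set.seed(seed + 2L)
  dominant <- c("head_tail", "nose_genitals", "following", "approaching",
                "nuzzling", "mount1", "mount2", "chasing", "fight")
  submissive <- c("avoiding", "crawling_under", "submissive_posture")
  for (i in 1:2) {
    j <- 3L - i
    src <- logs[[i]]
    hits <- which(src$behavior %in% dominant &
                    stats::runif(nrow(src)) < hc$pairing)
    if (length(hits)) {
      resp <- sample(submissive, length(hits), replace = TRUE)
      combined <- bout_log(
        c(logs[[j]]$behavior, resp),
        c(logs[[j]]$t_start, src$t_start[hits]),
        c(logs[[j]]$t_stop, src$t_stop[hits]),
        rat_id = attr(logs[[j]], "rat_id"), group = group,
        partner_id = attr(logs[[j]], "partner_id"))
      logs[[j]] <- combined
    }
  }
  logs
}

#' Pipeline power / type-I recovery experiment
#'
#' Repeatedly simulates a cohort, runs the MCSF pipeline (parameter table,
#' Mann-Whitney battery, trend-analysis category scores and within-trial
#' group t-tests) and records per-parameter and per-category rejection
#' rates at `alpha`.  With no configured effects the rates estimate type-I
#' error; with effects, the affected parameters' rates estimate power.
#'
#' @param config An `mcsf_simulation_config` (only the MCSF part is run;
#'   replicate r uses master seed `config$seed + r`).
#' @param n_replicates Number of simulated cohorts.
#' @param alpha Rejection threshold.
#' @param trial Trial analyzed (default "1").
#' @param parameters Parameter columns to test (default: all numeric).
#' @param arena Arena.
#' @return A list of class `mcsf_recovery` with `parameter_rates` and
#'   `category_rates` (named rejection-rate vectors), `n_replicates`,
#'   `alpha`, `effects`.
#' @export
recovery_experiment <- function(config, n_replicates = 200, alpha = 0.05,
                                trial = "1", parameters = NULL,
                                arena = mcsf_default()) {
  param_rej <- NULL; cat_rej <- NULL
  cfg <- config
  cfg$include <- "mcsf"
  cfg$tracks <- FALSE
  map <- trend_categories_default()
  for (rep_i in seq_len(n_replicates)) {
    cfg$seed <- (config$seed + rep_i) %% 2147483647L
    coh <- simulate_cohort(cfg, arena)
    tab <- parameter_table(coh$visits, arena, sidecar = coh$sidecar,
                           missing_mode = "within_trial")
    tab1 <- tab[tab$trial == trial, , drop = FALSE]
    res <- group_compare_all(tab1, parameters = parameters)
    p <- stats::setNames(res$p, res$parameter)
    rej <- as.integer(!is.na(p) & p <= alpha)
    names(rej) <- names(p)
    if (is.null(param_rej)) {
      param_rej <- rej
      param_n <- as.integer(!is.na(p)); names(param_n) <- names(p)
    } else {
      common <- intersect(names(param_rej), names(rej))
      param_rej[common] <- param_rej[common] + rej[common]
      param_n[common] <- param_n[common] + as.integer(!is.na(p[common]))
    }
    sc <- trend_scores(tab1, map)
    tt <- trend_tests(sc)
    tt <- tt[tt$effect == paste0("t_trial_", trial), , drop = FALSE]
    crej <- stats::setNames(as.integer(tt$p <= alpha), tt$category)
    if (is.null(cat_rej)) {
      cat_rej <- crej; cat_n <- stats::setNames(rep(1L, length(crej)),
                                                names(crej))
    } else {
      cat_rej[names(crej)] <- cat_rej[names(crej)] + crej
      cat_n[names(crej)] <- cat_n[names(crej)] + 1L
    }
  }
  structure(list(
    parameter_rates = param_rej / pmax(param_n, 1L),
    category_rates = cat_rej / pmax(cat_n, 1L),
    n_replicates = n_replicates, alpha = alpha,
    effects = names(config$effect_multipliers)
  ), class = "mcsf_recovery")
}
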