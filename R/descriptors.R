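#' Zone-level descriptive parameters for one rat-trial
#'
#' For every arena zone: latency to first visit (LAT, s; NA when never
#' visited), number of visits (FRQ), total visit duration (DUR, s), mean
#' duration per visit (DUR/FRQ, s; NA when FRQ = 0), distance moved (cm) and
#' mean velocity within the zone (cm/s = distance / duration).
#'
#' @param visits An `mcsf_visits` data.frame from a single rat-trial.
#' @param arena An `mcsf_arena`.
#' @param session_duration Session length (s); defaults to the arena's.
#' @return A data.frame of class `mcsf_descriptors`, one row per zone, with
#'   columns `zone_id`, `lat`, `frq`, `dur`, `durfrq`, `dist`, `vel`.
#' @export
compute_zone_descriptors <- function(visits, arena,
                                     session_duration = arena$session_duration) {
  if (length(unique(visits$rat_id)) > 1L || length(unique(visits$trial)) > 1L) {
    stop("usage error: compute_zone_descriptors expects visits from one rat-trial")
  }
  zones <- zone_ids(arena)
  zf <- factor(visits$zone_id, levels = zones)
  lat <- as.numeric(tapply(visits$t_enter, zf, min))
  frq <- as.integer(table(zf))
  dur <- as.numeric(tapply(visits$duration, zf, sum))
  dur[is.na(dur)] <- 0
  dist <- as.numeric(tapply(visits$distance, zf, sum))
  dist[is.na(dist)] <- 0
  durfrq <- ifelse(frq > 0, dur / frq, NA_real_)
  vel <- ifelse(dur > 0, dist / dur, NA_real_)
  structure(
    data.frame(zone_id = zones, lat = lat, frq = frq, dur = dur,
               durfrq = durfrq, dist = dist, vel = vel,
               stringsAsFactors = FALSE),
    rat_id = visits$rat_id[1], group = visits$group[1],
    trial = visits$trial[1], session_duration = session_duration,
    class = c("mcsf_descriptors", "data.frame")
  )
}

#' Append aggregate-zone rows (TOTAL CORR, ARENA) to zone descriptors
#'
#' Aggregates are defined in the arena config (`total_corr` = corridors A-C,
#' `arena` = all zones).  FRQ, DUR and distance sum over members; LAT is the
#' minimum member latency; DUR/FRQ is summed DUR over summed FRQ; velocity is
#' summed distance over summed duration.  TOTAL ACT (total number of visits
#' to all zones) equals the `arena` aggregate's FRQ.
#'
#' @param desc An `mcsf_descriptors` data.frame.
#' @param arena An `mcsf_arena`.
#' @return The descriptors with one extra row per aggregate.
#' @export
compute_aggregates <- function(desc, arena) {
  out <- desc
  for (agg in names(arena$aggregates)) {
    members <- desc[desc$zone_id %in% arena$aggregates[[agg]], , drop = FALSE]
    frq <- sum(members$frq)
    dur <- sum(members$dur)
    dist <- sum(members$dist)
    lat <- if (all(is.na(members$lat))) NA_real_ else min(members$lat, na.rm = TRUE)
    row <- data.frame(zone_id = agg, lat = lat, frq = frq, dur = dur,
                      durfrq = if (frq > 0) dur / frq else NA_real_,
                      dist = dist,
                      vel = if (dur > 0) dist / dur else NA_real_,
                      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  attributes(out)[c("rat_id", "group", "trial", "session_duration")] <-
    attributes(desc)[c("rat_id", "group", "trial", "session_duration")]
  class(out) <- class(desc)
  out
}

#' Percent frequency and duration per zone
#'
#' `%FRQ(zone) = 100 * FRQ(zone) / TOTAL ACT`.  `%DUR(zone)` uses either the
#' total time of visits to all zones (`"total_visits_time"`, the default used
#' in parameter tables) or the session duration (`"trial_time"`, the variant
#' used for time-budget displays) as denominator.  When TOTAL ACT is 0 the
#' relative measures are missing.
#'
#' @param desc Descriptors including aggregate rows ([compute_aggregates()]).
#' @param denominator_mode `"total_visits_time"` or `"trial_time"`.
#' @return The descriptors with `pct_frq` and `pct_dur` columns (NA for
#'   aggregate rows other than zones' own shares).
#' @export
compute_relative_measures <- function(desc,
                                      denominator_mode = c("total_visits_time",
                                                           "trial_time")) {
  denominator_mode <- match.arg(denominator_mode)
  if (!"arena" %in% desc$zone_id) {
    stop("usage error: compute_relative_measures needs the 'arena' aggregate ",
         "row (run compute_aggregates first)")
  }
  total_act <- desc$frq[desc$zone_id == "arena"]
  total_time <- desc$dur[desc$zone_id == "arena"]
  denom <- switch(denominator_mode,
                  total_visits_time = total_time,
                  trial_time = attr(desc, "session_duration"))
  if (total_act == 0) {
    desc$pct_frq <- NA_real_
    desc$pct_dur <- NA_real_
  } else {
    desc$pct_frq <- 100 * desc$frq / total_act
    desc$pct_dur <- if (denom > 0) 100 * desc$dur / denom else NA_real_
  }
  attr(desc, "denominator_mode") <- denominator_mode
  desc
}

#' Behavioral indexes from zone descriptors
#'
#' Four indexes computed per rat-trial from the Table of descriptive
#' parameters:
#' * shelter/corridor index `(FRQ DCR - FRQ corrA) / (FRQ DCR + FRQ corrA)` —
#'   home-base use of the shelter;
#' * slope/bridge interval `(LAT slope - LAT bridge) / LAT slope` — delay of
#'   visiting the bridge from the slope (impulsivity interpretation);
#' * risk/shelter duration index `(DUR bridge - DUR DCR) / (DUR bridge + DUR DCR)`;
#' * risk/shelter frequency index `(FRQ bridge - FRQ DCR) / (FRQ bridge + FRQ DCR)`.
#'
#' A zero denominator or a missing input yields a missing index (absent
#' values are treated as missing data, never as 0 or +/-1).  The three
#' ratio-form indexes lie in `[-1, 1]`.
#'
#' @param desc An `mcsf_descriptors` data.frame (zone rows required:
#'   `dcr`, `corr_a`, `slope`, `bridge`).
#' @return Named numeric vector of the four indexes.
#' @export
compute_indexes <- function(desc) {
  g <- function(col, zone) {
    v <- desc[[col]][match(zone, desc$zone_id)]
    if (length(v) != 1L) NA_real_ else v
  }
  safe_ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  frq_dcr <- g("frq", "dcr"); frq_corr_a <- g("frq", "corr_a")
  lat_slope <- g("lat", "slope"); lat_bridge <- g("lat", "bridge")
  dur_bridge <- g("dur", "bridge"); dur_dcr <- g("dur", "dcr")
  frq_bridge <- g("frq", "bridge")
  c(
    idx_shelter_corridor = safe_ratio(frq_dcr - frq_corr_a, frq_dcr + frq_corr_a),
    idx_slope_bridge = safe_ratio(lat_slope - lat_bridge, lat_slope),
    idx_risk_shelter_dur = safe_ratio(dur_bridge - dur_dcr, dur_bridge + dur_dcr),
    idx_risk_shelter_frq = safe_ratio(frq_bridge - frq_dcr, frq_bridge + frq_dcr)
  )
}

#' Assemble the rats x parameters table
#'
#' One row per rat-trial; columns follow the standard abbreviations:
#' `LAT_*`, `FRQ_*`, `DUR_*`, `DURFRQ_*`, `DIST_*`, `VEL_*`, `PCT_FRQ_*`,
#' `PCT_DUR_*` per zone and aggregate, `TOTAL_ACT`, the four `idx_*` index
#' columns, and any manually scored sidecar counts (rearings, SAPs, grooming,
#' nose pokes, urine spots, fecal boli).
#'
#' @param visits An `mcsf_visits` data.frame covering one or more rat-trials.
#' @param arena An `mcsf_arena`.
#' @param sidecar Optional data.frame of manually scored counts keyed by
#'   `rat_id` and `trial` (remaining numeric columns are carried over).
#' @param denominator_mode Passed to [compute_relative_measures()].
#' @param missing_mode If not NULL, [apply_missing_rules()] is applied with
#'   this mode.
#' @return A data.frame of class `mcsf_parameter_table` with identifier
#'   columns `rat_id`, `group`, `trial` followed by numeric parameters.
#' @export
parameter_table <- function(visits, arena, sidecar = NULL,
                            denominator_mode = "total_visits_time",
                            missing_mode = NULL) {
  key <- interaction(visits$rat_id, visits$trial, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(visits)), key), function(idx) {
    v <- visits[idx, , drop = FALSE]
    class(v) <- c("mcsf_visits", "data.frame")
    desc <- compute_zone_descriptors(v, arena)
    desc <- compute_aggregates(desc, arena)
    desc <- compute_relative_measures(desc, denominator_mode)
    idxs <- compute_indexes(desc)
    wide <- c(
      stats::setNames(desc$lat, paste0("LAT_", desc$zone_id)),
      stats::setNames(desc$frq, paste0("FRQ_", desc$zone_id)),
      stats::setNames(desc$dur, paste0("DUR_", desc$zone_id)),
      stats::setNames(desc$durfrq, paste0("DURFRQ_", desc$zone_id)),
      stats::setNames(desc$dist, paste0("DIST_", desc$zone_id)),
      stats::setNames(desc$vel, paste0("VEL_", desc$zone_id)),
      stats::setNames(desc$pct_frq, paste0("PCT_FRQ_", desc$zone_id)),
      stats::setNames(desc$pct_dur, paste0("PCT_DUR_", desc$zone_id)),
      TOTAL_ACT = desc$frq[desc$zone_id == "arena"],
      idxs
    )
    data.frame(rat_id = v$rat_id[1], group = v$group[1], trial = v$trial[1],
               as.list(wide), check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(sidecar)) {
    need <- c("rat_id", "trial")
    if (!all(need %in% names(sidecar))) {
      stop("usage error: sidecar must have rat_id and trial columns")
    }
    sidecar$trial <- as.character(sidecar$trial)
    tab <- merge(tab, sidecar, by = c("rat_id", "trial"), all.x = TRUE,
                 sort = FALSE)
    tab <- tab[order(tab$rat_id, tab$trial), ]
    tab <- tab[, c("rat_id", "group", "trial",
                   setdiff(names(tab), c("rat_id", "group", "trial")))]
    rownames(tab) <- NULL
  }
  class(tab) <- c("mcsf_parameter_table", "data.frame")
  attr(tab, "session_duration") <- arena$session_duration
  attr(tab, "zones") <- zone_ids(arena)
  if (!is.null(missing_mode)) {
    tab <- apply_missing_rules(tab, missing_mode, arena$session_duration)
  }
  tab
}

#' Apply unvisited-zone missing/imputation rules to a parameter table
#'
#' When a rat never entered a zone, the zone's dependent variables are
#' treated per mode: `"within_trial"` — LAT, DUR, FRQ, DUR/FRQ, distance and
#' velocity all set missing; `"between_trial"` (paired trial comparisons) —
#' DUR and FRQ set to 0, LAT set to the session duration, DUR/FRQ and
#' velocity missing.  DUR/FRQ is always missing when FRQ = 0, and index
#' columns are left as computed (absent values already propagate as missing).
#' The operation is idempotent.
#'
#' @param tab An `mcsf_parameter_table`.
#' @param mode `"within_trial"` or `"between_trial"`.
#' @param session_duration Imputation value for latencies (s); defaults to
#'   the table's recorded session duration.
#' @return The table with the rules applied; attribute `missing_mode` set.
#' @export
apply_missing_rules <- function(tab, mode = c("within_trial", "between_trial"),
                                session_duration = attr(tab, "session_duration")) {
  mode <- match.arg(mode)
  zones <- attr(tab, "zones")
  if (is.null(zones)) {
    zones <- sub("^FRQ_", "", grep("^FRQ_", names(tab), value = TRUE))
  }
  units <- c(zones, intersect(c("total_corr", "arena"), sub("^FRQ_", "",
             grep("^FRQ_", names(tab), value = TRUE))))
  for (z in unique(units)) {
    frq_col <- paste0("FRQ_", z)
    if (!frq_col %in% names(tab)) next
    frq <- tab[[frq_col]]
    unvisited <- !is.na(frq) & frq == 0
    for (col in paste0(c("DURFRQ_", "VEL_"), z)) {
      if (col %in% names(tab)) tab[[col]][unvisited] <- NA_real_
    }
    if (mode == "within_trial") {
      for (col in paste0(c("LAT_", "FRQ_", "DUR_", "DIST_"), z)) {
        if (col %in% names(tab)) tab[[col]][unvisited] <- NA_real_
      }
    } else {
      lat_col <- paste0("LAT_", z)
      if (lat_col %in% names(tab)) tab[[lat_col]][unvisited] <- session_duration
      # DUR and FRQ stay 0 for unvisited zones in between-trial mode
    }
  }
  attr(tab, "missing_mode") <- mode
  tab
}

#' Per-group occurrence counts for a parameter
#'
#' Occurrence is the number of rats in each group with a positive value of a
#' count-type parameter (zone visit frequency or behavior count), reported
#' with the group size — the 2x2-ready input to [occurrence_test()].
#'
#' @param tab An `mcsf_parameter_table` (or any data.frame with `group`).
#' @param parameter Column name of a count or frequency parameter.
#' @param trial Optional trial label to restrict to.
#' @return Data.frame with columns `group`, `occurrence`, `n`.
#' @export
compute_occurrence <- function(tab, parameter, trial = NULL) {
  if (!parameter %in% names(tab)) {
    stop("usage error: unknown parameter '", parameter, "'")
  }
  if (!is.null(trial)) tab <- tab[tab$trial == as.character(trial), , drop = FALSE]
  groups <- unique(tab$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- tab[[parameter]][tab$group == g]
    data.frame(group = g,
               occurrence = sum(!is.na(v) & v > 0),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-time-bin activity measures from a visit log
#'
#' Counts visits and sums distance per 10-min (or custom) bin for every
#' rat-trial, assigning each visit to the bin of its entry time — the input
#' to intra-trial time-course tests ([timecourse_test()]).
#'
#' @param visits An `mcsf_visits` data.frame.
#' @param session_duration Session length (s).
#' @param bin_width Bin width (s), default 600.
#' @return Data.frame with `rat_id`, `group`, `trial`, `bin`, `n_visits`,
#'   `distance`.
#' @export
bin_visit_measures <- function(visits, session_duration = 1800,
                               bin_width = 600) {
  n_bins <- max(1L, ceiling(session_duration / bin_width - 1e-12))
  bin <- pmin(floor(visits$t_enter / bin_width) + 1L, n_bins)
  key <- interaction(visits$rat_id, visits$trial, drop = TRUE,
                     lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(visits)), key), function(idx) {
    bf <- factor(bin[idx], levels = seq_len(n_bins))
    dist <- as.numeric(tapply(visits$distance[idx], bf, sum))
    dist[is.na(dist)] <- 0
    data.frame(rat_id = visits$rat_id[idx[1]], group = visits$group[idx[1]],
               trial = visits$trial[idx[1]], bin = seq_len(n_bins),
               n_visits = as.integer(table(bf)), distance = dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a parameter table to a delimited file
#' @param tab An `mcsf_parameter_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
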