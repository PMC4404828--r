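#' Construct a track object from time-stamped coordinates
#'
#' A track is one rat-trial's positional record: strictly increasing time
#' stamps plus x/y coordinates in cm (NA coordinates mark missing frames).
#'
#' @param t Numeric vector of times (s), strictly increasing, first >= 0.
#' @param x,y Numeric coordinate vectors (cm); NA marks a missing frame.
#' @param rat_id,group,trial Identifying labels.
#' @param frame_rate Nominal frame rate (Hz); inferred from the median time
#'   step when NULL.
#' @param session_duration Session length (s); defaults to the last time stamp.
#' @return A data.frame of class `mcsf_track` with columns `t`, `x`, `y` and
#'   attributes `rat_id`, `group`, `trial`, `frame_rate`, `session_duration`.
#' @export
track <- function(t, x, y, rat_id = "rat", group = "group", trial = "1",
                  frame_rate = NULL, session_duration = NULL) {
  n <- length(t)
  if (n == 0L) stop("track data error: no samples")
  if (length(x) != n || length(y) != n) {
    stop("track data error: t, x, y lengths differ")
  }
  if (any(!is.finite(t))) stop("track data error: non-finite time stamp")
  if (n > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop("track data error: non-monotonic time stamps, first at row ",
           bad[1] + 1L)
    }
  }
  if (t[1] < 0) stop("track data error: first time stamp < 0")
  if (is.null(frame_rate)) {
    frame_rate <- if (n > 1L) 1 / stats::median(diff(t)) else 1
  }
  if (is.null(session_duration)) session_duration <- t[n]
  if (t[n] > session_duration + 1e-9) {
    stop("track data error: last time stamp exceeds session_duration")
  }
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  structure(out,
            rat_id = rat_id, group = group, trial = as.character(trial),
            frame_rate = frame_rate, session_duration = session_duration,
            class = c("mcsf_track", "data.frame"))
}

#' Read a tracking log file
#'
#' Supported dialects: `"simple_csv"` — comma/whitespace-delimited columns
#' `time_s, x_cm, y_cm` (extra columns ignored, one optional header row);
#' `"ethovision_like"` — additionally tolerates a header preamble (lines
#' before the first data row) and locale decimal commas.
#'
#' @param path File path.
#' @param dialect `"simple_csv"` or `"ethovision_like"`.
#' @inheritParams track
#' @return An `mcsf_track`.
#' @export
read_track <- function(path, dialect = c("simple_csv", "ethovision_like"),
                       rat_id = "rat", group = "group", trial = "1",
                       frame_rate = NULL, session_duration = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("track data error: empty file ", path)
  if (dialect == "ethovision_like") {
    # decimal commas: "1,5" -> "1.5" (only when comma sits between digits and
    # the field separator is ';' or tab or the line has paired quotes)
    lines <- gsub("(?<=[0-9]),(?=[0-9])", ".", lines, perl = TRUE)
  }
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[;,\t ]+")[[1]]
    suppressWarnings(as.numeric(fields[seq_len(min(3, length(fields)))]))
  }
  parsed <- lapply(lines, parse_row)
  is_data <- vapply(parsed, function(p) length(p) >= 3 && is.finite(p[1]), TRUE)
  if (dialect == "simple_csv") {
    # allow at most one header line
    first_data <- which(is_data)[1]
    if (is.na(first_data) || first_data > 2) {
      stop("track data error: no parseable data rows in ", path)
    }
    keep <- seq(first_data, length(parsed))
  } else {
    first_data <- which(is_data)[1]
    if (is.na(first_data)) stop("track data error: no parseable data rows in ", path)
    keep <- seq(first_data, length(parsed))
  }
  m <- do.call(rbind, parsed[keep])
  if (any(!is.finite(m[, 1]))) {
    stop("track data error: unparseable time stamp at data row ",
         which(!is.finite(m[, 1]))[1])
  }
  track(m[, 1], m[, 2], m[, 3], rat_id = rat_id, group = group, trial = trial,
        frame_rate = frame_rate, session_duration = session_duration)
}

#' Extract zone-visit events from a track
#'
#' Assigns every sample to a zone with [locate_zones()] and partitions the
#' located time into maximal runs of constant zone assignment.  Each
#' inter-sample interval is credited to the zone of the interval's first
#' sample; intervals starting at a missing frame count as missing time, and
#' `"unassigned"` runs never form visits.  Runs shorter than
#' `min_visit_duration` are merged into the surrounding visit of the previous
#' zone.  A missing-frame gap breaks a visit only when the gap exceeds
#' `min(2 s, 5 / frame_rate)`; otherwise the visit continues across it (the
#' gap's time still counts as missing, not visit, time).
#'
#' Per-visit distance is the summed Euclidean step length over steps whose
#' first sample lies in the visit; steps adjacent to a missing frame
#' contribute nothing.
#'
#' @param trk An `mcsf_track`.
#' @param arena An `mcsf_arena`.
#' @param min_visit_duration Minimum run duration (s) to stand as its own
#'   visit; default 0 (no smoothing).
#' @return A data.frame of class `mcsf_visits` with columns `rat_id`,
#'   `group`, `trial`, `zone_id`, `t_enter`, `t_exit`, `duration` (occupied
#'   time, s) and `distance` (cm), plus attribute `occupancy` holding the
#'   unassigned/missing time bookkeeping.
#' @export
extract_visits <- function(trk, arena, min_visit_duration = 0) {
  stopifnot(inherits(trk, "mcsf_track"), min_visit_duration >= 0)
  n <- nrow(trk)
  zone <- locate_zones(trk$x, trk$y, arena)
  missing <- !is.finite(trk$x) | !is.finite(trk$y)
  zone[missing] <- NA_character_
  if (all(is.na(zone) | zone == "unassigned")) {
    stop("track data error: zero located samples for rat '",
         attr(trk, "rat_id"), "'")
  }
  t <- trk$t
  dt <- c(diff(t), 0)                 # interval credited to sample i
  step <- c(sqrt(diff(trk$x)^2 + diff(trk$y)^2), 0)
  step[is.na(step)] <- 0

  gap_max <- min(2, 5 / attr(trk, "frame_rate"))

  # runs over located samples; break on zone change or oversized gap
  loc <- which(!is.na(zone))
  zl <- zone[loc]
  gap_break <- c(FALSE, diff(t[loc]) > gap_max + 1e-12)
  new_run <- c(TRUE, zl[-1] != zl[-length(zl)]) | gap_break
  run_id <- cumsum(new_run)
  runs <- data.frame(
    zone = zl[new_run],
    first = loc[new_run],
    last = loc[c(new_run[-1], TRUE)],
    stringsAsFactors = FALSE
  )
  # occupied time and distance per run: sum over located samples in the run,
  # excluding each run's final interval when the next sample starts a new run
  # elsewhere -- credit rule: interval/step belongs to the zone of its first
  # sample, so intervals from a run's samples up to (not including) the next
  # run's first sample belong to the run, except those starting at missing
  # samples.
  occ <- numeric(nrow(runs)); dist <- numeric(nrow(runs))
  t_enter <- t[runs$first]
  t_exit <- numeric(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    i0 <- runs$first[r]
    i1 <- if (r < nrow(runs)) runs$first[r + 1] - 1L else n
    located <- (i0:i1)[!is.na(zone[i0:i1])]
    occ[r] <- sum(dt[located])     # dt[n] is 0, so the final sample adds nothing
    dist[r] <- sum(step[located])  # step is 0 for NA-adjacent steps and at n
    t_exit[r] <- if (r < nrow(runs)) t[runs$first[r + 1]] else t[runs$last[r]]
  }
  runs$t_enter <- t_enter; runs$t_exit <- t_exit
  runs$duration <- occ; runs$distance <- dist

  # a zone entered only at the final frame has no measurable time: no visit
  drop0 <- runs$duration <= 0 & runs$zone != "unassigned"
  runs <- runs[!drop0, , drop = FALSE]

  # smoothing: zoned runs shorter than min_visit_duration are relabelled to
  # the previous zoned run's zone ("unassigned" runs never absorb or form)
  runs$relabeled <- FALSE
  if (min_visit_duration > 0) {
    zoned <- which(runs$zone != "unassigned")
    prev_zone <- NA_character_
    for (k in zoned) {
      if (runs$duration[k] < min_visit_duration && !is.na(prev_zone)) {
        runs$zone[k] <- prev_zone
        runs$relabeled[k] <- TRUE
      }
      prev_zone <- runs$zone[k]
    }
  }
  # coalesce same-zone zoned runs made adjacent by the relabelling above;
  # runs split by an oversized gap (not relabelled) stay separate visits
  keep <- runs$zone != "unassigned"
  vr <- runs[keep, , drop = FALSE]
  if (nrow(vr)) {
    same <- c(FALSE, vr$zone[-1] == vr$zone[-nrow(vr)] &
                diff(which(keep)) == 1L &
                (vr$relabeled[-1] | vr$relabeled[-nrow(vr)]))
    vid <- cumsum(!same)
    vr <- data.frame(
      zone_id = vr$zone[!same],
      t_enter = vr$t_enter[!same],
      t_exit = as.numeric(tapply(vr$t_exit, vid, function(v) v[length(v)])),
      duration = as.numeric(tapply(vr$duration, vid, sum)),
      distance = as.numeric(tapply(vr$distance, vid, sum)),
      stringsAsFactors = FALSE
    )
  } else {
    vr <- data.frame(zone_id = character(), t_enter = numeric(),
                     t_exit = numeric(), duration = numeric(),
                     distance = numeric(), stringsAsFactors = FALSE)
  }
  out <- data.frame(
    rat_id = attr(trk, "rat_id"), group = attr(trk, "group"),
    trial = attr(trk, "trial"), vr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  total <- t[n] - t[1]
  missing_time <- sum(dt[seq_len(n - 1)][is.na(zone[seq_len(max(0, n - 1))])])
  unassigned_time <- sum(dt[seq_len(n - 1)][!is.na(zone[seq_len(max(0, n - 1))]) &
                                              zone[seq_len(max(0, n - 1))] == "unassigned"])
  structure(out,
            occupancy = list(total_time = total,
                             visit_time = sum(out$duration),
                             unassigned_time = unassigned_time,
                             missing_time = missing_time),
            session_duration = attr(trk, "session_duration"),
            class = c("mcsf_visits", "data.frame"))
}

#' Split a track into fixed-width time bins
#'
#' Bins are contiguous half-open segments `[k*w, (k+1)*w)` covering
#' `[0, session_duration)`; a sample whose time falls exactly on a boundary
#' goes to the later bin.
#'
#' @param trk An `mcsf_track`.
#' @param bin_width Bin width (s), > 0.
#' @return A list of `mcsf_track` segments (possibly with zero rows), one per
#'   bin, each carrying a `bin` attribute (1-based).
#' @export
bin_track <- function(trk, bin_width) {
  stopifnot(inherits(trk, "mcsf_track"), bin_width > 0)
  dur <- attr(trk, "session_duration")
  n_bins <- max(1L, ceiling(dur / bin_width - 1e-12))
  bin <- pmin(floor(trk$t / bin_width) + 1L, n_bins)
  lapply(seq_len(n_bins), function(b) {
    seg <- trk[bin == b, , drop = FALSE]
    structure(seg,
              rat_id = attr(trk, "rat_id"), group = attr(trk, "group"),
              trial = attr(trk, "trial"),
              frame_rate = attr(trk, "frame_rate"),
              session_duration = dur, bin = b,
              class = c("mcsf_track", "data.frame"))
  })
}

#' Read or write a canonical zone-visit log
#'
#' The visit log is the alternative direct input to the pipeline: one row
#' per visit with columns `rat_id, group, trial, zone_id, t_enter, t_exit,
#' duration, distance` (`duration` defaults to `t_exit - t_enter` if absent).
#'
#' @param path CSV file path.
#' @return `read_visit_log`: an `mcsf_visits` data.frame.
#' @export
read_visit_log <- function(path) {
  if (!file.exists(path)) stop("visit log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rat_id", "group", "trial", "zone_id", "t_enter", "t_exit")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("visit log data error: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (is.null(df$duration)) df$duration <- df$t_exit - df$t_enter
  if (is.null(df$distance)) df$distance <- NA_real_
  bad <- which(df$t_exit <= df$t_enter)
  if (length(bad)) {
    stop("visit log data error: t_exit <= t_enter at row ", bad[1])
  }
  df$trial <- as.character(df$trial)
  structure(df, class = c("mcsf_visits", "data.frame"))
}

#' @rdname read_visit_log
#' @param visits An `mcsf_visits` data.frame.
#' @return `write_visit_log`: `path`, invisibly.
#' @export
write_visit_log <- function(visits, path) {
  utils::write.csv(as.data.frame(visits)[, c("rat_id", "group", "trial",
                                             "zone_id", "t_enter", "t_exit",
                                             "duration", "distance")],
                   path, row.names = FALSE)
  invisible(path)
}
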