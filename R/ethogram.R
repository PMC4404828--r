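#' Ethogram definitions
#'
#' An ethogram maps behavior names to functional categories — coping styles
#' (proactive, reactive, exploratory, locomotor) for the novel cage test;
#' social-behavior classes (neutral, dominant, aggressive, submissive) for
#' the home cage change test — plus standalone behaviors (burrowing) that
#' are reported raw and excluded from relative-measure denominators.
#'
#' @param path YAML ethogram file.
#' @param test `"novel_cage"` or `"home_cage_change"` for the bundled
#'   defaults.
#' @return A list of class `mcsf_ethogram` with elements `test_type`,
#'   `session_duration`, `categories` (named list of data.frames
#'   behavior/description) and `standalone` (character vector).
#' @export
load_ethogram <- function(path) {
  if (!file.exists(path)) stop("ethogram file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories)) {
    stop("ethogram format error: missing key 'categories'")
  }
  categories <- lapply(raw$categories, function(entries) {
    do.call(rbind, lapply(entries, function(e) {
      data.frame(behavior = as.character(e$behavior),
                 description = if (is.null(e$description)) "" else e$description,
                 stringsAsFactors = FALSE)
    }))
  })
  standalone <- vapply(raw$standalone, function(e) as.character(e$behavior), "")
  all_b <- c(unlist(lapply(categories, `[[`, "behavior")), standalone)
  if (anyDuplicated(all_b)) {
    stop("ethogram validation error: behavior(s) mapped more than once: ",
         paste(unique(all_b[duplicated(all_b)]), collapse = ", "))
  }
  structure(list(
    test_type = raw$test_type,
    session_duration = as.numeric(raw$session_duration),
    categories = categories,
    standalone = standalone
  ), class = "mcsf_ethogram")
}

#' @rdname load_ethogram
#' @export
ethogram_default <- function(test = c("novel_cage", "home_cage_change")) {
  test <- match.arg(test)
  file <- switch(test, novel_cage = "ethogram_novel_cage.yaml",
                 home_cage_change = "ethogram_home_cage.yaml")
  load_ethogram(system.file("extdata", file, package = "mcsfr",
                            mustWork = TRUE))
}

ethogram_behaviors <- function(def) {
  c(unlist(lapply(def$categories, `[[`, "behavior"), use.names = FALSE),
    def$standalone)
}

behavior_category <- function(def, behavior) {
  for (cat in names(def$categories)) {
    if (behavior %in% def$categories[[cat]]$behavior) return(cat)
  }
  NA_character_
}

#' Construct or read a behavior bout log
#'
#' A bout log holds one rat's manually scored behavior bouts for a session:
#' `(behavior, t_start, t_stop)` with `t_stop >= t_start` (point events are
#' allowed with zero duration).  Overlapping bouts are permitted — two
#' behaviors can co-occur — but are flagged in the `overlaps` attribute.
#'
#' @param behavior Character vector of behavior labels.
#' @param t_start,t_stop Numeric bout boundaries (s).
#' @param rat_id,group Identifying labels.
#' @param partner_id Cage-mate id (home cage test), or NA.
#' @param def Optional `mcsf_ethogram` to validate behavior labels against.
#' @return A data.frame of class `mcsf_bout_log`.
#' @export
bout_log <- function(behavior, t_start, t_stop, rat_id = "rat",
                     group = "group", partner_id = NA_character_,
                     def = NULL) {
  n <- length(behavior)
  if (n == 0L) stop("degenerate input: empty bout log")
  if (length(t_start) != n || length(t_stop) != n) {
    stop("bout log data error: column lengths differ")
  }
  bad <- which(t_stop < t_start)
  if (length(bad)) {
    stop("bout log data error: t_stop < t_start at row ", bad[1])
  }
  if (!is.null(def)) {
    unknown <- setdiff(unique(behavior), ethogram_behaviors(def))
    if (length(unknown)) {
      stop("bout log data error: behavior(s) not in ethogram: ",
           paste(unknown, collapse = ", "))
    }
    if (is.finite(def$session_duration) &&
        any(t_stop > def$session_duration + 1e-9)) {
      stop("bout log data error: bout extends past session duration")
    }
  }
  o <- order(t_start, t_stop)
  df <- data.frame(behavior = behavior[o], t_start = t_start[o],
                   t_stop = t_stop[o], stringsAsFactors = FALSE)
  overlaps <- nrow(df) > 1 &&
    any(df$t_start[-1] < cummax(df$t_stop[-nrow(df)]) - 1e-12)
  structure(df, rat_id = rat_id, group = group, partner_id = partner_id,
            overlaps = overlaps,
            class = c("mcsf_bout_log", "data.frame"))
}

#' @rdname bout_log
#' @param path CSV with columns `rat_id, session, behavior, t_start_s,
#'   t_stop_s` (single rat per file; extra columns ignored).
#' @export
read_bout_log <- function(path, def = NULL) {
  if (!file.exists(path)) stop("bout log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("degenerate input: empty bout log file ", path)
  cols <- c(behavior = "behavior", t_start = "t_start_s", t_stop = "t_stop_s")
  miss <- setdiff(unname(cols), names(df))
  if (length(miss)) {
    stop("bout log data error: missing column(s) ", paste(miss, collapse = ", "))
  }
  bout_log(df$behavior, df$t_start_s, df$t_stop_s,
           rat_id = if ("rat_id" %in% names(df)) df$rat_id[1] else "rat",
           group = if ("group" %in% names(df)) df$group[1] else "group",
           def = def)
}

#' Relative frequency and duration per behavior
#'
#' `rel_freq(b) = count(b) / total categorized bouts` and
#' `rel_dur(b) = duration(b) / total categorized duration`, computed as
#' fractions of the total behavior scored for the rat.  Standalone behaviors
#' (burrowing) are excluded from both denominators and reported raw.
#'
#' @param log An `mcsf_bout_log`.
#' @param def An `mcsf_ethogram`.
#' @return Data.frame with one row per ethogram behavior: `behavior`,
#'   `category` (NA for standalone), `n_bouts`, `duration`, `rel_freq`,
#'   `rel_dur` (NA for standalone behaviors).
#' @export
relative_behavior_measures <- function(log, def) {
  behaviors <- ethogram_behaviors(def)
  unknown <- setdiff(unique(log$behavior), behaviors)
  if (length(unknown)) {
    stop("bout log data error: behavior(s) not in ethogram: ",
         paste(unknown, collapse = ", "))
  }
  bf <- factor(log$behavior, levels = behaviors)
  n_bouts <- as.integer(table(bf))
  dur <- as.numeric(tapply(log$t_stop - log$t_start, bf, sum))
  dur[is.na(dur)] <- 0
  category <- vapply(behaviors, behavior_category, "", def = def)
  categorized <- !is.na(category) & category != ""
  categorized[behaviors %in% def$standalone] <- FALSE
  total_bouts <- sum(n_bouts[categorized])
  total_dur <- sum(dur[categorized])
  if (total_bouts == 0L) {
    stop("degenerate input: zero categorized bouts in log for rat '",
         attr(log, "rat_id"), "'")
  }
  rel_freq <- ifelse(categorized, n_bouts / total_bouts, NA_real_)
  rel_dur <- if (total_dur > 0) {
    ifelse(categorized, dur / total_dur, NA_real_)
  } else NA_real_
  out <- data.frame(behavior = behaviors, category = category,
                    n_bouts = n_bouts, duration = dur,
                    rel_freq = rel_freq, rel_dur = rel_dur,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, rat_id = attr(log, "rat_id"), group = attr(log, "group"),
            class = c("mcsf_behavior_measures", "data.frame"))
}

#' Functional-category scores from a bout log
#'
#' The score for a category is the sum of its member behaviors' relative
#' frequencies (frequency variant) or relative durations (duration variant).
#' On an all-categorized log each variant sums to exactly 1 over categories.
#' Standalone behaviors are returned raw (bouts and seconds).
#'
#' @inheritParams relative_behavior_measures
#' @return A list of class `mcsf_category_scores` with data.frame `scores`
#'   (`category`, `rel_freq_score`, `rel_dur_score`) and data.frame
#'   `standalone` (`behavior`, `n_bouts`, `duration`).
#' @export
category_scores <- function(log, def) {
  meas <- relative_behavior_measures(log, def)
  cats <- names(def$categories)
  scores <- do.call(rbind, lapply(cats, function(cat) {
    m <- meas[meas$category %in% cat & !meas$behavior %in% def$standalone, ]
    data.frame(category = cat,
               rel_freq_score = sum(m$rel_freq),
               rel_dur_score = if (all(is.na(m$rel_dur))) NA_real_ else
                 sum(m$rel_dur, na.rm = FALSE),
               stringsAsFactors = FALSE)
  }))
  standalone <- meas[meas$behavior %in% def$standalone,
                     c("behavior", "n_bouts", "duration")]
  rownames(scores) <- rownames(standalone) <- NULL
  structure(list(scores = scores, standalone = standalone,
                 rat_id = attr(log, "rat_id"), group = attr(log, "group")),
            class = "mcsf_category_scores")
}

#' Category-score table for a cohort of bout logs
#'
#' Applies [category_scores()] to each log and assembles a wide table, one
#' row per rat: `<category>_freq`, `<category>_dur` columns plus raw
#' `<standalone>_bouts` / `<standalone>_dur` columns.
#'
#' @param logs List of `mcsf_bout_log` objects.
#' @param def An `mcsf_ethogram`.
#' @return Data.frame with `rat_id`, `group` and score columns.
#' @export
category_score_table <- function(logs, def) {
  rows <- lapply(logs, function(log) {
    cs <- category_scores(log, def)
    vals <- c(
      stats::setNames(cs$scores$rel_freq_score,
                      paste0(cs$scores$category, "_freq")),
      stats::setNames(cs$scores$rel_dur_score,
                      paste0(cs$scores$category, "_dur")))
    if (nrow(cs$standalone)) {
      vals <- c(vals,
                stats::setNames(cs$standalone$n_bouts,
                                paste0(cs$standalone$behavior, "_bouts")),
                stats::setNames(cs$standalone$duration,
                                paste0(cs$standalone$behavior, "_dur")))
    }
    data.frame(rat_id = attr(log, "rat_id"), group = attr(log, "group"),
               as.list(vals), check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
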