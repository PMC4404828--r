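#' Functional-category maps for trend analysis
#'
#' A category map assigns parameter-table columns to functional categories
#' (general activity, exploratory activity, shelter seeking, risk
#' assessment, risk taking), each entry carrying an explicit `inverse` flag:
#' inverted parameters (e.g. duration per visit in the corridors, where a
#' short stay indicates high activity) are reversed before ranking.
#'
#' `trend_categories_default()` returns the bundled standard map;
#' `load_category_map()` reads one from YAML
#' (`category: [{parameter: ..., inverse: ...}, ...]`).
#'
#' @param path YAML file path.
#' @return A named list (category -> data.frame with columns `parameter`,
#'   `inverse`), class `mcsf_category_map`.
#' @export
load_category_map <- function(path) {
  if (!file.exists(path)) stop("category map file not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(entries) {
    df <- do.call(rbind, lapply(entries, function(e) {
      if (is.null(e$parameter) || is.null(e$inverse)) {
        stop("category map format error: every entry needs keys ",
             "'parameter' and 'inverse'")
      }
      data.frame(parameter = as.character(e$parameter),
                 inverse = as.logical(e$inverse), stringsAsFactors = FALSE)
    }))
    df
  })
  structure(out, class = "mcsf_category_map")
}

#' @rdname load_category_map
#' @export
trend_categories_default <- function() {
  load_category_map(system.file("extdata", "trend_categories_default.yaml",
                                package = "mcsfr", mustWork = TRUE))
}

#' Rank one parameter across rats (and trials)
#'
#' Ascending mid-ranks over the pooled non-missing values: the largest raw
#' value receives the largest rank, ties receive their mid-rank, and missing
#' entries receive a missing rank.  With `inverse = TRUE` the order is
#' reversed before ranking, so a low raw value earns a high rank.
#'
#' @param values Numeric vector (may contain NA).
#' @param inverse Reverse the ranking direction?
#' @return Numeric vector of ranks, NA where `values` is NA.  For each
#'   parameter the non-missing ranks sum to `m(m+1)/2` (m = number ranked),
#'   a sum preserved by mid-rank ties.
#' @export
rank_parameter <- function(values, inverse = FALSE) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop("degenerate input: rank_parameter needs >= 2 non-missing values")
  }
  v <- if (inverse) -values[ok] else values[ok]
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(v, ties.method = "average")
  out
}

#' Functional-category trend scores
#'
#' Rats are ranked across experimental groups and trials for each mapped
#' parameter ([rank_parameter()]), and the ranks within each functional
#' category are summed per rat-trial.  A missing rank contributes the
#' parameter's pooled mid-rank `(m + 1) / 2` under the default
#' `missing = "midrank"` policy (keeping scores comparable across rats with
#' different missingness); `missing = "listwise"` leaves the category score
#' missing instead.
#'
#' @param tab An `mcsf_parameter_table`.
#' @param map An `mcsf_category_map` (default: bundled standard map).
#' @param missing `"midrank"` or `"listwise"`.
#' @param pooling `"pooled"` ranks all trials together (the default,
#'   matching a joint group-and-trial ranking); `"per_trial"` ranks each
#'   trial separately.
#' @return A data.frame of class `mcsf_trend_scores`: `rat_id`, `group`,
#'   `trial`, `category`, `score`, `n_ranked`.
#' @export
trend_scores <- function(tab, map = trend_categories_default(),
                         missing = c("midrank", "listwise"),
                         pooling = c("pooled", "per_trial")) {
  missing <- match.arg(missing)
  pooling <- match.arg(pooling)
  all_params <- unique(unlist(lapply(map, `[[`, "parameter")))
  absent <- setdiff(all_params, names(tab))
  if (length(absent)) {
    stop("usage error: unmapped parameter(s) not in table: ",
         paste(absent, collapse = ", "))
  }
  strata <- if (pooling == "pooled") rep(1L, nrow(tab)) else
    as.integer(factor(tab$trial))
  rank_col <- function(param, inverse) {
    out <- rep(NA_real_, nrow(tab))
    for (s in unique(strata)) {
      i <- strata == s
      r <- rank_parameter(tab[[param]][i], inverse)
      if (missing == "midrank") {
        m <- sum(!is.na(r))
        r[is.na(r)] <- (m + 1) / 2
      }
      out[i] <- r
    }
    out
  }
  res <- lapply(names(map), function(cat) {
    entries <- map[[cat]]
    rank_mat <- mapply(rank_col, entries$parameter, entries$inverse)
    score <- rowSums(rank_mat)
    data.frame(rat_id = tab$rat_id, group = tab$group, trial = tab$trial,
               category = cat, score = score,
               n_ranked = rowSums(!is.na(rank_mat)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("mcsf_trend_scores", "data.frame")
  out
}

#' Group and trial tests on trend-analysis category scores
#'
#' Per category: an unpaired two-sample t-test between groups within each
#' trial; and, when two trials are present, a two-way repeated-measures
#' ANOVA (group x trial with rat as the repeated unit) reporting the group
#' main effect, trial main effect and interaction, followed by
#' Bonferroni-adjusted within-group paired trial contrasts.  Rats missing a
#' trial are excluded listwise from the repeated-measures part, with a
#' warning.
#'
#' @param scores An `mcsf_trend_scores` data.frame (two groups).
#' @return A data.frame of class `mcsf_trend_tests`: one row per category
#'   and effect (`t_trial_<k>`, `anova_group`, `anova_trial`,
#'   `anova_interaction`, `posthoc_trial_in_<group>`), with `statistic`,
#'   `df1`, `df2`, `p`, `p_adj`, `label`.
#' @export
trend_tests <- function(scores) {
  groups <- unique(scores$group)
  if (length(groups) != 2L) {
    stop("usage error: trend_tests expects exactly two groups")
  }
  trials <- sort(unique(scores$trial))
  rows <- list()
  add <- function(category, effect, statistic, df1, df2, p, p_adj = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, effect = effect, statistic = statistic,
      df1 = df1, df2 = df2, p = p, p_adj = p_adj,
      label = significance_label(if (is.na(p_adj)) p else p_adj),
      stringsAsFactors = FALSE)
  }
  for (cat in unique(scores$category)) {
    sc <- scores[scores$category == cat, , drop = FALSE]
    for (tr in trials) {
      a <- sc$score[sc$trial == tr & sc$group == groups[1]]
      b <- sc$score[sc$trial == tr & sc$group == groups[2]]
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        if (stats::sd(c(a, b), na.rm = TRUE) == 0) {
          add(cat, paste0("t_trial_", tr), 0, NA, length(c(a, b)) - 2, 1)
        } else {
          tt <- stats::t.test(a, b, var.equal = TRUE)
          add(cat, paste0("t_trial_", tr), unname(tt$statistic), NA,
              unname(tt$parameter), tt$p.value)
        }
      }
    }
    if (length(trials) == 2L) {
      wide <- merge(
        sc[sc$trial == trials[1], c("rat_id", "group", "score")],
        sc[sc$trial == trials[2], c("rat_id", "score")],
        by = "rat_id", suffixes = c("_1", "_2"), all = TRUE)
      complete <- stats::complete.cases(wide[, c("score_1", "score_2")])
      if (any(!complete)) {
        warning("trend_tests: ", sum(!complete),
                " rat(s) missing a trial excluded listwise")
        wide <- wide[complete, , drop = FALSE]
      }
      if (nrow(wide) >= 4L && length(unique(wide$group)) == 2L) {
        long <- data.frame(
          rat_id = factor(rep(wide$rat_id, 2)),
          group = factor(rep(wide$group, 2)),
          trial = factor(rep(trials, each = nrow(wide))),
          score = c(wide$score_1, wide$score_2))
        fit <- stats::aov(score ~ group * trial + Error(rat_id/trial),
                          data = long)
        s <- summary(fit)
        between <- s[["Error: rat_id"]][[1]]
        within <- s[["Error: rat_id:trial"]][[1]]
        grab <- function(stratum, term) {
          i <- match(term, trimws(rownames(stratum)))
          resid <- nrow(stratum)
          c(stratum[i, "F value"], stratum[i, "Df"], stratum[resid, "Df"],
            stratum[i, "Pr(>F)"])
        }
        gg <- grab(between, "group")
        add(cat, "anova_group", gg[1], gg[2], gg[3], gg[4])
        tt <- grab(within, "trial")
        add(cat, "anova_trial", tt[1], tt[2], tt[3], tt[4])
        ii <- grab(within, "group:trial")
        add(cat, "anova_interaction", ii[1], ii[2], ii[3], ii[4])
        for (g in groups) {
          w <- wide[wide$group == g, , drop = FALSE]
          d <- w$score_2 - w$score_1
          if (length(d) >= 2 && stats::sd(d) > 0) {
            pt <- stats::t.test(w$score_2, w$score_1, paired = TRUE)
            add(cat, paste0("posthoc_trial_in_", g), unname(pt$statistic),
                NA, unname(pt$parameter), pt$p.value,
                min(1, pt$p.value * length(groups)))
          } else if (length(d) >= 2) {
            add(cat, paste0("posthoc_trial_in_", g), 0, NA, length(d) - 1,
                1, 1)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mcsf_trend_tests", "data.frame")
  out
}
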