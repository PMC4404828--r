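#' Significance labelling
#'
#' Differences are labelled `significant` at `p <= 0.05`, `trend` for
#' `0.05 < p <= 0.1`, `ns` otherwise (boundary values inclusive).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.05, "significant",
                ifelse(p <= 0.1, "trend", "ns")))
}

test_result <- function(test, parameter, statistic, df, p, p_adj = NA_real_,
                        note = NA_character_) {
  structure(
    data.frame(test = test, parameter = parameter,
               statistic = statistic, df = df, p = p, p_adj = p_adj,
               label = significance_label(ifelse(is.na(p_adj), p, p_adj)),
               note = note, stringsAsFactors = FALSE),
    class = c("mcsf_test_result", "data.frame"))
}

# exact when both groups small and tie-free, else tie-corrected normal
# approximation (Mann-Whitney / Wilcoxon signed rank)
use_exact <- function(x, y = NULL, limit = 12L) {
  vals <- c(x, y)
  length(x) <= limit && (is.null(y) || length(y) <= limit) &&
    !anyDuplicated(vals)
}

#' Mann-Whitney U comparison between the two experimental groups
#'
#' Two-sided Mann-Whitney U-test on one parameter, exact when both groups
#' have <= 12 observations and no ties, otherwise the tie-corrected normal
#' approximation.  Missing cells are excluded.
#'
#' @param tab An `mcsf_parameter_table` (two groups).
#' @param parameter Column name.
#' @param trial Optional trial label to restrict to.
#' @return An `mcsf_test_result` row.
#' @export
group_compare <- function(tab, parameter, trial = NULL) {
  if (!parameter %in% names(tab)) {
    stop("usage error: unknown parameter '", parameter, "'")
  }
  if (!is.null(trial)) tab <- tab[tab$trial == as.character(trial), , drop = FALSE]
  groups <- unique(tab$group)
  if (length(groups) != 2L) stop("usage error: need exactly two groups")
  x <- tab[[parameter]][tab$group == groups[1]]
  y <- tab[[parameter]][tab$group == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("degenerate input: fewer than 2 non-missing values in a group for '",
         parameter, "'")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact(x, y), correct = TRUE))
  test_result("mann_whitney", parameter, unname(wt$statistic), NA_real_,
              wt$p.value)
}

#' Wilcoxon matched-pairs comparison between trials within a group
#'
#' Two-sided Wilcoxon signed-rank test on paired trial-1/trial-2 values.
#' Pairs with either value missing are excluded; zero differences are
#' dropped before ranking (standard convention), and when every difference
#' is zero the result is p = 1 by convention.  Apply the between-trial
#' missing rules upstream so unvisited-zone latencies participate as real
#' imputed pairs.
#'
#' @param tab An `mcsf_parameter_table` with two trials.
#' @param parameter Column name.
#' @param group Optional group label to restrict to.
#' @return An `mcsf_test_result` row.
#' @export
trial_compare <- function(tab, parameter, group = NULL) {
  if (!parameter %in% names(tab)) {
    stop("usage error: unknown parameter '", parameter, "'")
  }
  if (!is.null(group)) tab <- tab[tab$group == group, , drop = FALSE]
  trials <- sort(unique(tab$trial))
  if (length(trials) != 2L) stop("usage error: need exactly two trials")
  t1 <- tab[tab$trial == trials[1], c("rat_id", parameter)]
  t2 <- tab[tab$trial == trials[2], c("rat_id", parameter)]
  m <- merge(t1, t2, by = "rat_id", suffixes = c("_1", "_2"))
  x <- m[[2]]; y <- m[[3]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    stop("degenerate input: fewer than 2 usable pairs for '", parameter, "'")
  }
  d <- y - x
  if (all(d == 0)) {
    return(test_result("wilcoxon_signed_rank", parameter, 0, NA_real_, 1,
                       note = "all differences zero"))
  }
  nz <- d != 0
  wt <- suppressWarnings(
    stats::wilcox.test(y[nz], x[nz], paired = TRUE,
                       exact = use_exact(d[nz]), correct = TRUE))
  test_result("wilcoxon_signed_rank", parameter, unname(wt$statistic),
              NA_real_, wt$p.value)
}

#' Friedman test over time bins with Dunn's post-hoc comparisons
#'
#' Intra-trial time courses (one value per rat per bin) are tested with the
#' Friedman rank-sum test; pairwise bins are then compared with Dunn's test
#' (z on within-rat rank means, Bonferroni-adjusted over the bin pairs).
#' Rats missing any bin are excluded listwise with a warning.  The Friedman
#' statistic is reported in its chi-squared form.
#'
#' @param values Numeric matrix or data.frame, rats x bins.
#' @return List with `friedman` (an `mcsf_test_result` row) and `posthoc`
#'   (data.frame of pairwise z, raw and Bonferroni-adjusted p).
#' @export
timecourse_test <- function(values) {
  m <- as.matrix(values)
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning("timecourse_test: ", sum(!complete),
            " rat(s) with a missing bin excluded listwise")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("degenerate input: need >= 2 rats and >= 2 bins")
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic); pval <- ft$p.value
  if (!is.finite(stat)) { stat <- 0; pval <- 1 }  # all rows fully tied
  friedman <- test_result("friedman", "timecourse", stat,
                          unname(ft$parameter), pval)
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    z <- (rbar[i1] - rbar[i2]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(bin_1 = i1, bin_2 = i2, z = z, p = p,
               p_adj = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  }))
  posthoc$label <- significance_label(posthoc$p_adj)
  rownames(posthoc) <- NULL
  list(friedman = friedman, posthoc = posthoc)
}

#' Fisher's exact test on occurrence counts
#'
#' Two-sided Fisher's exact test on a 2x2 table of animals showing vs not
#' showing a zone visit or behavior, per group (see [compute_occurrence()]).
#'
#' @param counts 2x2 matrix (`rbind(c(yes_A, no_A), c(yes_B, no_B))`), or a
#'   data.frame with `occurrence` and `n` columns as returned by
#'   [compute_occurrence()].
#' @return An `mcsf_test_result` row.
#' @export
occurrence_test <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- cbind(counts$occurrence, counts$n - counts$occurrence)
  }
  m <- as.matrix(counts)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  ft <- stats::fisher.test(m)
  test_result("fisher_exact", "occurrence", NA_real_, NA_real_, ft$p.value)
}

#' Spearman rank correlation with strength banding
#'
#' Monotonic association between paired measurements, with the conventional
#' strength bands on `|r|`: `< 0.40` weak/none, `0.40-0.59` moderate,
#' `0.60-0.79` strong, `>= 0.80` very strong; the sign is reported
#' separately in the label.
#'
#' @param x,y Numeric vectors (pairs with any NA are dropped; >= 4 complete
#'   pairs required).
#' @return An `mcsf_test_result` row with `statistic` = Spearman r and the
#'   band in `note` (e.g. `"strong negative"`).
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("degenerate input: need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result("spearman", "correlation", NA_real_, NA_real_,
                       NA_real_, note = "undefined (constant input)"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  r <- unname(ct$estimate)
  test_result("spearman", "correlation", r, NA_real_, ct$p.value,
              note = correlation_band(r))
}

#' @rdname correlate
#' @param r A correlation coefficient.
#' @return `correlation_band`: the strength label.
#' @export
correlation_band <- function(r) {
  if (is.na(r)) return(NA_character_)
  strength <- if (abs(r) < 0.40) "weak/none" else
    if (abs(r) < 0.60) "moderate" else
      if (abs(r) < 0.80) "strong" else "very strong"
  if (strength == "weak/none") return(strength)
  paste(strength, if (r >= 0) "positive" else "negative")
}

#' Run the Mann-Whitney battery over all numeric parameters
#'
#' Convenience wrapper: [group_compare()] for every numeric column of the
#' table, returned as one tidy results table.  Columns with insufficient
#' data are skipped, as are zero-variance columns (a parameter that is
#' constant across all animals — e.g. the latency to the release zone —
#' carries no between-group information and cannot be rank-tested).
#'
#' @param tab An `mcsf_parameter_table`.
#' @param trial Optional trial restriction.
#' @param parameters Optional subset of column names.
#' @return Data.frame of `mcsf_test_result` rows.
#' @export
group_compare_all <- function(tab, trial = NULL, parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                          c("rat_id", "group", "trial"))
  }
  rows <- lapply(parameters, function(p) {
    v <- tab[[p]]
    if (!is.null(trial)) v <- v[tab$trial == as.character(trial)]
    if (stats::sd(v, na.rm = TRUE) %in% c(0, NA) || all(is.na(v))) {
      return(NULL)
    }
    tryCatch(group_compare(tab, p, trial = trial), error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
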