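#' Prepare a parameter matrix for multivariate profiling
#'
#' Unit-variance scaling and mean-centering standardize the weighting of
#' each parameter.  Zero-variance columns are dropped with a warning; after
#' scaling, remaining missing cells are imputed at the column mean (i.e. 0)
#' and flagged.
#'
#' @param tab An `mcsf_parameter_table` (or data.frame).
#' @param parameters Column names to include.
#' @return Numeric matrix with attributes `imputed` (logical matrix) and
#'   `dropped` (zero-variance column names).
#' @keywords internal
scale_parameters <- function(tab, parameters) {
  x <- as.matrix(tab[, parameters, drop = FALSE])
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance parameter(s): ",
            paste(parameters[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  x <- scale(x)
  imputed <- is.na(x)
  x[imputed] <- 0
  attr(x, "imputed") <- imputed
  attr(x, "dropped") <- parameters[drop]
  x
}

#' Principal component analysis of a parameter table
#'
#' Variables are unit-variance scaled and mean-centered, then decomposed
#' into principal components; component 1 carries the largest share of the
#' variance, component 2 the largest of the remainder, and so on.  Returns
#' per-rat scores, per-parameter loadings and the explained-variance
#' fraction R2X per component.
#'
#' @param tab An `mcsf_parameter_table`.
#' @param parameters Column names to include (default: all numeric
#'   parameters).
#' @param ncomp Number of components to keep (default all).
#' @return A list of class `mcsf_multivariate` with `method`, `scores`,
#'   `loadings`, `r2x`, `imputed_cells`, `dropped`.
#' @export
pca_profile <- function(tab, parameters = NULL, ncomp = NULL) {
  if (is.null(parameters)) {
    parameters <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                          c("rat_id", "group", "trial"))
  }
  if (nrow(tab) < 3L || length(parameters) < 2L) {
    stop("usage error: pca_profile needs >= 3 rows and >= 2 parameters")
  }
  x <- scale_parameters(tab, parameters)
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  r2x <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(ncomp)) length(fit$sdev) else min(ncomp, length(fit$sdev))
  structure(list(
    method = "pca",
    scores = fit$x[, seq_len(k), drop = FALSE],
    loadings = fit$rotation[, seq_len(k), drop = FALSE],
    r2x = r2x[seq_len(k)],
    imputed_cells = sum(attr(x, "imputed")),
    dropped = attr(x, "dropped"),
    center = attr(x, "scaled:center"),
    scale = attr(x, "scaled:scale")
  ), class = "mcsf_multivariate")
}

#' PLS-DA group profiling of a parameter table
#'
#' Projection to latent structures discriminant analysis relating the
#' parameter matrix X to group membership Y (a centered two-group
#' indicator).  Components are fitted by NIPALS: each X-weight vector `w`
#' maximizes the covariance between the X-score `t = Xw` and Y, with X
#' deflated between components; `c` are the Y-weights.  With separable
#' groups the two groups' score distributions locate opposite to each other
#' on component 1, and the parameters most characteristic of a group carry
#' the largest `|w|`.
#'
#' @inheritParams pca_profile
#' @param ncomp Number of latent components (default 2).
#' @return A list of class `mcsf_multivariate` with `scores` (t),
#'   `x_weights` (w, columns unit norm), `x_loadings` (p), `y_weights` (c),
#'   `r2x` per component, `groups`, and bookkeeping fields.
#' @export
plsda_profile <- function(tab, parameters = NULL, ncomp = 2L) {
  if (is.null(parameters)) {
    parameters <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                          c("rat_id", "group", "trial"))
  }
  groups <- unique(tab$group)
  if (length(groups) != 2L) {
    stop("usage error: plsda_profile needs exactly two groups")
  }
  x <- scale_parameters(tab, parameters)
  y <- ifelse(tab$group == groups[2], 1, 0)
  y <- y - mean(y)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, p, n - 1L)
  ssx0 <- sum(x^2)
  w_mat <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  p_mat <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  t_mat <- matrix(0, n, ncomp)
  c_vec <- numeric(ncomp)
  r2x <- numeric(ncomp)
  xr <- x; yr <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(xr, yr)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- xr %*% w
    tt_ss <- sum(tt^2)
    cc <- sum(yr * tt) / tt_ss
    pp <- crossprod(xr, tt)[, 1] / tt_ss
    xr <- xr - tt %*% t(pp)
    yr <- yr - tt[, 1] * cc
    w_mat[, a] <- w; p_mat[, a] <- pp; t_mat[, a] <- tt; c_vec[a] <- cc
    r2x[a] <- tt_ss * sum(pp^2) / ssx0
  }
  keep <- seq_len(ncomp)
  w_mat <- w_mat[, keep, drop = FALSE]
  p_mat <- p_mat[, keep, drop = FALSE]
  colnames(w_mat) <- colnames(p_mat) <- paste0("comp", keep)
  structure(list(
    method = "plsda",
    scores = t_mat[, keep, drop = FALSE],
    x_weights = w_mat,
    x_loadings = p_mat,
    y_weights = c_vec[keep],
    r2x = r2x[keep],
    groups = groups,
    group_of_row = tab$group,
    imputed_cells = sum(attr(x, "imputed")),
    dropped = attr(x, "dropped")
  ), class = "mcsf_multivariate")
}

#' @export
print.mcsf_multivariate <- function(x, ...) {
  cat("<mcsf_multivariate> ", toupper(x$method), ": ",
      ncol(x$scores), " component(s), R2X = ",
      paste(sprintf("%.3f", x$r2x), collapse = ", "), "\n", sep = "")
  if (x$imputed_cells > 0) {
    cat("  ", x$imputed_cells, " missing cell(s) imputed at column mean\n")
  }
  invisible(x)
}
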