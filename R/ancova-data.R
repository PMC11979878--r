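#' Construct an ANCOVA data object
#'
#' Bundles a numeric response, a grouping structure and an optional covariate
#' matrix into the single input object used by all fitting and testing
#' functions. The model is the general heteroscedastic ANCOVA
#' \deqn{Y_{ij} = b_i + \sum_l p_l M_{ij}^{(l)} + \epsilon_{ij},}
#' with treatment cells \eqn{i = 1, \dots, a} and independent, mean-zero
#' errors whose variances may differ between groups or between subjects.
#'
#' Two crossed factors may be supplied instead of a single grouping vector;
#' they are combined into one cell index with the first factor varying
#' slowest, the convention shared by [factorial_contrast()].
#'
#' @param y numeric response vector of length N.
#' @param groups vector (factor, character or integer) of cell labels, or a
#'   data frame / list of exactly two such vectors for a two-way layout.
#' @param covariates numeric matrix (or vector, or data frame) with N rows and
#'   M columns; `NULL` for the covariate-free model (heteroscedastic ANOVA).
#' @param factor_structure optional integer vector of per-factor level counts;
#'   filled in automatically when `groups` holds two factors.
#'
#' @return An object of class `"ancova_data"`: a list with elements `y`,
#'   `groups` (factor with levels in order of first appearance), `covariates`
#'   (N x M matrix, possibly zero columns) and `factor_structure`.
#' @examples
#' d <- ancova_data(rnorm(12), rep(c("ctrl", "lo", "hi"), each = 4),
#'                  covariates = runif(12))
#' d$n
#' @export
ancova_data <- function(y, groups, covariates = NULL, factor_structure = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  if (N < 2L) stop("need at least two observations")
  if (anyNA(y)) stop("missing values in response at rows: ",
                     paste(which(is.na(y)), collapse = ", "))

  if (is.data.frame(groups) || (is.list(groups) && !is.factor(groups))) {
    if (length(groups) != 2L)
      stop("`groups` as a list/data.frame must contain exactly two factors")
    f1 <- .as_first_appearance_factor(groups[[1]])
    f2 <- .as_first_appearance_factor(groups[[2]])
    if (length(f1) != N || length(f2) != N)
      stop("factor columns must have the same length as the response")
    factor_structure <- c(nlevels(f1), nlevels(f2))
    # first factor slow, second fast
    lab <- paste(as.character(f1), as.character(f2), sep = ".")
    lev <- as.vector(t(outer(levels(f1), levels(f2), paste, sep = ".")))
    groups <- factor(lab, levels = lev)
    if (any(table(groups) == 0L))
      stop("empty cells in the two-way layout: ",
           paste(lev[table(groups) == 0L], collapse = ", "))
  } else {
    groups <- .as_first_appearance_factor(groups)
  }
  if (length(groups) != N) stop("`groups` must have the same length as `y`")
  if (anyNA(groups)) stop("missing group labels at rows: ",
                          paste(which(is.na(groups)), collapse = ", "))

  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = N, ncol = 0L)
  } else {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates)) stop("covariates must be numeric")
    if (nrow(covariates) != N)
      stop("covariate matrix must have one row per observation")
    if (anyNA(covariates)) {
      bad <- which(rowSums(is.na(covariates)) > 0L)
      stop("missing covariate values at rows: ", paste(bad, collapse = ", "))
    }
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("M", seq_len(ncol(covariates)))
  }

  n_i <- as.integer(table(groups)[levels(groups)])
  structure(list(y = y, groups = groups, covariates = covariates,
                 factor_structure = factor_structure,
                 a = nlevels(groups), n = n_i, N = N),
            class = "ancova_data")
}

# factor with levels ordered by first appearance; the ordering is recorded
# in every result
.as_first_appearance_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  factor(x, levels = unique(x))
}

#' @export
print.ancova_data <- function(x, ...) {
  cat("Heteroscedastic ANCOVA data: N =", x$N, ", a =", x$a, "cells, M =",
      ncol(x$covariates), "covariate(s)\n")
  cat("cell sizes:", paste(levels(x$groups), x$n, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
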