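#' Standard contrast families for one-way layouts
#'
#' Builds the q x a hypothesis matrix C whose rows \eqn{c_\ell'} define the
#' individual null hypotheses \eqn{H_0^{(\ell)}: c_\ell'b = 0}.
#'
#' * `dunnett`: many-to-one comparisons of groups 2..a against group 1,
#'   rows \eqn{(-1, 0, \dots, 1, \dots, 0)}; q = a - 1.
#' * `tukey`: all pairwise differences; q = a(a-1)/2.
#' * `grandmean`: comparisons to the average, the centering projection
#'   \eqn{P_a = I_a - J_a/a}; all a (linearly dependent) rows are kept —
#'   the max statistic and its equicoordinate quantile are well defined
#'   under the singular correlation structure.
#'
#' @param family one of `"dunnett"`, `"tukey"`, `"grandmean"`.
#' @param a number of groups (>= 2).
#' @param labels optional character vector of group names for row labels.
#' @return A `"contrast_matrix"`: numeric matrix with row labels and a
#'   `family` attribute.
#' @examples
#' build_contrast("dunnett", 3)
#' @export
build_contrast <- function(family = c("dunnett", "tukey", "grandmean"), a,
                           labels = NULL) {
  family <- match.arg(family)
  if (!is.numeric(a) || length(a) != 1L || a < 2 || a != round(a))
    stop("`a` must be an integer >= 2")
  a <- as.integer(a)
  if (is.null(labels)) labels <- as.character(seq_len(a))
  if (length(labels) != a) stop("`labels` must have length a")

  C <- switch(family,
    dunnett = {
      Cm <- cbind(-1, diag(a - 1L))
      rownames(Cm) <- paste(labels[-1L], "-", labels[1L])
      Cm
    },
    tukey = {
      pairs <- utils::combn(a, 2L)
      Cm <- matrix(0, ncol(pairs), a)
      for (k in seq_len(ncol(pairs))) {
        Cm[k, pairs[1L, k]] <- -1
        Cm[k, pairs[2L, k]] <- 1
      }
      rownames(Cm) <- paste(labels[pairs[2L, ]], "-", labels[pairs[1L, ]])
      Cm
    },
    grandmean = {
      Cm <- diag(a) - 1 / a
      rownames(Cm) <- paste(labels, "- mean")
      Cm
    })
  colnames(C) <- labels
  .as_contrast_matrix(C, family)
}

#' Kronecker contrasts for two-way factorial layouts
#'
#' For cells ordered with the first factor varying slowest (the convention
#' of [ancova_data()] with two factors), main and interaction effect
#' hypotheses are built from the centering matrices \eqn{P_a = I_a - J_a/a}:
#' \deqn{\mathrm{main\_first}: P_{a_1} \otimes \tfrac{1}{a_2}1_{a_2}', \quad
#'       \mathrm{main\_second}: \tfrac{1}{a_1}1_{a_1}' \otimes P_{a_2}, \quad
#'       \mathrm{interaction}: P_{a_1} \otimes P_{a_2}.}
#' Main-effect rows compare each level's average over the other factor to
#' the grand mean; interaction rows annihilate both main-effect spaces.
#'
#' @param levels integer vector `c(a1, a2)` of factor level counts (each >= 2).
#' @param effect `"main_first"`, `"main_second"` or `"interaction"`.
#' @param labels optional list of two character vectors of level names.
#' @return A `"contrast_matrix"` with `a1*a2` columns.
#' @examples
#' factorial_contrast(c(2, 3), "main_second")
#' @export
factorial_contrast <- function(levels,
                               effect = c("main_first", "main_second",
                                          "interaction"),
                               labels = NULL) {
  effect <- match.arg(effect)
  if (length(levels) != 2L || any(levels < 2) || any(levels != round(levels)))
    stop("`levels` must be two integers >= 2")
  a1 <- as.integer(levels[1L]); a2 <- as.integer(levels[2L])
  if (is.null(labels)) labels <- list(as.character(seq_len(a1)),
                                      as.character(seq_len(a2)))
  P1 <- diag(a1) - 1 / a1
  P2 <- diag(a2) - 1 / a2
  one1 <- matrix(1 / a1, 1L, a1)
  one2 <- matrix(1 / a2, 1L, a2)
  C <- switch(effect,
    main_first  = kronecker(P1, one2),
    main_second = kronecker(one1, P2),
    interaction = kronecker(P1, P2))
  rownames(C) <- switch(effect,
    main_first  = paste(labels[[1L]], "- mean"),
    main_second = paste(labels[[2L]], "- mean"),
    interaction = as.vector(t(outer(labels[[1L]], labels[[2L]], paste,
                                    sep = ":"))))
  colnames(C) <- as.vector(t(outer(labels[[1L]], labels[[2L]], paste,
                                   sep = ".")))
  .as_contrast_matrix(C, "factorial")
}

#' Use a custom contrast matrix
#'
#' Wraps a user-supplied q x a matrix. Rows that do not sum to zero are
#' accepted with a warning: the test statistics are defined for arbitrary
#' rows, but only zero-sum rows test pure treatment-effect differences.
#'
#' @param C numeric matrix with one row per hypothesis.
#' @param labels optional row labels.
#' @return A `"contrast_matrix"` with `family = "custom"`.
#' @export
contrast_matrix <- function(C, labels = NULL) {
  C <- as.matrix(C)
  if (!is.numeric(C) || nrow(C) < 1L) stop("C must be a numeric matrix")
  if (any(apply(C, 1L, function(r) all(r == 0))))
    stop("all-zero contrast rows are not allowed")
  if (any(abs(rowSums(C)) > 1e-8))
    warning("some rows do not sum to zero; they are not contrasts of the ",
            "treatment effects")
  if (!is.null(labels)) rownames(C) <- labels
  if (is.null(rownames(C))) rownames(C) <- paste0("c", seq_len(nrow(C)))
  .as_contrast_matrix(C, "custom")
}

.as_contrast_matrix <- function(C, family) {
  structure(C, family = family, class = c("contrast_matrix", class(C)))
}
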