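#' Read ANCOVA data from a delimited text file
#'
#' Reads a long-format CSV/TSV table (one row per subject) and assembles an
#' [ancova_data()] object from declared column roles. Two factor columns are
#' crossed into a single cell index with the first factor varying slowest,
#' the same convention as [factorial_contrast()]. Decimal points only; any
#' missing value is a hard error naming the rows.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, everything
#'   else comma-separated (override with `sep`).
#' @param response name of the numeric response column.
#' @param factors character vector of one or two factor column names.
#' @param covariates character vector of numeric covariate columns (may be
#'   empty).
#' @param sep field separator; `NULL` chooses by file extension.
#' @return an [ancova_data()] object.
#' @export
read_ancova <- function(path, response, factors, covariates = character(0),
                        sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(factors) < 1L || length(factors) > 2L)
    stop("declare one or two factor columns")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(response, factors, covariates)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  y <- tab[[response]]
  if (!is.numeric(y)) stop("response column '", response, "' is not numeric")
  cov <- NULL
  if (length(covariates)) {
    cov <- as.matrix(tab[covariates])
    if (!is.numeric(cov))
      stop("non-numeric covariate column(s): ",
           paste(covariates[!vapply(tab[covariates], is.numeric, TRUE)],
                 collapse = ", "))
  }
  groups <- if (length(factors) == 2L) tab[factors] else tab[[factors]]
  ancova_data(y, groups, covariates = cov)
}

#' Write MCTP results as delimited text
#'
#' Writes one CSV data line per contrast (`contrast`, `estimate`, `lower`,
#' `upper`, `statistic`, `p_adjusted`) preceded by a commented header block
#' recording the method, degrees of freedom or bootstrap size and seed, the
#' critical value, alpha and the global decision. The file round-trips
#' through [read_results()].
#'
#' @param result an `"mctp_t"` or `"mctp_boot"` object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_results <- function(result, path) {
  if (!inherits(result, c("mctp_t", "mctp_boot")))
    stop("result must come from mctp_t_test() or boot_mctp()")
  hdr <- c(
    sprintf("# method: %s", result$method),
    if (result$method == "mvt")
      sprintf("# df_rule: %s", result$df_rule),
    if (result$method == "mvt")
      sprintf("# nu: %.15g", result$df_used),
    if (result$method == "boot")
      sprintf("# nboot: %d", result$nboot),
    if (result$method == "boot")
      sprintf("# seed: %d", result$seed),
    sprintf("# critical: %.15g", result$critical),
    sprintf("# alpha: %.15g", result$alpha),
    sprintf("# T0: %.15g", result$T0),
    sprintf("# reject_global: %s", result$reject_global))
  tab <- data.frame(contrast = rownames(result$contrast),
                    estimate = unname(result$estimates),
                    lower = result$sci[, "lower"],
                    upper = result$sci[, "upper"],
                    statistic = unname(result$statistics),
                    p_adjusted = unname(result$p_adjusted))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path results file path.
#' @return list with `header` (named character) and `table` (data frame).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", hdr_lines)
  header <- stats::setNames(trimws(sub("^[^:]+:", "", kv)),
                            trimws(sub(":.*$", "", kv)))
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  list(header = header, table = tab)
}

#' Deterministic test fixtures
#'
#' Small synthetic datasets with known generating parameters, used by the
#' test suite and examples. `welch_pair` is a two-group Behrens-Fisher
#' layout without covariates; `three_group` has three groups and one
#' covariate; `factorial_2x6` emulates the shape of a two-way toxicology
#' layout — 2 x 6 cells of 10 subjects and two covariates — with entirely
#' synthetic values.
#'
#' @param kind `"welch_pair"`, `"three_group"` or `"factorial_2x6"`.
#' @param seed integer seed; the same seed always returns the same fixture.
#' @return an [ancova_data()] object.
#' @export
make_fixture <- function(kind = c("welch_pair", "three_group",
                                  "factorial_2x6"), seed = 1L) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  switch(kind,
    welch_pair = {
      n <- c(10L, 14L)
      g <- rep(c("A", "B"), times = n)
      y <- c(stats::rnorm(n[1], 5, 2), stats::rnorm(n[2], 6, 0.8))
      ancova_data(y, g)
    },
    three_group = {
      n <- c(9L, 11L, 10L)
      g <- rep(c("ctrl", "lo", "hi"), times = n)
      x <- stats::rnorm(sum(n), 7, 1)
      sd_g <- rep(c(1, 1.6, 0.7), times = n)
      y <- rep(c(5, 5.5, 6.2), times = n) + 0.8 * x +
        stats::rnorm(sum(n), 0, sd_g)
      ancova_data(y, g, covariates = cbind(x = x))
    },
    factorial_2x6 = {
      sex <- rep(c("f", "m"), each = 60L)
      dose <- rep(rep(c("0", "50", "100", "250", "500", "1000"), each = 10L),
                  times = 2L)
      base <- stats::rnorm(120L, 16, 2)
      dw <- stats::rnorm(120L, 80, 20)
      cell_eff <- rep(rep(c(0, -0.4, 0.1, -1.2, 0.3, 1.8), each = 10L), 2L) +
        rep(c(0, 2.5), each = 60L)
      sd_cell <- rep(rep(c(1, 1.4, 0.8, 1.8, 1.1, 2.2), each = 10L), 2L)
      y <- 14 + cell_eff - 0.04 * base - 0.01 * dw +
        stats::rnorm(120L, 0, sd_cell)
      ancova_data(y, data.frame(sex = sex, dose = dose),
                  covariates = cbind(baseline = base, delta_weight = dw))
    })
}
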