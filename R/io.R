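#' Read one or two samples from a text file
#'
#' Supported formats:
#' \describe{
#'   \item{`plain`}{one numeric value per line; yields a single sample.}
#'   \item{`csv_two_column`}{CSV with columns `group,value`; yields one
#'     sample per group label (at most two groups).}
#'   \item{`csv_wide`}{CSV with columns `x,y`; blank cells allow ragged
#'     group sizes.}
#' }
#' Non-numeric tokens are reported with their line number; non-finite
#' values are rejected; every group needs at least 2 values.
#'
#' @param path file path.
#' @param format one of `"plain"`, `"csv_two_column"`, `"csv_wide"`.
#' @return a named list of [observed_sample()] objects (length 1 or 2).
#' @export
read_samples <- function(path, format = c("plain", "csv_two_column",
                                          "csv_wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  parse_num <- function(tok, line_no) {
    v <- suppressWarnings(as.numeric(tok))
    bad <- which(is.na(v) & !(trimws(tok) == ""))
    if (length(bad)) {
      stopf("non-numeric value '%s' at line %d of %s",
            tok[bad[1]], line_no[bad[1]], path)
    }
    v
  }
  if (format == "plain") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    v <- parse_num(lines[keep], which(keep))
    check_group(v, "sample", path)
    return(list(sample = observed_sample(v)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  if (format == "csv_two_column") {
    if (!all(c("group", "value") %in% names(df))) {
      stopf("%s: csv_two_column format needs columns 'group' and 'value'", path)
    }
    vals <- parse_num(df$value, seq_len(nrow(df)) + 1L)
    groups <- unique(df$group)
    if (length(groups) > 2) stopf("%s: more than two groups", path)
    out <- lapply(groups, function(g) {
      v <- vals[df$group == g]
      check_group(v, g, path)
      observed_sample(v)
    })
    names(out) <- groups
    return(out)
  }
  # csv_wide
  if (!all(c("x", "y") %in% names(df))) {
    stopf("%s: csv_wide format needs columns 'x' and 'y'", path)
  }
  out <- lapply(c("x", "y"), function(g) {
    v <- parse_num(df[[g]], seq_len(nrow(df)) + 1L)
    v <- v[!is.na(v)]
    check_group(v, g, path)
    observed_sample(v)
  })
  names(out) <- c("x", "y")
  out
}

check_group <- function(v, label, path) {
  if (length(v) < 2) {
    stopf("%s: group '%s' has fewer than 2 values", path, label)
  }
  if (any(!is.finite(v))) {
    stopf("%s: group '%s' contains non-finite values", path, label)
  }
  invisible(v)
}

#' Write test results to JSON or TSV
#'
#' Serialises one or more `dil_test_result` objects with a schema-stable
#' set of fields (statistic, estimate, stderr, z, p-value, thresholds,
#' level, decision, sizes, method) plus package version and an optional
#' seed for provenance.
#'
#' @param results a `dil_test_result` or list of them.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv"),
                         seed = NULL) {
  format <- match.arg(format)
  if (inherits(results, "dil_test_result")) results <- list(results)
  if (!length(results)) stopf("no results to write")
  df <- do.call(rbind, lapply(results, as.data.frame))
  df$package_version <- as.character(utils::packageVersion("diltest"))
  if (!is.null(seed)) df$seed <- seed
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Generate a reproducible two-group fixture file
#'
#' Draws `n` baseline and `m` alternative observations from a scenario and
#' writes them as a two-column CSV (`group,value`) with a comment header
#' recording family, `beta` and seed.  Identical inputs regenerate an
#' identical file.
#'
#' @param family,beta scenario (see [scenario_spec()]).
#' @param n,m group sizes.
#' @param seed integer seed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(family, beta, n, m, seed, path) {
  spec <- scenario_spec(family, beta)
  x <- sample_scenario(spec, 1, n, seed = derive_seed(seed, "fixture", 1))
  y <- sample_scenario(spec, 2, m, seed = derive_seed(seed, "fixture", 2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diltest fixture: family=%s beta=%g n=%d m=%d seed=%d",
                     family, beta, n, m, seed), con)
  writeLines("group,value", con)
  writeLines(c(sprintf("x,%.17g", x$values), sprintf("y,%.17g", y$values)),
             con)
  invisible(path)
}
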