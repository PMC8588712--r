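#' Read a categorical data table
#'
#' Reads a delimited text file with a header row into a data frame of
#' factors, mapping the configured missing tokens to `NA`. Every column is
#' treated as categorical; levels are inferred as the sorted distinct
#' observed labels unless declared explicitly.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter (default `","`).
#' @param missing_tokens Character vector of tokens read as missing
#'   (default `c("NA", "")`).
#' @param levels Optional named list declaring the level set of some or all
#'   variables; undeclared variables keep data-driven levels.
#' @return A data frame in which every column is a factor and missing cells
#'   are `NA`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("x,y", "0,1", "1,NA"), tf)
#' read_discrete(tf)
#' @seealso [write_discrete()], [make_missing_indicator()]
#' @export
read_discrete <- function(path, sep = ",", missing_tokens = c("NA", ""),
                          levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !nzchar(lines[[1L]])) {
    stop("empty file or missing header: ", path)
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops a trailing empty field; pad so "a," parses as 2 fields
  width <- length(fields[[1L]]) + (substring(lines[[1L]],
    nchar(lines[[1L]])) == sep)
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (substring(lines[[i]], nchar(lines[[i]])) == sep) f <- c(f, "")
    f
  })
  header <- fields[[1L]]
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad)) {
    stop("ragged row: line ", bad[[1L]] + 1L, " has ", lengths(body)[bad[[1L]]],
         " fields, expected ", length(header))
  }
  cols <- lapply(seq_along(header), function(j) {
    v <- vapply(body, `[[`, character(1L), j)
    v[v %in% missing_tokens] <- NA_character_
    v
  })
  names(cols) <- header
  out <- lapply(header, function(nm) {
    lev <- if (!is.null(levels) && nm %in% names(levels)) {
      as.character(levels[[nm]])
    } else {
      sort(unique(cols[[nm]][!is.na(cols[[nm]])]))
    }
    factor(cols[[nm]], levels = lev)
  })
  names(out) <- header
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a categorical data table
#'
#' Inverse of [read_discrete()]: writes a data frame of factors as delimited
#' text, encoding `NA` cells with `missing_token`. A read/write round trip
#' is the identity on valid datasets.
#'
#' @param data A data frame of factors (or coercible columns).
#' @param path Output file path.
#' @param sep Field delimiter.
#' @param missing_token Token written for `NA` cells.
#' @return Invisibly, `path`.
#' @export
write_discrete <- function(data, path, sep = ",", missing_token = "NA") {
  stopifnot(is.data.frame(data))
  m <- vapply(data, as.character, character(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L)
  if (nrow(data) == 0L) m <- matrix(character(0), 0L, ncol(data))
  m[is.na(m)] <- missing_token
  lines <- c(paste(names(data), collapse = sep),
             apply(m, 1L, paste, collapse = sep))
  if (nrow(data) == 0L) lines <- lines[1L]
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

# Names of variables containing at least one NA.
missing_variables <- function(data) {
  names(data)[vapply(data, anyNA, logical(1L))]
}

#' Replace an incomplete variable by its missing indicator
#'
#' The data-preparation step: the incompletely observed variable is removed
#' and replaced by a dichotomous missing indicator (0 = observed,
#' 1 = missing), yielding a complete dataset on which structure learning
#' operates. Only univariate missingness is supported; rows are never
#' dropped.
#'
#' @param data A data frame of factors in which `var` is the only variable
#'   with missing (`NA`) cells.
#' @param var Name of the incompletely observed variable.
#' @param indicator_name Name for the indicator variable (default
#'   `"<var>_missing"`).
#' @return A list of class `"bnmmi_prepared"` with elements `data` (the
#'   complete updated data frame), `source_variable`, `indicator_variable`,
#'   and `n_missing`.
#' @examples
#' d <- data.frame(fee = factor(c("1", NA, "0", "0", NA, "1")),
#'                 op  = factor(c("1", "0", "1", "1", "0", "0")))
#' prep <- make_missing_indicator(d, "fee")
#' prep$data$fee_missing   # 0 1 0 0 1 0
#' @export
make_missing_indicator <- function(data, var,
                                   indicator_name = paste0(var, "_missing")) {
  stopifnot(is.data.frame(data))
  if (!var %in% names(data)) stop("variable not found: ", var)
  if (indicator_name %in% names(data)) {
    stop("indicator name already present: ", indicator_name)
  }
  others <- setdiff(missing_variables(data), var)
  if (length(others)) {
    stop("multivariate missingness is not supported: variable(s) ",
         paste(others, collapse = ", "), " also contain missing cells")
  }
  miss <- is.na(data[[var]])
  if (!any(miss)) {
    warning("variable '", var, "' has no missing cells; ",
            "indicator is degenerate (all zero)")
  }
  out <- data[setdiff(names(data), var)]
  out[[indicator_name]] <- factor(ifelse(miss, "1", "0"),
                                  levels = c("0", "1"))
  structure(list(data = out,
                 source_variable = var,
                 indicator_variable = indicator_name,
                 n_missing = sum(miss)),
            class = "bnmmi_prepared")
}

#' @export
print.bnmmi_prepared <- function(x, ...) {
  cat("Prepared dataset:", nrow(x$data), "rows,", ncol(x$data), "variables\n")
  cat("  source variable   :", x$source_variable, "\n")
  cat("  missing indicator :", x$indicator_variable, "\n")
  cat(sprintf("  missing cells     : %d (%.2f%%)\n", x$n_missing,
              100 * x$n_missing / max(1L, nrow(x$data))))
  invisible(x)
}

# Internal integer encoding of a complete factor data frame.
# Returns list(X: n x p integer matrix (1-based codes), nlev, vars, levels).
encode_discrete <- function(data) {
  stopifnot(is.data.frame(data))
  if (anyNA(data)) stop("dataset contains missing cells; prepare it first")
  vars <- names(data)
  cols <- lapply(data, function(col) {
    f <- if (is.factor(col)) col else factor(col)
    as.integer(f)
  })
  X <- matrix(unlist(cols, use.names = FALSE), ncol = length(vars))
  lev <- lapply(data, function(col) levels(if (is.factor(col)) col
                                           else factor(col)))
  list(X = X, nlev = vapply(lev, length, integer(1L)),
       vars = vars, levels = lev)
}
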