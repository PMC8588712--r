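#' Parameters of the clinical chain generator
#'
#' Defaults for the three-variable generative model used in the method's
#' calibration study, a chain `tumor_type -> operation -> twoweeks` of
#' binary variables: 58% of tumour patients have a malignant tumour; 89% of
#' benign-tumour patients but only 62% of malignant-tumour patients receive
#' an operation; and patients who receive an operation are discharged
#' within two weeks less often (51%) than those who do not (65%).
#'
#' @param p_malignant `P(tumor_type = 1)`.
#' @param p_op_benign `P(operation = 1 | tumor_type = 0)`.
#' @param p_op_malignant `P(operation = 1 | tumor_type = 1)`.
#' @param p_fast_op `P(twoweeks = 0 | operation = 1)`.
#' @param p_fast_noop `P(twoweeks = 0 | operation = 0)`.
#' @return An object of class `"bnmmi_generator_params"`.
#' @export
generator_params <- function(p_malignant = 0.58,
                             p_op_benign = 0.89,
                             p_op_malignant = 0.62,
                             p_fast_op = 0.51,
                             p_fast_noop = 0.65) {
  p <- list(p_malignant = p_malignant, p_op_benign = p_op_benign,
            p_op_malignant = p_op_malignant, p_fast_op = p_fast_op,
            p_fast_noop = p_fast_noop)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x >= 0 && x <= 1,
                       logical(1L))))
  structure(p, class = "bnmmi_generator_params")
}

# Theoretical P(operation = 0) under the chain generator.
p_no_operation <- function(params = generator_params()) {
  (1 - params$p_malignant) * (1 - params$p_op_benign) +
    params$p_malignant * (1 - params$p_op_malignant)
}

#' Generate complete records from the chain generator
#'
#' Draws `n` i.i.d. records of (`tumor_type`, `operation`, `twoweeks`) from
#' the chain `tumor_type -> operation -> twoweeks` with binomial draws at
#' each node.
#'
#' @param n Number of records.
#' @param params A [generator_params()].
#' @param seed Optional integer seed.
#' @return A data frame of factors (levels `"0"`, `"1"`) with `n` rows.
#' @examples
#' head(generate_complete(5, seed = 1))
#' @export
generate_complete <- function(n, params = generator_params(), seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  tumor <- stats::rbinom(n, 1L, params$p_malignant)
  p_op <- ifelse(tumor == 1L, params$p_op_malignant, params$p_op_benign)
  operation <- stats::rbinom(n, 1L, p_op)
  p_slow <- ifelse(operation == 1L, 1 - params$p_fast_op,
                   1 - params$p_fast_noop)
  twoweeks <- stats::rbinom(n, 1L, p_slow)
  lv <- c("0", "1")
  data.frame(tumor_type = factor(as.character(tumor), levels = lv),
             operation = factor(as.character(operation), levels = lv),
             twoweeks = factor(as.character(twoweeks), levels = lv))
}

#' Solve the group-wise MAR missing rates
#'
#' Under the MAR scenario the missing rate in the non-operation group
#' (`p1`) is `ratio` times the rate in the operation group (`p2`). Given
#' the overall missing rate `p1 * p_noop + p2 * (1 - p_noop) = rate`, the
#' two group rates follow in closed form.
#'
#' @param rate Overall missing rate in `(0, 1)`.
#' @param ratio `p1 / p2 >= 1` (default 2.5).
#' @param p_noop Probability of the non-operation group; by default the
#'   theoretical marginal `P(operation = 0)` under `params`.
#' @param params A [generator_params()] (used only for the default
#'   `p_noop`).
#' @return Named numeric vector `c(p1 = ..., p2 = ...)`.
#' @examples
#' solve_mar_rates(0.05)   # c(p1 = 0.08929, p2 = 0.03572)
#' @export
solve_mar_rates <- function(rate, ratio = 2.5,
                            p_noop = p_no_operation(params),
                            params = generator_params()) {
  stopifnot(rate > 0, rate < 1, ratio >= 1, p_noop > 0, p_noop < 1)
  p2 <- rate / (ratio * p_noop + (1 - p_noop))
  p1 <- ratio * p2
  if (p1 > 1) stop("infeasible missing rate: p1 = ", signif(p1, 4), " > 1")
  c(p1 = p1, p2 = p2)
}

#' Impose MCAR missingness of the fee variable
#'
#' Appends the missing indicator `fee_missing`, drawn i.i.d.
#' Bernoulli(`rate`) independently of every other column — the MCAR
#' missing data structure, in which the indicator is an isolated node. The
#' latent fee values themselves are never generated; no stage of the
#' method uses them.
#'
#' @param data A data frame (typically from [generate_complete()]).
#' @param rate Missing rate in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param indicator Indicator column name (default `"fee_missing"`).
#' @return `data` with the indicator column appended (factor, levels
#'   `"0"`, `"1"`).
#' @export
impose_mcar <- function(data, rate, seed = NULL, indicator = "fee_missing") {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rbinom(nrow(data), 1L, rate)
  data[[indicator]] <- factor(as.character(m), levels = c("0", "1"))
  data
}

#' Impose MAR missingness of the fee variable
#'
#' Appends the missing indicator `fee_missing`, drawn Bernoulli(`p1`) for
#' non-operation records and Bernoulli(`p2`) for operation records with
#' `(p1, p2)` from [solve_mar_rates()] — the MAR missing data structure,
#' in which the indicator depends on `operation` only.
#'
#' @param data A data frame containing an `operation` column with levels
#'   `"0"`/`"1"`.
#' @param rate Overall missing rate in `(0, 1)`.
#' @param ratio Non-operation to operation missing-rate ratio (default
#'   2.5).
#' @param seed Optional integer seed.
#' @param indicator Indicator column name.
#' @param p_noop Non-operation group probability used to solve the group
#'   rates; defaults to the generator's theoretical marginal so that
#'   `(p1, p2)` are constant across realizations. Set it to
#'   `mean(data$operation == "0")` for a per-sample calibration.
#' @return `data` with the indicator column appended.
#' @export
impose_mar <- function(data, rate, ratio = 2.5, seed = NULL,
                       indicator = "fee_missing",
                       p_noop = p_no_operation()) {
  if (!"operation" %in% names(data)) stop("data must contain 'operation'")
  rates <- solve_mar_rates(rate, ratio, p_noop)
  if (!is.null(seed)) set.seed(seed)
  noop <- data$operation == "0"
  p <- ifelse(noop, rates[["p1"]], rates[["p2"]])
  m <- stats::rbinom(nrow(data), 1L, p)
  data[[indicator]] <- factor(as.character(m), levels = c("0", "1"))
  data
}

#' Generate one prepared scenario dataset
#'
#' Convenience wrapper: complete records from the chain generator plus the
#' missing indicator under the requested mechanism. The result is already
#' in prepared form (complete, indicator included) and can be passed
#' straight to [hill_climb()] or [bnmmi()].
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Overall missing rate.
#' @param n Sample size (the calibration study uses 2000).
#' @param seed Optional integer seed.
#' @param params A [generator_params()].
#' @param ratio MAR missing-rate ratio (ignored for MCAR).
#' @return A prepared data frame of four factor columns.
#' @export
simulate_scenario <- function(mechanism = c("MCAR", "MAR"), rate, n = 2000,
                              seed = NULL, params = generator_params(),
                              ratio = 2.5) {
  mechanism <- match.arg(mechanism)
  if (!is.null(seed)) set.seed(seed)
  d <- generate_complete(n, params)
  if (mechanism == "MCAR") {
    impose_mcar(d, rate)
  } else {
    impose_mar(d, rate, ratio, p_noop = p_no_operation(params))
  }
}

# True missing data structures of the two scenarios.
true_structure <- function(mechanism = c("MCAR", "MAR"),
                           indicator = "fee_missing") {
  mechanism <- match.arg(mechanism)
  nodes <- c("tumor_type", "operation", "twoweeks", indicator)
  arcs <- rbind(c("tumor_type", "operation"), c("operation", "twoweeks"))
  if (mechanism == "MAR") arcs <- rbind(arcs, c("operation", indicator))
  bn_dag(nodes, arcs)
}
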