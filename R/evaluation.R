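#' Validity of a set of learned structures
#'
#' Fraction of learned structures that coincide with the true structure.
#' By default structures are compared by their CPDAGs (the statistically
#' identifiable target); `"skeleton"` compares undirected relation sets and
#' `"dag"` requires exact arc equality.
#'
#' @param learned Non-empty list of [bn_dag()] objects.
#' @param truth The true structure ([bn_dag()] over the same nodes).
#' @param mode `"cpdag"` (default), `"skeleton"` or `"dag"`.
#' @return A proportion in `[0, 1]`.
#' @export
validity <- function(learned, truth, mode = c("cpdag", "skeleton", "dag")) {
  mode <- match.arg(mode)
  stopifnot(length(learned) >= 1L, inherits(truth, "bn_dag"))
  for (l in learned) {
    if (!setequal(l$nodes, truth$nodes)) stop("node sets differ")
  }
  key <- switch(mode,
    cpdag = cpdag_key,
    skeleton = function(d) paste(skeleton_keys(d), collapse = ";"),
    dag = function(d) paste(sort(paste0(d$arcs[, 1L], ">", d$arcs[, 2L])),
                            collapse = ";"))
  truth_key <- key(truth)
  mean(vapply(learned, function(d) key(d) == truth_key, logical(1L)))
}

#' Per-pair simulation consistency
#'
#' Fraction of learned structures whose relation status for one variable
#' pair — present or absent — matches the true structure. By default the
#' pair is treated as unordered (skeleton level); with `directed = TRUE`
#' the exact arc orientation must match, which is sensitive to
#' search-order artifacts within an equivalence class.
#'
#' @param learned Non-empty list of [bn_dag()] objects.
#' @param pair Character vector of two variable names.
#' @param truth The true structure ([bn_dag()]).
#' @param directed Compare the ordered arc `pair[1] -> pair[2]` instead of
#'   the unordered relation.
#' @return A proportion in `[0, 1]`.
#' @export
simulation_consistency <- function(learned, pair, truth, directed = FALSE) {
  stopifnot(length(pair) == 2L, inherits(truth, "bn_dag"))
  if (!all(pair %in% truth$nodes)) stop("unknown pair: ",
                                        paste(pair, collapse = ", "))
  status <- if (directed) {
    function(d) any(d$arcs[, 1L] == pair[[1L]] & d$arcs[, 2L] == pair[[2L]])
  } else {
    k <- paste(sort(pair), collapse = "|")
    function(d) k %in% skeleton_keys(d)
  }
  truth_status <- status(truth)
  mean(vapply(learned, function(d) status(d) == truth_status, logical(1L)))
}

#' Robustness of validity across missing rates
#'
#' Spread of the per-scenario validities within one missing mechanism,
#' reported as their sample standard deviation (the headline value); the
#' sample variance is attached as attribute `"variance"`. Zero when all
#' validities are equal.
#'
#' @param validities Numeric vector of at least two per-scenario
#'   validities.
#' @return The sample standard deviation, with attribute `"variance"`.
#' @examples
#' robustness(c(0.9698, 0.9727, 0.9686, 0.9697))  # 0.0018
#' @export
robustness <- function(validities) {
  if (length(validities) < 2L) stop("need at least two validities")
  s <- stats::sd(validities)
  structure(s, variance = stats::var(validities))
}

#' Logistic regression of the missing indicator
#'
#' The traditional comparator: a maximum-likelihood logistic regression
#' (iteratively reweighted least squares, tolerance 1e-8, at most 50
#' iterations) of the missing indicator on every other variable, with the
#' global likelihood-ratio statistic `2 * (l_full - l_null)` against the
#' intercept-only model and per-coefficient Wald tests. Constant
#' predictors are dropped with a warning; (quasi-)complete separation is
#' flagged.
#'
#' @param data Complete data frame of factors.
#' @param indicator Name of the binary indicator variable.
#' @param predictors Predictor names (default: all other variables).
#' @return An object of class `"bnmmi_logistic"`: list with
#'   `coefficients`, `loglik_full`, `loglik_null`, `lr_stat`, `df`,
#'   `p_value`, `wald_p`, `separation` and the underlying `glm` object.
#' @export
logistic_fit <- function(data, indicator,
                         predictors = setdiff(names(data), indicator)) {
  stopifnot(indicator %in% names(data), length(predictors) >= 1L)
  if (anyNA(data)) stop("dataset contains missing cells; prepare it first")
  y <- data[[indicator]]
  if (nlevels(factor(y)) != 2L) stop("indicator must be binary")
  constant <- predictors[vapply(predictors, function(p) {
    length(unique(data[[p]])) < 2L
  }, logical(1L))]
  if (length(constant)) {
    warning("dropping constant predictor(s): ",
            paste(constant, collapse = ", "))
    predictors <- setdiff(predictors, constant)
    if (!length(predictors)) stop("no non-constant predictors left")
  }
  fml <- stats::as.formula(paste(indicator, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mu <- stats::fitted(fit)
  separation <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (separation) warning("possible (quasi-)complete separation")
  ll_full <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(stats::as.formula(paste(indicator, "~ 1")),
                         data = data, family = stats::binomial())
  ll_null <- as.numeric(stats::logLik(null_fit))
  lr <- 2 * (ll_full - ll_null)
  df <- length(stats::coef(fit)) - 1L
  coefs <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit),
                 loglik_full = ll_full,
                 loglik_null = ll_null,
                 lr_stat = lr,
                 df = df,
                 p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                 wald_p = coefs[, "Pr(>|z|)"],
                 separation = separation,
                 glm = fit),
            class = "bnmmi_logistic")
}

#' @export
print.bnmmi_logistic <- function(x, ...) {
  cat("Logistic missingness model (", x$df, " predictors)\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("Global LR statistic %.4f on %d df, p = %.4g\n",
              x$lr_stat, x$df, x$p_value))
  invisible(x)
}

#' Validity of the logistic comparator
#'
#' Fraction of replicates whose test decision matches the truth. Under the
#' default `"lr"` rule a replicate rejects when the global likelihood-ratio
#' test is significant at `alpha`; a decision is correct when the truth has
#' no related variables and the test does not reject, or the truth has
#' related variables and it rejects. The `"wald"` rule instead requires
#' significance/non-significance of each predictor's Wald test to match
#' membership of `truth_related` exactly.
#'
#' @param fits List of [logistic_fit()] results.
#' @param truth_related Character vector of variables truly related to the
#'   indicator (empty under MCAR).
#' @param alpha Test level (default 0.05).
#' @param rule `"lr"` (default) or `"wald"`.
#' @return A proportion in `[0, 1]`.
#' @export
logistic_validity <- function(fits, truth_related = character(0),
                              alpha = 0.05, rule = c("lr", "wald")) {
  rule <- match.arg(rule)
  correct <- vapply(fits, function(f) {
    if (rule == "lr") {
      reject <- f$p_value < alpha
      if (length(truth_related)) reject else !reject
    } else {
      wp <- f$wald_p[setdiff(names(f$wald_p), "(Intercept)")]
      vars <- sub("1$", "", names(wp))   # strip factor-level suffix
      all((wp < alpha) == (vars %in% truth_related))
    }
  }, logical(1L))
  mean(correct)
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with the Yates continuity correction by default (the
#' convention used for the empirical contingency tables this package
#' reports), on a 2x2 table of counts.
#'
#' @param table A 2x2 numeric matrix of non-negative counts.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return List with `statistic`, `p_value` and `df` (= 1).
#' @examples
#' chi_square_2x2(matrix(c(235, 650, 77, 76), 2))  # 33.95
#' @export
chi_square_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (sum(table) == 0) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal: chi-square undefined")
  }
  ct <- stats::chisq.test(table, correct = continuity)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Contingency tables of the motivating hospital study
#'
#' The 2x2 cross-tabulations reported for the motivating medical-record
#' study of 1038 oncology in-patients (153 of whom had a missing fee
#' value): operation against the fee missing indicator, tumour type
#' against operation, and operation against two-week discharge.
#'
#' @return Named list of three 2x2 integer matrices with informative
#'   dimnames.
#' @export
hospital_tables <- function() {
  list(
    operation_vs_missing_fee = matrix(
      c(235L, 650L, 77L, 76L), 2L,
      dimnames = list(operation = c("0", "1"), fee_missing = c("0", "1"))),
    tumor_type_vs_operation = matrix(
      c(51L, 261L, 366L, 360L), 2L,
      dimnames = list(tumor_type = c("0", "1"), operation = c("0", "1"))),
    operation_vs_twoweeks = matrix(
      c(198L, 377L, 114L, 349L), 2L,
      dimnames = list(operation = c("0", "1"), twoweeks = c("0", "1"))))
}

# Aggregated logistic fit for the three-predictor scenario datasets:
# collapses the n x 4 integer matrix to the 8 covariate patterns and fits
# a weighted binomial glm, which is much faster than a row-level fit and
# yields the same likelihood-ratio statistic.
logistic_lr_fast <- function(X) {
  cell <- X[, 1L] + 2L * (X[, 2L] - 1L) + 4L * (X[, 3L] - 1L) +
    8L * (X[, 4L] - 1L)
  counts <- tabulate(cell, 16L)
  m0 <- counts[1:8]            # indicator = 0
  m1 <- counts[9:16]           # indicator = 1
  grid <- expand.grid(t = 0:1, o = 0:1, w = 0:1)
  keep <- (m0 + m1) > 0L
  fit <- stats::glm(cbind(m1, m0)[keep, , drop = FALSE] ~ t + o + w,
                    data = grid[keep, , drop = FALSE],
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50L))
  lr <- fit$null.deviance - fit$deviance
  df <- length(stats::coef(fit)) - 1L
  list(lr_stat = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Run the simulation experiment
#'
#' Reproduces the calibration experiment: for each (mechanism, missing
#' rate) scenario, `reps` datasets of `n` records are generated from the
#' chain generator, the missing indicator is imposed, the structure is
#' learned by [hill_climb()], and validity (default: CPDAG match against
#' the true structure), skeleton-level per-pair simulation consistencies,
#' per-mechanism robustness, and the logistic comparator validity (global
#' likelihood-ratio rule at `alpha`) are computed. Deterministic given the
#' master seed: every scenario and replicate uses an independently derived
#' stream.
#'
#' @param mechanisms Mechanisms to simulate (subset of `c("MCAR",
#'   "MAR")`).
#' @param rates Missing rates (default `c(0.05, 0.10, 0.15, 0.20)`).
#' @param n Records per replicate (default 2000).
#' @param reps Replicates per scenario (the reference study uses 10,000;
#'   default 1000 keeps a full grid under a few minutes).
#' @param seed Integer master seed.
#' @param config A [score_config()].
#' @param params A [generator_params()].
#' @param ratio MAR missing-rate ratio.
#' @param alpha Level of the logistic comparator's global test.
#' @param mode Structure-comparison mode for [validity()].
#' @return An object of class `"bnmmi_performance"`: list with `scenarios`
#'   (data frame: mechanism, rate, validity, logistic_validity),
#'   `consistency` (data frame: mechanism, rate, relation, consistency),
#'   `robustness` (data frame: mechanism, sd, variance) and the call
#'   settings.
#' @export
run_experiment <- function(mechanisms = c("MCAR", "MAR"),
                           rates = c(0.05, 0.10, 0.15, 0.20),
                           n = 2000, reps = 1000, seed = 1L,
                           config = score_config(),
                           params = generator_params(), ratio = 2.5,
                           alpha = 0.05,
                           mode = c("cpdag", "skeleton", "dag")) {
  mode <- match.arg(mode)
  mechanisms <- match.arg(mechanisms, c("MCAR", "MAR"), several.ok = TRUE)
  grid <- expand.grid(rate = rates, mechanism = mechanisms,
                      stringsAsFactors = FALSE)[, c("mechanism", "rate")]
  scen_seeds <- derive_seeds(seed, nrow(grid))
  vars <- c("tumor_type", "operation", "twoweeks", "fee_missing")
  nlev <- stats::setNames(rep(2L, 4L), vars)
  levels <- stats::setNames(rep(list(c("0", "1")), 4L), vars)
  pairs <- t(utils::combn(sort(vars), 2L))
  pair_keys <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  p_noop <- p_no_operation(params)
  scen_rows <- vector("list", nrow(grid))
  cons_rows <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    mech <- grid$mechanism[[s]]
    rate <- grid$rate[[s]]
    truth <- true_structure(mech)
    truth_key <- switch(mode, cpdag = cpdag_key(truth),
      skeleton = paste(skeleton_keys(truth), collapse = ";"),
      dag = paste(sort(paste0(truth$arcs[, 1L], ">", truth$arcs[, 2L])),
                  collapse = ";"))
    truth_sk <- skeleton_keys(truth)
    mr <- if (mech == "MAR") solve_mar_rates(rate, ratio, p_noop) else NULL
    rep_seeds <- derive_seeds(scen_seeds[[s]], reps)
    match_truth <- logical(reps)
    pair_match <- matrix(0L, reps, length(pair_keys))
    lr_reject <- logical(reps)
    for (b in seq_len(reps)) {
      set.seed(rep_seeds[[b]])
      tumor <- stats::rbinom(n, 1L, params$p_malignant)
      operation <- stats::rbinom(n, 1L, ifelse(tumor == 1L,
        params$p_op_malignant, params$p_op_benign))
      twoweeks <- stats::rbinom(n, 1L, ifelse(operation == 1L,
        1 - params$p_fast_op, 1 - params$p_fast_noop))
      ind <- if (mech == "MCAR") {
        stats::rbinom(n, 1L, rate)
      } else {
        stats::rbinom(n, 1L, ifelse(operation == 0L, mr[["p1"]],
                                    mr[["p2"]]))
      }
      X <- cbind(tumor, operation, twoweeks, ind) + 1L
      enc <- list(X = X, nlev = nlev, vars = vars, levels = levels)
      dag <- hill_climb_int(enc, config)
      key <- switch(mode, cpdag = cpdag_key(dag),
        skeleton = paste(skeleton_keys(dag), collapse = ";"),
        dag = paste(sort(paste0(dag$arcs[, 1L], ">", dag$arcs[, 2L])),
                    collapse = ";"))
      match_truth[[b]] <- key == truth_key
      sk <- skeleton_keys(dag)
      pair_match[b, ] <- (pair_keys %in% sk) == (pair_keys %in% truth_sk)
      lr_reject[[b]] <- logistic_lr_fast(X)$p_value < alpha
    }
    logit_ok <- if (mech == "MCAR") !lr_reject else lr_reject
    scen_rows[[s]] <- data.frame(mechanism = mech, rate = rate,
                                 validity = mean(match_truth),
                                 logistic_validity = mean(logit_ok),
                                 stringsAsFactors = FALSE)
    cons_rows[[s]] <- data.frame(mechanism = mech, rate = rate,
                                 relation = pair_keys,
                                 consistency = colMeans(pair_match),
                                 stringsAsFactors = FALSE)
  }
  scenarios <- do.call(rbind, scen_rows)
  rob <- do.call(rbind, lapply(unique(scenarios$mechanism), function(m) {
    v <- scenarios$validity[scenarios$mechanism == m]
    if (length(v) < 2L) {
      data.frame(mechanism = m, sd = NA_real_, variance = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      r <- robustness(v)
      data.frame(mechanism = m, sd = as.numeric(r),
                 variance = attr(r, "variance"), stringsAsFactors = FALSE)
    }
  }))
  structure(list(scenarios = scenarios,
                 consistency = do.call(rbind, cons_rows),
                 robustness = rob,
                 n = n, reps = reps, seed = seed, mode = mode,
                 alpha = alpha, ratio = ratio),
            class = "bnmmi_performance")
}

#' @export
print.bnmmi_performance <- function(x, ...) {
  cat("Simulation experiment:", x$reps, "replicates of n =", x$n,
      "per scenario (seed", paste0(x$seed, ")\n"))
  df <- x$scenarios
  df$validity <- sprintf("%.4f", df$validity)
  df$logistic_validity <- sprintf("%.4f", df$logistic_validity)
  print(df, row.names = FALSE)
  cat("\nRobustness (sd of validity across rates):\n")
  rdf <- x$robustness
  rdf$sd <- sprintf("%.4f", rdf$sd)
  rdf$variance <- signif(rdf$variance, 3)
  print(rdf, row.names = FALSE)
  invisible(x)
}

#' Serialize a performance table as JSON
#'
#' @param x A [run_experiment()] result.
#' @param path Output file path.
#' @export
write_performance_json <- function(x, path) {
  stopifnot(inherits(x, "bnmmi_performance"))
  jsonlite::write_json(
    list(schema = "bnmmi-performance/1",
         n = x$n, reps = x$reps, seed = x$seed, mode = x$mode,
         scenarios = x$scenarios, consistency = x$consistency,
         robustness = x$robustness),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
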