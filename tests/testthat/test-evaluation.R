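test_that("validity counts structure matches per comparison mode", {
  nodes <- c("a", "b", "c")
  truth <- bn_dag(nodes, rbind(c("a", "b")))
  learned <- list(bn_dag(nodes, rbind(c("a", "b"))),
                  bn_dag(nodes, rbind(c("b", "a"))),   # same CPDAG
                  bn_dag(nodes, rbind(c("a", "b"), c("b", "c"))),
                  bn_dag(nodes))
  expect_equal(validity(learned, truth), 0.5)              # cpdag mode
  expect_equal(validity(learned, truth, "skeleton"), 0.5)
  expect_equal(validity(learned, truth, "dag"), 0.25)
  expect_equal(validity(list(truth, truth), truth), 1)
  # 3 of 4 handcrafted structures match
  l2 <- list(truth, truth, truth, bn_dag(nodes))
  expect_equal(validity(l2, truth), 0.75)
  expect_error(validity(learned, bn_dag(c("a", "b"))), "node sets")
})

test_that("simulation consistency matches per-pair status", {
  nodes <- c("a", "b", "c")
  truth <- bn_dag(nodes, rbind(c("a", "b")))
  learned <- list(bn_dag(nodes, rbind(c("a", "b"))),
                  bn_dag(nodes),
                  bn_dag(nodes, rbind(c("b", "a"))))
  expect_equal(simulation_consistency(learned, c("a", "b"), truth), 2 / 3)
  # absent-in-truth pair absent everywhere -> 1
  expect_equal(simulation_consistency(learned, c("a", "c"), truth), 1)
  # consistency + error rate sum to one
  err <- 1 - simulation_consistency(learned, c("a", "b"), truth)
  expect_equal(simulation_consistency(learned, c("a", "b"), truth) + err, 1)
  # directed mode distinguishes orientation
  expect_equal(simulation_consistency(learned, c("a", "b"), truth,
                                      directed = TRUE), 1 / 3)
  expect_error(simulation_consistency(learned, c("a", "z"), truth),
               "unknown pair")
})

test_that("robustness is the sample sd of per-rate validities", {
  expect_equal(as.numeric(robustness(c(0.9, 0.9, 0.9))), 0)
  expect_equal(as.numeric(robustness(c(0.9, 1.0))), 0.07071,
               tolerance = 1e-4)
  r <- robustness(c(0.9334, 0.9794, 0.9790, 0.9825))
  expect_equal(round(as.numeric(r), 4), 0.0235)
  expect_equal(attr(r, "variance"), var(c(0.9334, 0.9794, 0.9790, 0.9825)))
  expect_error(robustness(0.9), "at least two")
})

test_that("logistic coefficient equals the closed-form log odds ratio", {
  # a 2x2 table with cells (a, b; c, d): slope = log(ad/bc)
  counts <- c(a = 160L, b = 40L, c = 90L, d = 110L)
  d <- data.frame(
    x = factor(rep(c("0", "0", "1", "1"), counts)),
    y = factor(rep(c("0", "1", "0", "1"), counts)))
  fit <- logistic_fit(d, "y")
  expect_equal(unname(fit$coefficients["x1"]),
               log(160 * 110 / (40 * 90)), tolerance = 1e-6)
  # balanced independence: null model = full model, LR = 0
  bal <- data.frame(x = factor(rep(c("0", "1"), each = 100)),
                    y = factor(rep(c("0", "1"), 100)))
  expect_equal(logistic_fit(bal, "y")$lr_stat, 0, tolerance = 1e-8)
})

test_that("LR statistic matches a brute-force likelihood maximization", {
  set.seed(15)
  d <- simulate_scenario("MAR", 0.2, 400, seed = 15)
  fit <- logistic_fit(d, "fee_missing")
  X <- cbind(1, vapply(d[1:3], function(c) as.numeric(c == "1"),
                       numeric(nrow(d))))
  y <- as.numeric(d$fee_missing == "1")
  nll <- function(beta) {
    eta <- X %*% beta
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  nll0 <- function(b0) -sum(y * b0 - log1p(exp(rep(b0, length(y)))))
  opt0 <- optimize(nll0, c(-10, 10), tol = 1e-10)
  expect_equal(fit$lr_stat, 2 * (opt0$objective - opt$value),
               tolerance = 1e-4)
})

test_that("logistic fit flags degenerate predictors and separation", {
  d <- data.frame(x = factor(rep("0", 40)),
                  z = factor(rbinom(40, 1, 0.5)),
                  y = factor(rbinom(40, 1, 0.5)))
  expect_warning(fit <- logistic_fit(d, "y"), "constant predictor")
  expect_false("x1" %in% names(fit$coefficients))
  sep <- data.frame(x = factor(rep(c("0", "1"), each = 20)),
                    y = factor(rep(c("0", "1"), each = 20)))
  expect_warning(fit2 <- logistic_fit(sep, "y"), "separation")
  expect_true(fit2$separation)
})

test_that("logistic validity implements both decision rules", {
  fits <- list(list(p_value = 0.20, wald_p = c("(Intercept)" = 0.1,
                                               x1 = 0.30)),
               list(p_value = 0.01, wald_p = c("(Intercept)" = 0.1,
                                               x1 = 0.02)))
  fits <- lapply(fits, function(f) structure(f, class = "bnmmi_logistic"))
  expect_equal(logistic_validity(fits, character(0)), 0.5)
  expect_equal(logistic_validity(fits, "x"), 0.5)
  expect_equal(logistic_validity(fits, "x", rule = "wald"), 0.5)
  expect_equal(logistic_validity(fits, character(0), rule = "wald"), 0.5)
})

test_that("chi-square 2x2 reproduces the classical formula", {
  # corrected statistics on the hospital tables are checked in the
  # acceptance suite; here the uncorrected statistic must equal
  # n(ad - bc)^2 / (marginal product) on arbitrary tables
  set.seed(6)
  for (i in 1:10) {
    m <- matrix(rpois(4, 80) + 1, 2)
    ours <- chi_square_2x2(m, continuity = FALSE)
    n <- sum(m)
    expected <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
    expect_equal(ours$statistic, expected, tolerance = 1e-10)
  }
  # exact independence -> statistic 0 without correction
  prop <- matrix(c(10, 30, 20, 60), 2)
  expect_equal(chi_square_2x2(prop, continuity = FALSE)$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
})

test_that("run_experiment assembles the performance table", {
  pf <- run_experiment(mechanisms = "MCAR", rates = c(0.05, 0.15),
                       n = 400, reps = 8, seed = 3)
  expect_identical(nrow(pf$scenarios), 2L)
  expect_true(all(pf$scenarios$validity >= 0 & pf$scenarios$validity <= 1))
  expect_true(all(pf$consistency$consistency >= 0 &
                    pf$consistency$consistency <= 1))
  expect_identical(nrow(pf$robustness), 1L)
  # single replicate -> validity in {0, 1}
  pf1 <- run_experiment(mechanisms = "MAR", rates = 0.2, n = 400,
                        reps = 1, seed = 3)
  expect_true(pf1$scenarios$validity %in% c(0, 1))
  # determinism
  pf2 <- run_experiment(mechanisms = "MCAR", rates = c(0.05, 0.15),
                        n = 400, reps = 8, seed = 3)
  expect_identical(pf$scenarios, pf2$scenarios)
  tf <- withr::local_tempfile(fileext = ".json")
  write_performance_json(pf, tf)
  parsed <- jsonlite::read_json(tf)
  expect_length(parsed$scenarios, 2L)
})

test_that("MCAR consistency for indicator pairs is high for absence", {
  pf <- run_experiment(mechanisms = "MCAR", rates = 0.1, n = 2000,
                       reps = 100, seed = 17)
  ind_pairs <- grepl("fee_missing", pf$consistency$relation)
  expect_true(all(pf$consistency$consistency[ind_pairs] >= 0.95))
})
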