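test_that("bootstrap replicates are reproducible and verifiable", {
  d <- strong_pair(400L, seed = 3)
  r1 <- bootstrap_replicates(d, 5L, seed = 42, keep_indices = TRUE)
  r2 <- bootstrap_replicates(d, 5L, seed = 42, keep_indices = TRUE)
  expect_equal(r1, r2)
  expect_length(r1, 5L)
  # every stored resample re-learns to the same structure (oracle check)
  for (rep in r1) {
    expect_identical(hill_climb(d[attr(rep, "indices"), ])$arcs, rep$arcs)
    expect_identical(bnmmi:::skeleton_keys(rep), "x|y")
  }
  # an identity resample equals hill_climb on the original data
  expect_identical(hill_climb(d[seq_len(nrow(d)), ])$arcs,
                   hill_climb(d)$arcs)
  expect_error(bootstrap_replicates(d[1L, ], 3L), "at least 2 rows")
})

test_that("relation frequencies count skeleton presence", {
  nodes <- c("a", "b", "c")
  reps <- list(bn_dag(nodes, rbind(c("a", "b"))),
               bn_dag(nodes, rbind(c("b", "a"))),
               bn_dag(nodes, rbind(c("a", "b"), c("b", "c"))),
               bn_dag(nodes))
  f <- relation_frequencies(reps)
  expect_equal(unname(f["a|b"]), 0.75)
  expect_equal(unname(f["b|c"]), 0.25)
  expect_equal(unname(f["a|c"]), 0)
  # permutation invariance
  expect_equal(relation_frequencies(rev(reps)), f)
  # all replicates identical -> indicator function of that skeleton
  same <- replicate(4L, reps[[3L]], simplify = FALSE)
  expect_equal(unname(relation_frequencies(same)[c("a|b", "b|c", "a|c")]),
               c(1, 1, 0))
  expect_error(relation_frequencies(list(reps[[1L]], bn_dag(c("a", "b")))),
               "node sets")
})

test_that("credibility requires every original relation above threshold", {
  nodes <- c("operation", "fee_missing")
  original <- bn_dag(nodes, rbind(c("operation", "fee_missing")))
  f <- c("fee_missing|operation" = 0.9715)
  rep1 <- assess_credibility(original, f, 0.90, 10000L)
  expect_true(rep1$credible)
  rep2 <- assess_credibility(original, c("fee_missing|operation" = 0.85),
                             0.90, 10000L)
  expect_false(rep2$credible)
  expect_identical(rep2$relations$relation[!rep2$relations$passed],
                   "fee_missing|operation")
  # empty structure is vacuously credible
  rep3 <- assess_credibility(bn_dag(nodes), f, 0.90, 10000L)
  expect_true(rep3$credible)
  expect_identical(nrow(rep3$relations), 0L)
})

test_that("expert comparison yields consistency percentages", {
  nodes <- c("operation", "fee_missing", "tumor_type")
  with_arc <- bn_dag(nodes, rbind(c("operation", "fee_missing")))
  without <- bn_dag(nodes)
  reps <- c(replicate(9715L %/% 5L, with_arc, simplify = FALSE),
            replicate((10000L - 9715L) %/% 5L, without, simplify = FALSE))
  expert <- bn_dag(nodes, rbind(c("operation", "fee_missing")))
  cmp <- compare_with_expert(reps, expert)
  row <- cmp[cmp$relation == "fee_missing|operation", ]
  expect_equal(row$consistency, 97.15)
  expect_equal(row$consistency + row$inconsistency, 100)
  # expert = every replicate -> all pairs 100% consistent
  cmp2 <- compare_with_expert(replicate(5L, with_arc, simplify = FALSE),
                              with_arc)
  expect_true(all(cmp2$consistency == 100))
  # expert-only relation -> 0% consistency for that pair
  expert3 <- bn_dag(nodes, rbind(c("tumor_type", "fee_missing")))
  cmp3 <- compare_with_expert(replicate(5L, without, simplify = FALSE),
                              expert3)
  expect_equal(cmp3$consistency[cmp3$relation == "fee_missing|tumor_type"],
               0)
  expect_error(compare_with_expert(reps, bn_dag(c("a", "b"))),
               "node set")
})

test_that("the verdict truth table is exhaustive and orientation-free", {
  nodes <- c("tumor_type", "operation", "fee_missing")
  isolated <- bn_dag(nodes, rbind(c("tumor_type", "operation")))
  incident <- bn_dag(nodes, rbind(c("tumor_type", "operation"),
                                  c("operation", "fee_missing")))
  incident_rev <- bn_dag(nodes, rbind(c("tumor_type", "operation"),
                                      c("fee_missing", "operation")))
  ok <- assess_credibility(bn_dag(nodes), numeric(0), 0.9, 100L)
  bad <- assess_credibility(
    isolated, c("operation|tumor_type" = 0.5), 0.9, 100L)
  expect_identical(identify_mechanism(isolated, "fee_missing", ok)$verdict,
                   "MCAR")
  expect_identical(identify_mechanism(incident, "fee_missing", ok)$verdict,
                   "NOT_MCAR_MAR_OR_MNAR")
  # orientation of the incident arc never changes the verdict
  expect_identical(
    identify_mechanism(incident_rev, "fee_missing", ok)$verdict,
    "NOT_MCAR_MAR_OR_MNAR")
  expect_identical(
    identify_mechanism(incident_rev, "fee_missing", ok)$incident_relations,
    identify_mechanism(incident, "fee_missing", ok)$incident_relations)
  # failed credibility dominates everything
  expect_identical(identify_mechanism(isolated, "fee_missing", bad)$verdict,
                   "INCONCLUSIVE")
  expect_identical(identify_mechanism(incident, "fee_missing", bad)$verdict,
                   "INCONCLUSIVE")
  expect_error(identify_mechanism(isolated, "nope", ok), "not a node")
})

test_that("the full fit classifies simulated mechanisms end to end", {
  d_mar <- simulate_scenario("MAR", 0.15, 2000, seed = 21)
  f_mar <- bnmmi(d_mar, indicator = "fee_missing", n_boot = 60, seed = 4)
  expect_identical(f_mar$verdict$verdict, "NOT_MCAR_MAR_OR_MNAR")
  expect_true("fee_missing|operation" %in% f_mar$verdict$incident_relations)
  d_mcar <- simulate_scenario("MCAR", 0.15, 2000, seed = 22)
  f_mcar <- bnmmi(d_mcar, indicator = "fee_missing", n_boot = 60, seed = 4)
  expect_identical(f_mcar$verdict$verdict, "MCAR")
  # expert structure comparison and JSON report round out the pipeline
  expert <- bnmmi:::true_structure("MAR")
  f2 <- bnmmi(d_mar, indicator = "fee_missing", n_boot = 30, seed = 4,
              expert = expert)
  expect_s3_class(f2$expert_comparison, "bnmmi_expert_comparison")
  tf <- withr::local_tempfile(fileext = ".json")
  write_report_json(f2, tf)
  parsed <- jsonlite::read_json(tf)
  expect_identical(parsed$verdict$verdict, "NOT_MCAR_MAR_OR_MNAR")
  expect_identical(parsed$n, 2000L)
})

test_that("bnmmi() handles raw missing data and rejects bad input", {
  set.seed(9)
  d <- generate_complete(800, seed = 13)
  d <- impose_mar(d, 0.2, seed = 14)
  # convert the indicator back into an incomplete 'fee' column
  d$fee <- factor(ifelse(d$fee_missing == "1", NA, sample(c("lo", "hi"),
                  nrow(d), replace = TRUE)), levels = c("hi", "lo"))
  d$fee_missing <- NULL
  f <- bnmmi(d, n_boot = 40, seed = 2)
  expect_identical(f$indicator, "fee_missing")
  expect_identical(f$verdict$verdict, "NOT_MCAR_MAR_OR_MNAR")
  d2 <- d
  d2$twoweeks[1L] <- NA
  expect_error(bnmmi(d2, n_boot = 5), "multivariate")
  expect_error(bnmmi(generate_complete(50, seed = 1), n_boot = 5),
               "no variable contains missing cells")
})
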