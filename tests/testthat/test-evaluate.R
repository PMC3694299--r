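test_that("compatibility encodes the error definition", {
  expect_false(is_compatible("not_blue", "blue"))
  expect_true(is_compatible("not_blue", "green"))
  expect_true(is_compatible("not_blue", "brown"))
  expect_false(is_compatible("brown", "green"))
  expect_true(is_compatible("not_brown", "blue"))
  expect_false(is_compatible("not_dark", "dark"))
  expect_true(is_compatible("not_light", "medium"))
  expect_false(is_compatible("light", "medium"))
  # non-calls are never errors
  expect_true(all(is_compatible(rep("inconclusive", 3),
                                c("light", "medium", "dark"))))
  expect_true(all(is_compatible(rep("no_call", 3),
                                c("blue", "green", "brown"))))
  expect_true(is_compatible("conflict", "dark"))
  expect_error(is_compatible("purple", "blue"), "unknown label")
  expect_error(is_compatible("blue", "purple"), "unknown phenotype bin")
})

test_that("fixtures are self-consistent with the printed population headers", {
  header <- list(training = c(AA = 43, SA = 27, EA = 35, E = 555,
                              mix = 143),
                 test = c(AA = 8, SA = 9, EA = 10, E = 114, mix = 71))
  for (ds in c("training", "test")) {
    for (tr in c("eye", "skin")) {
      rows <- builtin_fixture(ds, tr)
      s <- summarize_fixture(rows)
      pops <- setNames(s$per_population$n, s$per_population$population)
      expect_equal(pops, header[[ds]], label = paste(ds, tr))
      expect_equal(s$n_samples, sum(header[[ds]]))
      # step-2 subsets never exceed their parent step-1 category
      s2 <- rows[rows$step == 2, ]
      if (nrow(s2)) {
        for (k in seq_len(nrow(s2))) {
          parent <- rows$step == 1 & rows$population == s2$population[k] &
            rows$bin == s2$bin[k] & rows$label == s2$parent_label[k]
          expect_equal(sum(parent), 1L)
          kin <- s2$population == s2$population[k] & s2$bin == s2$bin[k] &
            s2$parent_label == s2$parent_label[k]
          expect_lte(sum(s2$count[kin]), rows$count[parent])
        }
      }
      expect_true(all(rows$errors <= rows$count))
    }
  }
})

test_that("fixture summaries reproduce the printed aggregates", {
  tr <- summarize_fixture(builtin_fixture("training", "eye"))
  expect_equal(tr$n_positive_step1, 151)
  expect_equal(tr$n_positive_total, 248)
  expect_equal(tr$n_errors_step1, 13)
  expect_equal(tr$n_errors_step2, 12)
  sk <- summarize_fixture(builtin_fixture("training", "skin"))
  expect_equal(sk$n_predictions, 600)
  expect_equal(sk$n_errors, 4)
  expect_equal(sk$n_inconclusive, 203)
  expect_error(summarize_fixture(rbind(builtin_fixture("training", "eye"),
                                       builtin_fixture("test", "eye"))),
               "single dataset")
})

test_that("evaluate_cohort counts errors, calls and positives", {
  # rule-consistent truth (epsilon = 0) gives exactly zero errors
  sim <- simulate_cohort(cohort_config(n_samples = 400, discordance = 0,
                                       seed = 101))
  pred <- predict_cohort(sim$genotypes)
  for (trait in c("eye", "skin")) {
    ev <- evaluate_cohort(pred, sim$phenotypes, trait)
    expect_equal(ev$n_errors, 0)
    expect_equal(ev$n_samples, 400)
    expect_equal(sum(ev$per_population$n_samples), 400)
  }
  # eye call rate is 1 for complete genotypes; all-het skin never calls
  ev <- evaluate_cohort(pred, sim$phenotypes, "eye")
  expect_equal(ev$call_rate, 1)
  het <- do.call(rbind, replicate(10, mk_geno(
    rs12913832 = "A/G", rs16891982 = "C/G", rs1426654 = "A/G",
    rs1545397 = "A/T", rs885479 = "A/G", rs6119471 = "C/G"),
    simplify = FALSE))
  het$sample_id <- sprintf("H%02d", 1:10)
  truth <- data.frame(sample_id = het$sample_id, population = "mix",
                      eye_bin = "brown", skin_bin = "medium")
  ev <- evaluate_cohort(predict_cohort(het), truth, "skin")
  expect_equal(ev$n_called, 0)
  expect_equal(ev$call_rate, 0)
  # unmatched sample ids are an error
  expect_error(evaluate_cohort(pred, sim$phenotypes[-1, ], "eye"),
               "no phenotype record")
})

test_that("evaluation recovers a known discordance rate", {
  eps <- 0.05
  sim <- simulate_cohort(cohort_config(n_samples = 2000,
                                       discordance = eps, seed = 77))
  pred <- predict_cohort(sim$genotypes)
  for (trait in c("eye", "skin")) {
    ev <- evaluate_cohort(pred, sim$phenotypes, trait)
    rate <- ev$n_errors / ev$n_called
    expect_lt(abs(rate - eps),
              3 * sqrt(eps * (1 - eps) / ev$n_called))
  }
})
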