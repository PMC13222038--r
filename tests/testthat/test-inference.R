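coded_scores <- function(cfg) {
  sc <- score_sequences(simulate_cohort(cfg))
  sc$group <- factor(sc$group, levels = c("NC", "TBI"))
  sc$timepoint <- factor(sc$timepoint)
  sc
}

test_that("one-sample t test matches the closed form", {
  r <- one_sample_t(c(0.4, 0.5, 0.6))
  expect_equal(r$t, 0)
  expect_equal(r$df, 2)
  r2 <- one_sample_t(c(0.6, 0.7, 0.8))
  expect_equal(r2$t, 0.2 / (0.1 / sqrt(3)))
  expect_equal(r2$p, 2 * pt(-abs(r2$t), 2))
  expect_error(one_sample_t(0.7), "at least 2")
  expect_error(one_sample_t(c(0.7, 0.7, 0.7)), "degenerate")
  # textbook formula to machine precision on arbitrary samples
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), mean = 0.6, sd = 0.2)
    r <- one_sample_t(x, mu0 = 0.5)
    expect_equal(r$t, (mean(x) - 0.5) / (sd(x) / sqrt(length(x))))
    expect_equal(r$df, length(x) - 1)
  }
})

test_that("chance tests run per group and per timepoint within task", {
  cfg <- simulation_config(n_per_group = 10, wordlist = NULL, seed = 2)
  ch <- chance_tests(coded_scores(cfg))
  expect_setequal(ch$level[ch$subset == "group"], c("NC", "TBI"))
  expect_setequal(ch$level[ch$subset == "timepoint"],
                  c("No Delay", "Short Delay", "Long Delay"))
  # strong clustering in the generator puts every subset above chance
  expect_true(all(ch$mean > 0.5))
  expect_true(all(ch$p < 0.05))
})

test_that("re-basing a factor is a pure reparameterization", {
  cfg <- simulation_config(n_per_group = 15, wordlist = NULL, seed = 6)
  sc <- coded_scores(cfg)
  f_lin <- fit_score_model(sc, B = 0)
  f_rev <- recode_reference(f_lin, "group", "TBI")
  expect_equal(f_rev$log_lik, f_lin$log_lik, tolerance = 1e-8)
  # two-level factor: simple effect at the new reference equals
  # old simple effect + old interaction
  cf <- coef(f_lin)
  cr <- coef(f_rev)
  expect_equal(unname(cr["timepointLong Delay"]),
               unname(cf["timepointLong Delay"] +
                        cf["groupTBI:timepointLong Delay"]))
  # re-basing to the current reference changes nothing
  f_same <- recode_reference(f_lin, "group", "NC")
  expect_equal(coef(f_same), coef(f_lin))

  oc <- recall_outcomes(simulate_cohort(cfg))
  oc$group <- factor(oc$group); oc$timepoint <- factor(oc$timepoint)
  f_bin <- fit_recall_model(oc, B = 0)
  f_bin_rev <- recode_reference(f_bin, "group", "TBI")
  expect_equal(f_bin_rev$log_lik, f_bin$log_lik, tolerance = 1e-8)
  expect_error(recode_reference(f_lin, "group", "nope"), "not found")
})

test_that("recall model recovers a known group log-odds difference", {
  set.seed(77)
  n <- 200
  d <- tidyr::crossing(
    participant_id = sprintf("p%03d", 1:(2 * n)),
    item = 1:12)
  d$group <- factor(ifelse(as.integer(sub("p", "", d$participant_id)) <= n,
                           "NC", "TBI"), levels = c("NC", "TBI"))
  eta <- 0.2 - 0.6 * (d$group == "TBI")
  d$recalled <- rbinom(nrow(d), 1, plogis(eta))
  fit <- fit_recall_model(d, formula = recalled ~ group, B = 0)
  expect_lt(abs(coef(fit)["groupTBI"] - (-0.6)), 0.15)
})

test_that("null group effect is covered by the bootstrap interval", {
  set.seed(88)
  d <- tidyr::crossing(participant_id = sprintf("p%02d", 1:40), item = 1:12)
  d$group <- factor(ifelse(d$participant_id <= "p20", "NC", "TBI"))
  d$recalled <- rbinom(nrow(d), 1, 0.5)
  fit <- fit_recall_model(d, formula = recalled ~ group, B = 200, seed = 4)
  row <- fit$coefficients[fit$coefficients$term == "groupTBI", ]
  expect_true(row$ci_lo < 0 && row$ci_hi > 0)
  expect_gt(row$se, 0)
})

test_that("degenerate all-recalled data raises a separation error", {
  d <- tidyr::crossing(participant_id = sprintf("p%02d", 1:10), item = 1:5)
  d$group <- factor(rep(c("NC", "TBI"), length.out = nrow(d)))
  d$recalled <- 1
  expect_error(fit_recall_model(d, formula = recalled ~ group, B = 0),
               "separation")
})

test_that("score model separates groups simulated with different clustering", {
  cfg <- simulation_config(n_per_group = 200, wordlist = NULL, seed = 14)
  sc <- coded_scores(cfg)
  fit <- fit_score_model(sc, B = 199, seed = 2)
  row <- fit$coefficients[fit$coefficients$term == "groupTBI", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$ci_hi, 0)  # interval excludes zero
})

test_that("grand-mean centering makes the covariate fit shift-invariant", {
  cfg <- simulation_config(n_per_group = 20, wordlist = NULL, seed = 15)
  sc <- coded_scores(cfg)
  f1 <- fit_score_model(sc, percent_recall_covariate = TRUE, B = 0)
  sc2 <- sc
  sc2$percent_recall <- sc2$percent_recall + 0.3
  f2 <- fit_score_model(sc2, percent_recall_covariate = TRUE, B = 0)
  expect_equal(coef(f1), coef(f2))
})

test_that("aliased designs are rejected with the offending terms named", {
  cfg <- simulation_config(n_per_group = 8, wordlist = NULL, seed = 16)
  sc <- coded_scores(cfg)
  sc$dup <- as.character(sc$group)  # perfect alias of group
  expect_error(fit_score_model(sc, formula = score ~ group + dup, B = 0),
               "aliased")
})

test_that("bootstrap intervals cover a null group effect in most cohorts", {
  null_params <- tibble::tibble(
    task = "narrative", group = rep(c("NC", "TBI"), each = 3),
    timepoint = rep(c("No Delay", "Short Delay", "Long Delay"), 2),
    tau = 1.5, phi_fwd = 3, p_recall = 0.5)
  covered <- 0L
  for (s in 1:100) {
    cfg <- simulation_config(
      n_per_group = 30, wordlist = NULL,
      narrative = list(items_per_unit = 12L,
                       timepoints = c("No Delay", "Short Delay",
                                      "Long Delay")),
      params = null_params, seed = 1000 + s)
    sc <- coded_scores(cfg)
    fit <- fit_score_model(sc, formula = score ~ group, B = 199, seed = s)
    row <- fit$coefficients[fit$coefficients$term == "groupTBI", ]
    if (row$ci_lo < 0 && row$ci_hi > 0) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})
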