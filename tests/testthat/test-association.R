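test_that("impairment indicators keep six domains, drop 'other', retain 'none'", {
  coh <- toy_cohort(n = 254, seed = 10)
  imp <- impairment_indicators(coh)
  expect_named(imp, c(impairment_names(), "none"))
  expect_false("other" %in% names(imp))
  only_none <- which(imp$none == 1)[1]
  expect_true(all(imp[only_none, impairment_names()] == 0))
  # incomplete questionnaires are excluded
  cfg <- synth_config(n_participants = 400)
  coh2 <- generate_cohort(cfg, seed = 3)
  imp2 <- impairment_indicators(coh2)
  expect_equal(nrow(imp2), sum(coh2$impairment_data_available))
  # contradictory rows are flagged and removed
  coh3 <- toy_cohort(n = 40, seed = 1)
  i <- which(coh3$imp_none == 1)[1]
  coh3$imp_driving[i] <- 1L
  expect_message(imp3 <- impairment_indicators(coh3), "contradictory")
  expect_equal(nrow(imp3), 39)
})

test_that("Cramer's V matches its chi-squared closed form and limits", {
  x <- rep(c(0, 1), each = 30)
  expect_equal(cramers_v(x, x), 1)
  tab_counts <- c(20, 10, 10, 20)
  x2 <- rep(c(0, 0, 1, 1), tab_counts)
  y2 <- rep(c(0, 1, 0, 1), tab_counts)
  chi2 <- sum((table(x2, y2) - 30 * 30 / 60)^2 / (30 * 30 / 60))
  expect_equal(cramers_v(x2, y2), sqrt(chi2 / 60))
  set.seed(4)
  a <- rbinom(10000, 1, 0.4); b <- rbinom(10000, 1, 0.3)
  expect_lt(cramers_v(a, b), 0.05)
  expect_warning(v <- cramers_v(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_true(is.na(v))
})

test_that("two-by-two test selects Fisher on small expected counts and matches oracles", {
  sym <- two_by_two_test(matrix(20, 2, 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$test, "chi-squared")

  t4 <- two_by_two_test(matrix(c(10, 5, 5, 10), 2, byrow = TRUE))
  expect_equal(t4$odds_ratio, 4)
  se <- sqrt(1 / 10 + 1 / 5 + 1 / 5 + 1 / 10)
  expect_equal(t4$ci_low, exp(log(4) - 1.96 * se))
  expect_equal(t4$ci_high, exp(log(4) + 1.96 * se))
  expect_true(t4$ci_low <= t4$odds_ratio && t4$odds_ratio <= t4$ci_high)

  tf <- two_by_two_test(matrix(c(2, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(tf$test, "Fisher")
  expect_equal(tf$p_value, fisher_enum_p(2, 1, 1, 3), tolerance = 1e-12)

  z <- two_by_two_test(matrix(c(0, 5, 4, 6), 2, byrow = TRUE))
  expect_true(z$corrected)  # Haldane-Anscombe on the zero cell
  expect_equal(z$odds_ratio, (0.5 * 6.5) / (5.5 * 4.5))
  expect_error(two_by_two_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "empty margin")
})

test_that("odds ratio is invariant under double swaps and inverts under row swap", {
  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    or <- two_by_two_test(tab)$odds_ratio
    both <- two_by_two_test(tab[2:1, 2:1])$odds_ratio
    rows <- two_by_two_test(tab[2:1, ])$odds_ratio
    expect_equal(both, or)
    expect_equal(rows, 1 / or)
  }
})

test_that("Mann-Whitney exact p matches enumeration and known small-sample values", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2 of the 20 assignments are as extreme
  expect_equal(mw$method, "exact enumeration")

  set.seed(8)
  for (i in 1:15) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(0:4, nx, replace = TRUE)  # ties likely
    y <- sample(0:4, ny, replace = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$p_value, mw_enum_p(x, y), tolerance = 1e-12)
    # U identity under the first-sample convention
    expect_equal(mw$U + mann_whitney(y, x)$U, nx * ny)
  }
})

test_that("Mann-Whitney normal approximation tracks the permutation distribution", {
  set.seed(15)
  for (i in 1:5) {
    x <- sample(0:4, 12, replace = TRUE)
    y <- sample(0:4, 12, replace = TRUE) + rbinom(12, 1, 0.3)
    mw <- mann_whitney(x, y)
    expect_equal(mw$method, "normal approximation")
    mu <- 144 / 2
    r <- rank(c(x, y))
    us <- replicate(20000, sum(r[sample(24, 12)]) - 12 * 13 / 2)
    pperm <- mean(abs(us - mu) >= abs(mw$U - mu) - 1e-9)
    expect_lt(abs(mw$p_value - pperm),
              0.02 + 3 * sqrt(pperm * (1 - pperm) / 20000))
  }
})

test_that("tie-free large-sample p agrees with wilcox.test", {
  set.seed(22)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  mw <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$U, unname(wt$statistic))
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("membership association builds the 5 x 6 Bonferroni family", {
  coh <- toy_cohort(n = 300, seed = 9)
  sc <- score_cohort(coh, rpq_default_clusters())
  a <- membership_association(sc, rpq_default_clusters(), "mild")
  expect_equal(nrow(a), 30)
  expect_equal(unique(a$bonferroni_alpha), 0.05 / 30)
  expect_identical(a$significant, a$p_value < 0.05 / 30)
  expect_identical(a$significant_unadjusted, a$p_value < 0.05)
  expect_output(print(a), "family of 30")
})

test_that("a planted effect is detected and sensitivity analyses run on it", {
  sl <- matrix(0, 5, 6, dimnames = list(names(rpq_default_clusters()),
                                        impairment_names()))
  cfg0 <- synth_config()
  sl["cognitive", "conversations"] <-
    slope_for_target_or(cfg0, "cognitive", "conversations", 4)
  cfg <- synth_config(n_participants = 1000, p_impairment_data = 1,
                      prolonged_fraction = 1, impairment_slopes = sl)
  sc <- score_cohort(generate_cohort(cfg, seed = 14), planted_partition(cfg))
  a <- membership_association(sc, planted_partition(cfg), "mild")
  hit <- a[a$cluster == "cognitive" & a$impairment == "conversations", ]
  expect_true(hit$significant)
  expect_gt(hit$odds_ratio, 2)
  expect_false(is.na(hit$sensitivity_robust))
  expect_false(is.na(hit$or_any))
  # the any-criterion table has the widest exposed margin (nesting)
  m_any <- assign_membership(sc, planted_partition(cfg), membership_criteria("any"))
  m_mean <- assign_membership(sc, planted_partition(cfg), membership_criteria("mean"))
  m_all <- assign_membership(sc, planted_partition(cfg), membership_criteria("all"))
  expect_gte(sum(m_any$cognitive), sum(m_mean$cognitive))
  expect_gte(sum(m_mean$cognitive), sum(m_all$cognitive))
})

test_that("severity-by-impairment runs the 36-comparison family plus any-vs-none", {
  coh <- toy_cohort(n = 400, seed = 12)
  sc <- score_cohort(coh, rpq_default_clusters())
  sev <- severity_by_impairment(sc, rpq_default_clusters())
  expect_equal(sum(sev$impairment != "any_vs_none"), 36)
  expect_equal(unique(sev$bonferroni_alpha[!is.na(sev$bonferroni_alpha)]), 0.05 / 36)
  avn <- sev[sev$impairment == "any_vs_none", ]
  expect_equal(nrow(avn), 1)
  expect_lte(avn$U, avn$n_with * avn$n_without)
  expect_true(all(sev$U >= 0))
})

test_that("permuted labels keep the severity family near its nominal error rate", {
  coh <- toy_cohort(n = 500, seed = 30)
  sc <- score_cohort(coh, rpq_default_clusters())
  set.seed(31)
  for (k in paste0("imp_", c(impairment_names(), "other")))
    sc[[k]] <- sample(sc[[k]])
  sc$imp_none <- as.integer(rowSums(sc[paste0("imp_", c(impairment_names(), "other"))]) == 0)
  sev <- severity_by_impairment(sc, rpq_default_clusters())
  frac <- mean(sev$significant_unadjusted[sev$impairment != "any_vs_none"])
  expect_lte(frac, 0.20)  # about alpha, with family correlation slack
  expect_false(any(sev$significant[sev$impairment != "any_vs_none"]))
})

test_that("early-prolonged comparison yields one result per item with unit ORs on identical groups", {
  coh <- score_cohort(toy_cohort(n = 200, seed = 18))
  res <- compare_early_prolonged(coh, coh)
  expect_equal(nrow(res), 16)
  defined <- !res$or_corrected
  expect_true(all(abs(res$odds_ratio[defined] - 1) < 1e-12))
  # a planted prevalence difference pushes the OR above 1
  e <- coh; e$cor_01 <- pmin(4L, e$cor_01 + 2L)
  res2 <- compare_early_prolonged(e, coh)
  expect_gt(res2$odds_ratio[1], 1)
})
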