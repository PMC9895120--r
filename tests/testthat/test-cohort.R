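test_that("Spearman correlation handles monotone, tied and flat inputs", {
  expect_equal(spearman_age(c(0.1, 0.2, 0.3, 0.4), c(5, 10, 20, 40))$rho, 1)
  expect_equal(spearman_age(c(0.4, 0.3, 0.2, 0.1), c(5, 10, 20, 40))$rho, -1)
  # one adjacent rank swap: 1 - 6*2/(4^3-4) = 0.8
  r <- spearman_age(c(0.1, 0.4, 0.2, 0.3), c(10, 40, 30, 20))
  expect_equal(r$rho, 0.8)
  flat <- spearman_age(c(0.2, 0.2, 0.2), c(1, 2, 3))
  expect_true(flat$undefined)
  expect_true(is.na(flat$rho))
  expect_error(spearman_age(c(0.1, 0.2), c(1, 2)), "at least 3")
})

test_that("Spearman rho and exact p match the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    x <- round(runif(n), 2)
    y <- sample(c(1, 2, 2, 3, 5, 8, 13), n)
    if (sd(x) == 0 || sd(y) == 0) next
    r <- spearman_age(x, y)
    expect_equal(r$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(r$p_value, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
  # large-n branch stays close to the t reference implementation
  set.seed(7)
  x <- runif(30)
  y <- x + rnorm(30, sd = 0.5)
  r <- spearman_age(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  # same order of magnitude as the AS89-based reference p-value
  expect_lt(abs(log(r$p_value) - log(ct$p.value)), log(2))
})

test_that("Mann-Whitney U and exact p match full enumeration", {
  r <- mannwhitney_site(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(r$u_statistic, 9)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$direction, "hyper")

  same <- mannwhitney_site(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "tie")

  set.seed(99)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- sample(c(0, 0.1, 0.1, 0.3, 0.5, 0.5, 0.9), n1 + n2,
                   replace = TRUE)
    case <- vals[seq_len(n1)]
    control <- vals[-seq_len(n1)]
    r <- mannwhitney_site(case, control)
    expect_equal(r$u_statistic, oracle_u(case, control), tolerance = 1e-12)
    expect_equal(r$p_value, oracle_mw_p(case, control), tolerance = 1e-12)
  }
  expect_error(mannwhitney_site(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on its two branches", {
  # tie-free exact branch
  set.seed(5)
  case <- runif(6)
  control <- runif(7)
  r <- mannwhitney_site(case, control)
  wt <- stats::wilcox.test(case, control, exact = TRUE, correct = FALSE)
  expect_equal(r$u_statistic, unname(wt$statistic))
  expect_equal(r$p_value, wt$p.value, tolerance = 1e-12)
  # large-sample approximate branch (with ties and continuity correction)
  set.seed(6)
  case <- round(runif(25), 1)
  control <- round(runif(25) + 0.05, 1)
  r2 <- mannwhitney_site(case, control)
  wt2 <- suppressWarnings(stats::wilcox.test(case, control, exact = FALSE,
                                             correct = TRUE))
  expect_false(r2$exact)
  expect_equal(r2$p_value, wt2$p.value, tolerance = 1e-9)
})

test_that("group-label swap flips direction and preserves p", {
  set.seed(11)
  case <- runif(8)
  control <- runif(9) + 0.2
  a <- mannwhitney_site(case, control)
  b <- mannwhitney_site(control, case)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_true((a$direction == "hyper") == (b$direction == "hypo") ||
                a$direction == "tie")
  # p decreases as the group separation grows
  base <- runif(15)
  p_small <- mannwhitney_site(base + 0.05, base)$p_value
  p_large <- mannwhitney_site(base + 0.5, base)$p_value
  expect_lt(p_large, p_small)
})

test_that("BH correction matches the sorted-minimum definition", {
  expect_equal(bh_correct(0.01), 0.01)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  expect_error(bh_correct(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (rep in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_correct(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NAs are preserved and excluded from the family
  p <- c(0.01, NA, 0.04)
  q <- bh_correct(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(p[c(1, 3)]))
})

test_that("cohort analysis wires the design, subgroup and calls together", {
  set.seed(123)
  n_case <- 10
  n_control <- 10
  samples <- c(sprintf("case%02d", 1:n_case),
               sprintf("ctrl%02d", 1:n_control))
  design <- data.frame(
    sample = samples,
    group = rep(c("case", "control"), c(n_case, n_control)),
    region = "SFG",
    age = c(seq(2, 20, length.out = n_case),
            seq(2, 20, length.out = n_control)),
    stringsAsFactors = FALSE)
  levels <- rbind(
    diff_site = c(rnorm(n_case, 0.4, 0.05), rnorm(n_control, 0.05, 0.02)),
    null_site = rep(0.2, n_case + n_control),
    age_site = c(design$age[1:n_case] / 40 + rnorm(n_case, 0, 0.01),
                 design$age[-(1:n_case)] / 40 + rnorm(n_control, 0, 0.01)))
  levels <- pmin(pmax(levels, 0), 1)
  colnames(levels) <- samples

  res <- run_cohort_analysis(levels, design)
  cmp <- res$comparison
  expect_true(cmp$significant[cmp$key == "diff_site"])
  expect_equal(cmp$direction[cmp$key == "diff_site"], "hyper")
  expect_equal(cmp$p_value[cmp$key == "null_site"], 1)
  corr <- res$correlation
  expect_true(all(corr$rho[corr$key == "age_site"] > 0.9))
  expect_true(all(is.na(corr$rho[corr$key == "null_site"])))

  # strict under-10 subgroup filtering
  design$age <- rep(c(5, 9, 12, 15), 5)
  res10 <- run_cohort_analysis(levels, design, subgroup_max_age = 10)
  expect_equal(res10$n_case + res10$n_control, sum(design$age < 10))
  expect_error(run_cohort_analysis(levels, design, subgroup_max_age = 2),
               "empty group")
  expect_error(run_cohort_analysis(levels, design[-1, ]), "cover")
})

test_that("an uncorrected null comparison rejects at about the alpha rate", {
  set.seed(314)
  n_rep <- 600
  hits <- 0
  for (i in seq_len(n_rep)) {
    case <- rnorm(20, 0.2, 0.05)
    control <- rnorm(25, 0.2, 0.05)
    if (mannwhitney_site(case, control)$p_value < 0.05) hits <- hits + 1
  }
  rate <- hits / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
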