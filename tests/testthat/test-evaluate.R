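test_that("log-rank matches the hand O-E/V computation on a toy cohort", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 1, 1)
  grp <- c("a", "a", "b", "b")
  res <- km_logrank(times, events, grp)
  expect_equal(res$chisq, oracle_logrank(times, events, grp))
  expect_equal(res$df, 1L)
  expect_true(all(res$curves$surv >= 0 & res$curves$surv <= 1))
  # survival curves are non-increasing within each group
  for (g in unique(res$curves$group)) {
    s <- res$curves$surv[res$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }

  # identical groups: statistic 0, p = 1
  res0 <- km_logrank(c(1, 2, 1, 2), c(1, 0, 1, 0), c("a", "a", "b", "b"))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)

  expect_error(km_logrank(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_error(km_logrank(c(1, 2), c(1, 1), c("a", "a")), "2 groups")
})

test_that("concordance index handles perfect, tied, and random score patterns", {
  times <- c(5, 3, 9, 1, 7); events <- rep(1, 5)
  expect_equal(concordance_index(-times, times, events), 1)
  expect_equal(concordance_index(rep(2, 5), times, events), 0.5)
  set.seed(61)
  for (i in 1:50) {
    inst <- random_survival_instance(sample(4:8, 1))
    ref <- suppressWarnings(oracle_cindex(inst$scores, inst$times,
                                          inst$events))
    if (!is.finite(ref)) next            # no comparable pairs drawn
    expect_equal(concordance_index(inst$scores, inst$times, inst$events),
                 ref)
  }
  expect_error(concordance_index(1, 5, 0), "comparable")
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(62)
  n <- 60
  sc <- rnorm(n); tm <- runif(n, 1, 100); ev <- rbinom(n, 1, 0.6)
  ours <- concordance_index(sc, tm, ev)
  ref <- survival::concordance(survival::Surv(tm, ev) ~ sc, reverse = TRUE)
  expect_equal(ours, unname(ref$concordance), tolerance = 1e-12)
})

test_that("response AUC equals pair counting and respects orientation", {
  expect_equal(response_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  set.seed(63)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:4, n, replace = TRUE)
    expect_equal(response_auc(s, y), oracle_auc(s, y))
  }
  # complement identity for tie-free scores
  s <- rnorm(20); y <- rep(c(0, 1), 10)
  expect_equal(response_auc(s, y) + response_auc(-s, y), 1)
  # clinical label vocabulary: CR/PR respond, SD/PD do not
  expect_equal(response_auc(c(1, 2, 3, 4), c("PD", "SD", "PR", "CR")), 1)
  expect_error(response_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("classification metrics reproduce a hand-computed confusion matrix", {
  # confusion TP=2, FP=1, FN=1, TN=6
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  scores <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  m <- classification_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$tp, 2); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 6)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)

  expect_equal(classification_metrics(c(0, 1), c(0, 1), 0.5)$accuracy, 1)

  # inverted predictor with flipped labels swaps sensitivity/specificity
  m2 <- classification_metrics(-scores, 1 - labels, threshold = -0.5)
  expect_equal(m2$sensitivity, m$specificity)
  expect_equal(m2$specificity, m$sensitivity)

  # degenerate cells give NA, not NaN
  m3 <- classification_metrics(c(0, 0), c(1, 1), threshold = 0.5)
  expect_true(is.na(m3$ppv))
  expect_false(any(is.nan(unlist(m3))))
})

test_that("time-dependent AUC reduces to binary AUC without censoring", {
  set.seed(64)
  n <- 120
  times <- runif(n, 0, 10); events <- rep(1, n)
  # perfect ordering: earlier failure, higher score
  td <- time_dependent_auc(-times, times, events, horizons = c(3, 6))
  expect_equal(td$auc, c(1, 1))
  # censoring-free case equals the plain AUC of (time <= t) vs score
  sc <- rnorm(n)
  td2 <- time_dependent_auc(sc, times, events, horizons = 5)
  expect_equal(td2$auc, oracle_auc(sc, as.integer(times <= 5)))
  # random scores, larger n: near 0.5
  set.seed(65)
  n2 <- 500
  t2 <- rexp(n2, 0.2); e2 <- rbinom(n2, 1, 0.7)
  td3 <- time_dependent_auc(rnorm(n2), t2, e2, horizons = quantile(t2, 0.5))
  expect_gt(td3$auc, 0.45); expect_lt(td3$auc, 0.55)
  expect_error(time_dependent_auc(sc, times, events, horizons = 99),
               "beyond")
})

test_that("baseline scores are z-scored single genes and bounded pair counts", {
  expr <- rbind(CD274 = c(1, 2, 3), PDCD1 = c(3, 1, 2), TCF7 = c(0, 0, 1),
                A = c(5, 1, 2), B = c(1, 5, 3))
  colnames(expr) <- paste0("s", 1:3)
  bl <- baseline_scores(expr)
  expect_equal(bl$PDL1, as.numeric(scale(expr["CD274", ])))
  # absent gene -> baseline skipped, others intact
  bl2 <- baseline_scores(expr, single_genes = c(X = "absent", PDL1 = "CD274"))
  expect_false("X" %in% colnames(bl2))
  expect_true("PDL1" %in% colnames(bl2))
  # pair baseline counts expr[a] > expr[b]
  bl3 <- baseline_scores(expr, single_genes = character(0),
                         pair_sets = list(pairs = rbind(c("A", "B"))))
  expect_equal(bl3$pairs, c(1, 0, 0))
  expect_true(all(bl3$pairs <= 1))
})

test_that("drug screen spots monotone drugs and flags degenerate ones", {
  set.seed(66)
  n <- 30
  sc <- setNames(rnorm(n), paste0("CL", 1:n))
  ic50 <- rbind(
    hit_up = rank(sc),                     # monotone increasing
    hit_down = -rank(sc),                  # monotone decreasing
    flat = rep(3, n),
    noise = rnorm(n)
  )
  colnames(ic50) <- names(sc)
  scr <- drug_screen(sc, ic50)
  expect_equal(scr$rho[scr$drug == "hit_up"], 1)
  expect_equal(scr$rho[scr$drug == "hit_down"], -1)
  expect_true(scr$candidate[scr$drug == "hit_up"])
  expect_true(scr$degenerate[scr$drug == "flat"])
  expect_false(scr$candidate[scr$drug == "flat"])
  expect_error(drug_screen(sc[1:5], ic50[, 1:5]), "10 shared")
})

test_that("ORR comparison reports rates and both tests", {
  set.seed(67)
  groups <- rep(c("low", "high"), each = 30)
  y <- c(rbinom(30, 1, 0.7), rbinom(30, 1, 0.2))
  sc <- rnorm(60) + (1 - y)
  cmp <- orr_comparison(sc, groups, y)
  expect_gt(cmp$orr_low, cmp$orr_high)
  expect_lt(cmp$fisher_p, 0.05)
  expect_true(cmp$ranksum_p >= 0 && cmp$ranksum_p <= 1)
})
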