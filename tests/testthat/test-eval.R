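test_that("AUROC closed forms: perfect separation and all-tied scores", {
  perfect <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1), label = c(1, 1, 0, 0))
  expect_equal(auroc(perfect), 1)
  tied <- tibble::tibble(score = rep(0.5, 10), label = rep(c(0, 1), 5))
  expect_equal(auroc(tied), 0.5)
  expect_error(auroc(tibble::tibble(score = c(0.1, 0.2), label = c(1, 1))),
               "both classes")
})

test_that("AUROC and AUPRC match brute-force oracles on random cohorts", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(5:60, 1))
    cohort <- random_cohort(n, seed + 1000)
    expect_equal(auroc(cohort), auroc_oracle(cohort), tolerance = 1e-12)
    expect_equal(auprc(cohort), auprc_oracle(cohort), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  for (seed in c(2, 9, 41)) {
    cohort <- random_cohort(40, seed)
    ref <- as.numeric(pROC::auc(pROC::roc(cohort$label, cohort$score,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auroc(cohort), ref, tolerance = 1e-12)
  }
})

test_that("AUPRC closed forms: perfect separation and a flat classifier", {
  perfect <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1), label = c(1, 1, 0, 0))
  expect_equal(auprc(perfect), 1)
  flat <- tibble::tibble(score = rep(0.4, 20), label = rep(c(1, 0, 0, 0), 5))
  expect_equal(auprc(flat), 0.25)   # baseline precision = prevalence
  expect_error(auprc(tibble::tibble(score = 0.5, label = 0)), "positive")
})

test_that("bootstrap CI runs exactly n_boot evaluations, is seeded, brackets the point", {
  cohort <- random_cohort(40, 3)
  n_eval <- 0
  counting_auroc <- function(d) { n_eval <<- n_eval + 1; auroc(d) }
  ci <- bootstrap_ci(cohort, counting_auroc, n_boot = 2000, seed = 1)
  expect_equal(n_eval, 2000)
  expect_equal(attr(ci, "n_evaluations"), 2000)
  expect_lte(ci[1], auroc(cohort))
  expect_gte(ci[2], auroc(cohort))

  ci2 <- bootstrap_ci(cohort, auroc, n_boot = 200, seed = 1)
  ci3 <- bootstrap_ci(cohort, auroc, n_boot = 200, seed = 1)
  ci4 <- bootstrap_ci(cohort, auroc, n_boot = 200, seed = 2)
  expect_identical(as.numeric(ci2), as.numeric(ci3))
  expect_false(identical(as.numeric(ci2), as.numeric(ci4)))

  # degenerate cohort: constant metric collapses the interval
  cons <- bootstrap_ci(cohort, function(d) 0.42, n_boot = 50, seed = 1)
  expect_equal(as.numeric(cons), c(0.42, 0.42))
})

test_that("bootstrap CIs widen on average as the cohort shrinks", {
  width <- function(n) {
    mean(vapply(1:8, function(s) {
      ci <- bootstrap_ci(random_cohort(n, s, function(l) {
        pmin(pmax(0.3 + 0.2 * l + runif(length(l)) * 0.4, 0), 1)
      }), auroc, n_boot = 200, seed = s)
      ci[2] - ci[1]
    }, numeric(1)))
  }
  expect_gt(width(15), width(150))
})

test_that("Youden cutoff matches an exhaustive sweep and its closed forms", {
  # perfect separation: the midpoint threshold reaches J = 1
  sep <- tibble::tibble(score = c(0.8, 0.9, 0.1, 0.2), label = c(1, 1, 0, 0))
  cut <- youden_cutoff(sep)
  expect_equal(cut, 0.5)
  cm <- confusion_metrics(sep, cut)
  expect_equal(cm$sensitivity + cm$specificity - 1, 1)

  # all scores equal: degenerate threshold with J = 0
  same <- tibble::tibble(score = rep(0.3, 8), label = rep(c(0, 1), 4))
  expect_equal(youden_cutoff(same), 0.3)

  # random cohorts against the sweep oracle
  for (seed in 1:25) {
    cohort <- random_cohort(20, seed + 50)
    s <- sort(unique(cohort$score))
    cand <- (s[-length(s)] + s[-1]) / 2
    J <- vapply(cand, function(t) {
      pred <- cohort$score >= t
      mean(pred[cohort$label == 1]) + mean(!pred[cohort$label == 0]) - 1
    }, numeric(1))
    best <- cand[J == max(J)]
    got <- youden_cutoff(cohort)
    expect_true(got %in% best)
    expect_equal(got, max(best))   # tie-break toward higher specificity
  }
})

test_that("confusion metrics follow the 2x2 definitions", {
  cohort <- tibble::tibble(
    score = c(rep(0.9, 9), 0.1, rep(0.05, 9), 0.8),
    label = c(rep(1, 10), rep(0, 10)))
  cm <- confusion_metrics(cohort, 0.5)
  expect_equal(cm$accuracy, 0.9)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$ppv, 0.9)
  expect_equal(cm$npv, 0.9)

  all_pos <- confusion_metrics(cohort, 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)

  for (seed in 1:10) {
    d <- random_cohort(30, seed + 300)
    cm2 <- confusion_metrics(d, 0.5)
    tp <- sum(d$score >= 0.5 & d$label == 1)
    fp <- sum(d$score >= 0.5 & d$label == 0)
    tn <- sum(d$score < 0.5 & d$label == 0)
    fn <- sum(d$score < 0.5 & d$label == 1)
    expect_equal(cm2$accuracy, (tp + tn) / 30)
    if (tp + fp > 0) expect_equal(cm2$ppv, tp / (tp + fp))
  }
})

test_that("per-category breakdown counts multi-category images once overall", {
  cohort <- tibble::tibble(
    score = c(0.9, 0.9, 0.2, 0.9, 0.1, 0.9),
    label = c(1, 1, 1, 1, 0, 1),
    categories = c("hip_fracture", "hip_fracture;dislocation", "dislocation",
                   "pelvic_area_fracture", "", "hip_fracture"))
  tab <- per_category_breakdown(cohort, 0.5)
  overall <- tab[tab$category == "overall", ]
  expect_equal(overall$n, 5)          # 5 positive images
  expect_equal(overall$n_detected, 4)
  expect_equal(overall$n_missed, 1)
  hip <- tab[tab$category == "hip_fracture", ]
  expect_equal(hip$n, 3)
  expect_equal(hip$sensitivity, 1)
  dis <- tab[tab$category == "dislocation", ]
  expect_equal(dis$n, 2)
  expect_equal(dis$n_detected, 1)
  expect_equal(dis$sensitivity, 0.5)

  # all detected: every sensitivity is 1
  allpos <- tibble::tibble(score = rep(1, 4), label = rep(1, 4),
                           categories = rep("hip_fracture", 4))
  tab2 <- per_category_breakdown(allpos, 0.5)
  expect_true(all(tab2$sensitivity == 1))
})

test_that("McNemar exact branch equals the binomial closed form and is symmetric", {
  truth <- rep(1, 20)
  a <- rep(1, 20)
  expect_equal(mcnemar_test(a, a, truth)$p_value, 1.0)

  # b = 10, c = 0: exact p = 2 * 0.5^10
  b10 <- c(rep(1, 10), rep(0, 10))
  c0 <- rep(0, 20)
  truth2 <- c(rep(1, 10), rep(0, 10))
  # A right on first 10 (B wrong there); both wrong on rest? craft directly:
  calls_a <- truth2
  calls_b <- 1 - truth2
  # A right everywhere, B wrong everywhere -> b = 20; restrict to 10 cases
  r <- mcnemar_test(calls_a[1:10], calls_b[1:10], truth2[1:10])
  expect_equal(r$b, 10); expect_equal(r$c, 0)
  expect_equal(r$p_value, 2 * 0.5^10, tolerance = 1e-12)

  # b = 5, c = 3 against an independent exact binomial computation
  truth3 <- rep(1, 12)
  ca <- c(rep(1, 5), rep(0, 3), rep(1, 4))
  cb <- c(rep(0, 5), rep(1, 3), rep(1, 4))
  r2 <- mcnemar_test(ca, cb, truth3)
  expect_equal(r2$b, 5); expect_equal(r2$c, 3)
  pk <- sum(vapply(c(0:3, 5:8), function(k) choose(8, k) * 0.5^8, numeric(1)))
  expect_equal(r2$p_value, pk, tolerance = 1e-12)
  r2r <- mcnemar_test(cb, ca, truth3)
  expect_equal(r2$p_value, r2r$p_value)

  # asymptotic branch: agrees with stats::mcnemar.test on the 2x2
  truth4 <- rep(1, 60)
  ca4 <- c(rep(1, 20), rep(0, 15), rep(1, 25))
  cb4 <- c(rep(0, 20), rep(1, 15), rep(1, 25))
  r4 <- mcnemar_test(ca4, cb4, truth4)
  expect_equal(r4$method, "chisq")
  ref <- stats::mcnemar.test(matrix(c(25, 20, 15, 0), 2, 2, byrow = TRUE))
  expect_equal(r4$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("evaluate_cohort assembles a coherent report", {
  cohort <- random_cohort(60, 12, function(l) {
    pmin(pmax(0.25 + 0.45 * l + rnorm(length(l), 0, 0.18), 0), 1)
  })
  cohort$categories <- ifelse(cohort$label == 1, "hip_fracture", "")
  rep <- evaluate_cohort(cohort, n_boot = 100, seed = 5)
  m <- rep$metrics
  expect_true(all(m$ci_lower <= m$estimate + 1e-12))
  expect_true(all(m$estimate <= m$ci_upper + 1e-12))
  expect_true(all(m$estimate[!is.na(m$estimate)] >= 0 &
                    m$estimate[!is.na(m$estimate)] <= 1))
  expect_equal(glance(rep)$auroc, auroc(cohort))
  expect_s3_class(tidy(rep), "tbl_df")
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")

  dir <- withr::local_tempdir()
  write_eval_report(rep, file.path(dir, "r.json"), file.path(dir, "r.md"))
  js <- jsonlite::fromJSON(file.path(dir, "r.json"))
  expect_equal(js$cutoff, rep$cutoff)
  expect_true(file.exists(file.path(dir, "r.md")))
})

test_that("cohort CSVs round-trip", {
  dir <- withr::local_tempdir()
  cohort <- random_cohort(10, 2)
  cohort$image_id <- sprintf("img_%02d", 1:10)
  write_cohort(cohort, file.path(dir, "c.csv"))
  back <- read_cohort(file.path(dir, "c.csv"))
  expect_equal(back$score, cohort$score)
  expect_equal(back$label, cohort$label)
})
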