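#' Scored cohorts
#'
#' Evaluation functions operate on a *scored cohort*: a data frame with one
#' row per image, a `score` column in `[0, 1]`, a binary `label` column
#' (1 = trauma finding present), and optionally `image_id`, `categories`
#' (semicolon-separated finding categories) and `difficult` columns.
#'
#' @param cohort data frame with at least `score` and `label`.
#' @param require_both require both classes to be present.
#' @return The cohort, invisibly, after validation.
#' @keywords internal
validate_cohort <- function(cohort, require_both = TRUE) {
  if (!is.data.frame(cohort) || !all(c("score", "label") %in% names(cohort))) {
    abort("a scored cohort needs `score` and `label` columns.")
  }
  if (nrow(cohort) == 0) abort("empty cohort.")
  if (any(cohort$score < 0 | cohort$score > 1)) abort("scores must lie in [0, 1].")
  if (!all(cohort$label %in% c(0, 1))) abort("labels must be 0/1.")
  if (require_both && length(unique(cohort$label)) < 2) {
    abort("cohort must contain both classes.")
  }
  invisible(cohort)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability (ties count 1/2) via
#' average ranks; identical to trapezoidal integration of the empirical ROC
#' curve.
#'
#' @param cohort scored cohort (see [validate_cohort()]).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(cohort) {
  validate_cohort(cohort)
  r <- rank(cohort$score, ties.method = "average")
  n1 <- sum(cohort$label == 1)
  n0 <- sum(cohort$label == 0)
  (sum(r[cohort$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Area under the precision-recall step curve over all observed score
#' thresholds (no interpolation): `sum over thresholds of
#' (recall_i - recall_{i-1}) * precision_i`, sweeping thresholds from high to
#' low scores.
#'
#' @param cohort scored cohort with at least one positive.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(cohort) {
  validate_cohort(cohort, require_both = FALSE)
  if (sum(cohort$label == 1) == 0) abort("AUPRC needs at least one positive.")
  o <- order(cohort$score, decreasing = TRUE)
  s <- cohort$score[o]; y <- cohort$label[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each distinct score (threshold = that score)
  last <- which(!duplicated(s, fromLast = TRUE))
  P <- sum(y)
  recall <- tp[last] / P
  precision <- tp[last] / (tp[last] + fp[last])
  sum(diff(c(0, recall)) * precision)
}

#' Empirical ROC and PR curves
#'
#' @param cohort scored cohort.
#' @return Tibbles of curve coordinates over all observed thresholds.
#' @export
roc_curve <- function(cohort) {
  validate_cohort(cohort)
  thr <- sort(unique(cohort$score), decreasing = TRUE)
  rows <- lapply(c(Inf, thr), function(t) {
    pred <- cohort$score >= t
    tibble(threshold = t,
           tpr = mean(pred[cohort$label == 1]),
           fpr = mean(pred[cohort$label == 0]))
  })
  dplyr::bind_rows(rows)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(cohort) {
  validate_cohort(cohort, require_both = FALSE)
  thr <- sort(unique(cohort$score), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    pred <- cohort$score >= t
    tp <- sum(pred & cohort$label == 1)
    tibble(threshold = t, recall = tp / sum(cohort$label == 1),
           precision = tp / sum(pred))
  })
  dplyr::bind_rows(rows)
}

#' Percentile bootstrap confidence interval
#'
#' Case resampling with replacement; percentile 2.5/97.5 bounds over `n_boot`
#' replicates (the published battery uses 2000). Resamples on which the metric
#' is undefined because only one class was drawn are redrawn (the redraw count
#' is attached as an attribute); the metric is evaluated exactly `n_boot`
#' times. Deterministic per seed.
#'
#' @param cohort scored cohort.
#' @param metric function taking a cohort and returning a scalar.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param stratified resample within each class (preserving class counts).
#' @return Numeric `c(lower, upper)` with attributes `n_evaluations`,
#'   `n_redrawn` and `n_na` (replicates where the metric was undefined, e.g. a
#'   PPV with no positive calls; these are excluded from the percentiles).
#' @export
bootstrap_ci <- function(cohort, metric, n_boot = 2000, seed = 1,
                         stratified = FALSE) {
  validate_cohort(cohort, require_both = FALSE)
  n <- nrow(cohort)
  pos <- which(cohort$label == 1); neg <- which(cohort$label == 0)
  vals <- numeric(n_boot)
  n_eval <- 0L; n_redrawn <- 0L
  with_seed(derive_seed(seed, 424242), {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(1000)) {
        idx <- if (stratified) {
          c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
        } else sample.int(n, n, replace = TRUE)
        if (length(unique(cohort$label[idx])) == length(unique(cohort$label))) break
        n_redrawn <- n_redrawn + 1L
        if (try == 1000) abort("metric undefined on all resamples.")
      }
      vals[b] <- metric(cohort[idx, , drop = FALSE])
      n_eval <- n_eval + 1L
    }
  })
  if (all(is.na(vals))) abort("metric undefined on all resamples.")
  out <- unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE))
  attr(out, "n_evaluations") <- n_eval
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "n_na") <- sum(is.na(vals))
  out
}

#' Youden-J operating cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the midpoints between
#' consecutive distinct observed scores (a score at or above the cutoff is a
#' positive call). Ties are broken toward the higher threshold, i.e. toward
#' higher specificity. With a single distinct score the degenerate threshold
#' is that score (J = 0).
#'
#' @param cohort scored cohort with both classes.
#' @return The cutoff value.
#' @export
youden_cutoff <- function(cohort) {
  validate_cohort(cohort)
  s <- sort(unique(cohort$score))
  if (length(s) == 1) return(s)
  cand <- (s[-length(s)] + s[-1]) / 2
  J <- vapply(cand, function(t) {
    pred <- cohort$score >= t
    mean(pred[cohort$label == 1]) + mean(!pred[cohort$label == 0]) - 1
  }, numeric(1))
  best <- which(J >= max(J) - 1e-12)
  cand[max(best)]
}

#' Confusion metrics at a cutoff
#'
#' Standard 2x2 definitions with `score >= cutoff` as a positive call.
#'
#' @param cohort scored cohort.
#' @param cutoff finite threshold.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, plus the cell counts and `cutoff`.
#' @export
confusion_metrics <- function(cohort, cutoff) {
  validate_cohort(cohort, require_both = FALSE)
  if (!is.finite(cutoff)) abort("`cutoff` must be finite.")
  pred <- cohort$score >= cutoff
  y <- cohort$label == 1
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(accuracy = (tp + tn) / length(y),
         sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
         ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
         tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff)
}

cohort_category_list <- function(cohort) {
  if ("categories" %in% names(cohort)) {
    lapply(strsplit(ifelse(is.na(cohort$categories), "", cohort$categories), ";"),
           function(v) v[nzchar(v)])
  } else {
    rep(list(character(0)), nrow(cohort))
  }
}

#' Per-category detection breakdown
#'
#' Sensitivity among positive images carrying each finding category, plus an
#' overall row in which an image with multiple concurrent categories counts
#' exactly once.
#'
#' @param cohort scored cohort with a `categories` column
#'   (semicolon-separated).
#' @param cutoff decision threshold (`score >= cutoff` is a detection).
#' @return Tibble: `category`, `n`, `n_detected`, `n_missed`, `sensitivity`;
#'   first row is `"overall"`.
#' @export
per_category_breakdown <- function(cohort, cutoff) {
  validate_cohort(cohort, require_both = FALSE)
  pos <- cohort[cohort$label == 1, , drop = FALSE]
  det <- pos$score >= cutoff
  cats <- cohort_category_list(pos)
  all_cats <- sort(unique(unlist(cats)))
  rows <- list(tibble(category = "overall", n = nrow(pos),
                      n_detected = sum(det), n_missed = sum(!det),
                      sensitivity = if (nrow(pos)) mean(det) else NA_real_))
  for (cc in all_cats) {
    has <- vapply(cats, function(v) cc %in% v, logical(1))
    rows[[length(rows) + 1]] <- tibble(
      category = cc, n = sum(has), n_detected = sum(det[has]),
      n_missed = sum(!det[has]), sensitivity = mean(det[has]))
  }
  dplyr::bind_rows(rows)
}

#' McNemar's paired comparison of two classifiers
#'
#' Correctness indicators (`call == truth`) define the discordant counts
#' `b` (A right, B wrong) and `c` (A wrong, B right). With `b + c` below
#' `exact_threshold` the exact two-sided binomial test of `b` against
#' `Binomial(b + c, 1/2)` is used; otherwise the chi-square test with
#' continuity correction. Zero discordance gives p = 1.
#'
#' @param calls_a,calls_b binary (or logical) call vectors.
#' @param truth binary truth vector of the same length.
#' @param exact_threshold switch point between the exact and asymptotic
#'   branches (default 25).
#' @return List with `b`, `c`, `method`, `p_value`.
#' @export
mcnemar_test <- function(calls_a, calls_b, truth, exact_threshold = 25) {
  if (length(calls_a) != length(truth) || length(calls_b) != length(truth)) {
    abort("call vectors and truth must have equal lengths.")
  }
  ra <- as.integer(calls_a) == as.integer(truth)
  rb <- as.integer(calls_b) == as.integer(truth)
  b <- sum(ra & !rb)
  c_ <- sum(!ra & rb)
  if (b + c_ == 0) {
    return(list(b = b, c = c_, method = "none", p_value = 1.0))
  }
  if (b + c_ < exact_threshold) {
    p <- stats::binom.test(b, b + c_, p = 0.5)$p.value
    list(b = b, c = c_, method = "exact", p_value = min(1, p))
  } else {
    tab <- matrix(c(sum(ra & rb), b, c_, sum(!ra & !rb)), 2, 2, byrow = TRUE)
    p <- stats::mcnemar.test(tab, correct = TRUE)$p.value
    list(b = b, c = c_, method = "chisq", p_value = p)
  }
}

#' Full evaluation report for a scored cohort
#'
#' Computes AUROC and AUPRC with percentile-bootstrap 95% CIs, the operating
#' cutoff (Youden-J on this cohort unless a literal value is supplied),
#' accuracy/sensitivity/specificity/PPV/NPV with bootstrap CIs at that cutoff,
#' and the per-category detection breakdown.
#'
#' @param cohort scored cohort.
#' @param cutoff literal cutoff; `NULL` selects the Youden-J cutoff.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @return An `eval_report`; see [tidy.eval_report()], [glance.eval_report()],
#'   [autoplot.eval_report()], [write_eval_report()].
#' @export
evaluate_cohort <- function(cohort, cutoff = NULL, n_boot = 2000, seed = 1) {
  validate_cohort(cohort)
  if (is.null(cutoff)) cutoff <- youden_cutoff(cohort)
  metrics <- list(
    auroc = auroc,
    auprc = auprc,
    accuracy = function(d) confusion_metrics(d, cutoff)$accuracy,
    sensitivity = function(d) confusion_metrics(d, cutoff)$sensitivity,
    specificity = function(d) confusion_metrics(d, cutoff)$specificity,
    ppv = function(d) confusion_metrics(d, cutoff)$ppv,
    npv = function(d) confusion_metrics(d, cutoff)$npv)
  rows <- lapply(seq_along(metrics), function(i) {
    f <- metrics[[i]]
    est <- f(cohort)
    ci <- bootstrap_ci(cohort, f, n_boot = n_boot, seed = derive_seed(seed, i))
    tibble(metric = names(metrics)[i], estimate = est,
           ci_lower = min(ci[1], est, na.rm = TRUE),
           ci_upper = max(ci[2], est, na.rm = TRUE))
  })
  structure(list(metrics = dplyr::bind_rows(rows), cutoff = cutoff,
                 per_category = per_category_breakdown(cohort, cutoff),
                 confusion = confusion_metrics(cohort, cutoff),
                 n = nrow(cohort), n_pos = sum(cohort$label == 1),
                 n_boot = n_boot, cohort = as_tibble(cohort)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d (%d positive), cutoff = %.4f\n",
              x$n, x$n_pos, x$cutoff))
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_cohort
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' @rdname evaluate_cohort
#' @export
glance.eval_report <- function(x, ...) {
  est <- function(m) x$metrics$estimate[x$metrics$metric == m]
  tibble(n = x$n, n_pos = x$n_pos, cutoff = x$cutoff,
         auroc = est("auroc"), auprc = est("auprc"),
         accuracy = est("accuracy"), sensitivity = est("sensitivity"),
         specificity = est("specificity"))
}

#' @rdname evaluate_cohort
#' @param object an `eval_report`.
#' @importFrom ggplot2 geom_path geom_abline geom_point facet_wrap
#' @export
autoplot.eval_report <- function(object, ...) {
  roc <- roc_curve(object$cohort)
  pr <- pr_curve(object$cohort)
  df <- dplyr::bind_rows(
    tibble(x = roc$fpr, y = roc$tpr, curve = "ROC"),
    tibble(x = pr$recall, y = pr$precision, curve = "Precision-Recall"))
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_path() +
    facet_wrap(~curve) +
    labs(x = "FPR / recall", y = "TPR / precision") +
    theme_minimal()
}

#' Write an evaluation report as JSON and Markdown
#'
#' @param report an `eval_report`.
#' @param json_path,md_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n = report$n, n_pos = report$n_pos, cutoff = report$cutoff,
           n_boot = report$n_boot, metrics = report$metrics,
           per_category = report$per_category),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(md_path)) {
    m <- report$metrics
    lines <- c("| metric | estimate | 95% CI |", "|---|---|---|",
               sprintf("| %s | %.3f | %.3f-%.3f |", m$metric, m$estimate,
                       m$ci_lower, m$ci_upper),
               "", "| category | n | detected | missed | sensitivity |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %d | %d | %.3f |",
                       report$per_category$category, report$per_category$n,
                       report$per_category$n_detected,
                       report$per_category$n_missed,
                       report$per_category$sensitivity))
    writeLines(lines, md_path)
  }
  invisible(c(json_path, md_path))
}

#' Read / write scored-cohort CSVs
#'
#' Columns: `image_id`, `score`, `label`, optional `categories`
#' (semicolon-separated) and `difficult`.
#'
#' @param cohort scored cohort tibble.
#' @param path CSV path.
#' @return `read_cohort()`: a tibble; `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
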