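# Shared fixtures, built in code at test time.

# a small deterministic phantom with lesions
tiny_positive <- function(size = 128, n_lesions = 2, seed = 11) {
  ph <- generate_phantom(phantom_config(image_size = size), seed = seed)
  specs <- sample_lesion_specs(ph, n_lesions, seed = seed + 1)
  inject_lesions(ph, specs)
}

# random scored cohort with both classes guaranteed
random_cohort <- function(n, seed, score_fn = NULL) {
  withr::with_seed(seed, {
    label <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    score <- if (is.null(score_fn)) stats::runif(n) else score_fn(label)
    tibble::tibble(score = round(score, 3), label = label)
  })
}

# brute-force pairwise-concordance AUROC (ties count 1/2)
auroc_oracle <- function(cohort) {
  pos <- cohort$score[cohort$label == 1]
  neg <- cohort$score[cohort$label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive threshold-sweep AUPRC (step curve, high-to-low thresholds)
auprc_oracle <- function(cohort) {
  thr <- sort(unique(cohort$score), decreasing = TRUE)
  rec_prev <- 0; area <- 0
  for (t in thr) {
    pred <- cohort$score >= t
    tp <- sum(pred & cohort$label == 1)
    rec <- tp / sum(cohort$label == 1)
    prec <- tp / sum(pred)
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

# per-pixel high-precision BCE oracle (direct probability form)
bce_oracle <- function(logits_list, masks_list) {
  total <- 0
  for (k in seq_along(logits_list)) {
    P <- logits_list[[k]]; M <- masks_list[[k]]
    lk <- 0
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
      s <- 1 / (1 + exp(-P[i, j]))
      lk <- lk - (M[i, j] * log(s) + (1 - M[i, j]) * log(1 - s))
    }
    total <- total + lk / length(P)
  }
  total
}

# a constant-logit detector stub: zeroed parameters, head biases set so every
# level emits a constant logit
constant_logit_model <- function(logit, input_size = 64) {
  cfg <- model_config("tiny_fpn", input_size = input_size)
  m <- build_model(cfg, seed = 1)
  for (grp in c("enc", "lat", "head")) {
    for (l in seq_along(m$params[[grp]])) {
      m$params[[grp]][[l]]$W[] <- 0
      m$params[[grp]][[l]]$b[] <- 0
    }
  }
  for (l in seq_along(m$params$head)) m$params$head[[l]]$b[] <- logit
  m
}

# tiny 4-connected component counter (overlay red-region oracle)
image_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          r <- q[1] + d[1]; cc <- q[2] + d[2]
          if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  cur
}

# independent double-loop lattice oracle for disk membership
disk_count_oracle <- function(points, size, r) {
  cnt <- 0
  for (i in 0:(size - 1)) for (j in 0:(size - 1)) {
    for (k in seq_len(nrow(points))) {
      if ((j - points$x[k])^2 + (i - points$y[k])^2 <= r^2) {
        cnt <- cnt + 1
        break
      }
    }
  }
  cnt
}
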