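# Metrics, box statistics, and summaries.

test_that("confusion counts cross-tabulate with effect positive", {
  cc <- confusion(c("effect", "effect", "no_effect", "no_effect"),
                  c("effect", "no_effect", "effect", "no_effect"))
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  all_right <- confusion(rep("effect", 3), rep("effect", 3))
  expect_equal(all_right$fp + all_right$fn, 0)
  expect_error(confusion("effect", c("effect", "no_effect")), "mismatch")
})

test_that("metrics match the stated formulas and flag undefined ratios", {
  m <- metrics(list(tp = 9, tn = 8, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$tpr, 9 / 11)
  expect_equal(m$tnr, 8 / 9)
  m2 <- metrics(list(tp = 3, tn = 0, fp = 0, fn = 1))
  expect_equal(m2$tpr, 0.75)
  expect_true(is.na(m2$tnr))
  expect_identical(m2$undefined, "tnr")
  expect_error(metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "no evaluated")
})

test_that("metrics agree with brute-force recounts on random sets", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(10:200, 1)
    pred <- sample(c("effect", "no_effect"), n, TRUE)
    lab <- sample(c("effect", "no_effect"), n, TRUE)
    oc <- oracle_confusion(pred, lab)
    cc <- confusion(pred, lab)
    expect_equal(unlist(cc), oc[names(unlist(cc))])
    m <- metrics(cc)
    expect_equal(m$accuracy, mean(pred == lab))
    # permutation invariance of paired (pred, label) order
    p <- sample(n)
    expect_equal(metrics(confusion(pred[p], lab[p]))$accuracy, m$accuracy)
  }
})

test_that("box statistics follow the 1.5 IQR whisker convention", {
  b <- box_stats(c(0, 0, 0.2, 0.4, 0.6))
  expect_equal(b$median, 0.2)
  expect_equal(b$q25, unname(quantile(c(0, 0, 0.2, 0.4, 0.6), 0.25)))

  cst <- box_stats(rep(1.3, 10))
  expect_equal(cst$q75 - cst$q25, 0)
  expect_equal(cst$whisker_low, 1.3)
  expect_equal(cst$whisker_high, 1.3)
  expect_length(cst$outliers, 0)

  set.seed(2)
  v <- c(rnorm(200), 8, -9)
  b2 <- box_stats(v)
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7)   # independent oracle
  expect_equal(b2$median, unname(q[2]))
  iqr <- q[3] - q[1]
  expect_true(all(b2$outliers < q[1] - 1.5 * iqr | b2$outliers > q[3] + 1.5 * iqr))
  inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
  expect_equal(b2$whisker_low, min(inside))
  expect_equal(b2$whisker_high, max(inside))
  expect_error(box_stats(numeric(0)), "at least one")
})

test_that("confidence-over-time groups follow the canonical grid", {
  set.seed(4)
  recs <- expand.grid(animal_id = sprintf("a%d", 1:4),
                      time_label = c("baseline", "30min", "150min"),
                      stringsAsFactors = FALSE)
  recs <- recs[rep(seq_len(nrow(recs)), each = 3), ]
  recs$treatment <- "KXN"
  recs$mean_latent_score <- runif(nrow(recs), 0, 2)
  ce <- runif(nrow(recs))
  preds <- data.frame(conf_effect = ce, conf_no_effect = 1 - ce,
                      hard_label = ifelse(ce >= .5, "effect", "no_effect"))
  ct <- confidence_over_time(preds, recs)
  expect_identical(ct$time_label, c("baseline", "30min", "150min"))
  for (i in seq_len(nrow(ct))) {
    sel <- recs$time_label == ct$time_label[i]
    expect_equal(ct$conf_median[i], median(ce[sel]))   # brute-force median
    expect_equal(ct$mgs_median[i], median(recs$mean_latent_score[sel]))
  }
  # constant-confidence group: median 1, zero IQR
  preds$conf_effect <- 1; preds$conf_no_effect <- 0
  ct2 <- confidence_over_time(preds, recs)
  expect_equal(ct2$conf_median, rep(1, 3))
  expect_equal(ct2$conf_q75 - ct2$conf_q25, rep(0, 3))
  # without any score column the MGS panel is omitted
  ct3 <- confidence_over_time(preds, recs[setdiff(names(recs),
                                                  "mean_latent_score")])
  expect_false("mgs_median" %in% names(ct3))
})

test_that("detection report counts accepted images per stage", {
  recs <- data.frame(accepted = c(rep(TRUE, 8), FALSE, FALSE),
                     source = c(rep("whole_face", 6), "parts_fallback",
                                "parts_fallback", "parts_fallback",
                                "parts_fallback"))
  rep1 <- detection_report(recs)
  expect_equal(rep1$overall, 0.8)
  expect_equal(rep1$stage1, 0.6)
  expect_equal(rep1$stage2, 2 / 4)
  all1 <- detection_report(data.frame(accepted = TRUE,
                                      source = "whole_face")[rep(1, 5), ])
  expect_equal(all1$overall, 1)
  expect_true(is.na(all1$stage2))
  expect_error(detection_report(recs[0, ]), "no detection")

  # random acceptance pattern matches a brute-force recount
  set.seed(12)
  r <- data.frame(accepted = sample(c(TRUE, FALSE), 100, TRUE),
                  source = sample(c("whole_face", "parts_fallback"), 100, TRUE))
  expect_equal(detection_report(r)$overall, mean(r$accepted))
})

test_that("fold summaries report mean and sample sd", {
  pf <- data.frame(fold_index = 1:2, accuracy = c(0.8, 1.0),
                   tpr = c(1, 1), tnr = c(0.6, 1))
  s <- grimscan:::summarize_folds(pf)
  expect_equal(s$summary$accuracy[["mean"]], 0.9)
  expect_equal(s$summary$accuracy[["sd"]], sd(c(0.8, 1)))
  expect_equal(s$summary$tpr[["sd"]], 0)
  # undefined ratios are excluded with a warning, not zeroed
  pf$tnr[2] <- NA
  expect_warning(s2 <- grimscan:::summarize_folds(pf), "excluded")
  expect_equal(s2$summary$tnr[["mean"]], 0.6)
})
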