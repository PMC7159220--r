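# Confusion-based metrics, cross-validation orchestration, cross-treatment
# matrices, and confidence-over-time summaries.

#' Confusion counts with "effect" as the positive class
#'
#' @param predictions,labels Character vectors in `{"effect", "no_effect"}`
#'   of equal length.
#' @return List of non-negative integers `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("length mismatch: ", length(predictions), " predictions vs ",
         length(labels), " labels", call. = FALSE)
  stopifnot(all(predictions %in% nn_classes), all(labels %in% nn_classes))
  list(tp = sum(predictions == "effect" & labels == "effect"),
       tn = sum(predictions == "no_effect" & labels == "no_effect"),
       fp = sum(predictions == "effect" & labels == "no_effect"),
       fn = sum(predictions == "no_effect" & labels == "effect"))
}

#' Accuracy, sensitivity (TPR), specificity (TNR) from confusion counts
#'
#' `accuracy = (tp + tn) / (tp + tn + fp + fn)`, `tpr = tp / (tp + fn)`,
#' `tnr = tn / (tn + fp)`. A zero denominator yields `NA` with the
#' corresponding name listed in the `undefined` field rather than an error
#' or a silent zero (single-animal test folds can contain one class only).
#'
#' @param counts Confusion counts from [confusion()].
#' @return List with `accuracy`, `tpr`, `tnr`, and character vector
#'   `undefined`.
#' @export
metrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("no evaluated units", call. = FALSE)
  undef <- character(0)
  tpr <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
         else { undef <- c(undef, "tpr"); NA_real_ }
  tnr <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp)
         else { undef <- c(undef, "tnr"); NA_real_ }
  list(accuracy = (counts$tp + counts$tn) / total, tpr = tpr, tnr = tnr,
       undefined = undef)
}

#' Subject-disjoint cross-validation of a classifier
#'
#' For each fold: the training portion is balanced by sub-sampling (the
#' test portion is left as-is; TPR/TNR absorb test-set imbalance), a fresh
#' model is trained, and accuracy/TPR/TNR are computed per image — and,
#' when `average_by` is set, additionally on confidence-averaged groups.
#' The summary reports mean and sample standard deviation (denominator
#' n - 1) over folds; folds where a ratio is undefined are excluded from
#' that ratio's mean with a warning.
#'
#' @param records Metadata data frame (`animal_id`, `binary_label`, ...).
#' @param folds Fold specs from [subject_kfold()] or
#'   [leave_one_animal_out()].
#' @param images Optional named list of in-memory images.
#' @param arch Architecture passed to [train_classifier()].
#' @param config A [train_config()].
#' @param average_by `NULL` for per-image evaluation, or metadata columns
#'   (e.g. `c("animal_id", "time_label")`) for confidence-averaged groups.
#' @param balance_seed Seed for per-fold balancing.
#' @return List with `per_fold` (data.frame) and `summary`
#'   (mean/sd per metric).
#' @export
cross_validate <- function(records, folds, images = NULL, arch = "own_cnn",
                           config = train_config(), average_by = NULL,
                           balance_seed = 1) {
  all_animals <- unique(records$animal_id)
  per_fold <- lapply(folds, function(f) {
    unknown <- setdiff(c(f$train_animals, f$test_animals), all_animals)
    if (length(unknown))
      stop("fold ", f$fold_index, " references unknown animal(s): ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    tr <- records[records$animal_id %in% f$train_animals, , drop = FALSE]
    te <- records[records$animal_id %in% f$test_animals, , drop = FALSE]
    tr <- balance_by_subsampling(tr, seed = derive_seed(balance_seed, "bal",
                                                        f$fold_index))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", f$fold_index)
    fit <- train_classifier(tr, images, arch, cfg)
    preds <- predict_records(fit, te, images)
    if (!is.null(average_by)) {
      grp <- average_group_confidence(preds, te, average_by)
      # group truth: the label is constant within (animal, time) groups
      key <- interaction(te[average_by], drop = TRUE, lex.order = TRUE)
      truth <- tapply(te$binary_label, key, function(v) v[1])
      m <- metrics(confusion(grp$hard_label, as.character(truth)))
    } else {
      m <- metrics(confusion(preds$hard_label, te$binary_label))
    }
    data.frame(fold_index = f$fold_index, accuracy = m$accuracy,
               tpr = m$tpr, tnr = m$tnr)
  })
  per_fold <- do.call(rbind, per_fold)
  summarize_folds(per_fold)
}

summarize_folds <- function(per_fold) {
  summ <- lapply(c("accuracy", "tpr", "tnr"), function(mname) {
    v <- per_fold[[mname]]
    if (anyNA(v))
      warning(sum(is.na(v)), " fold(s) excluded from ", mname,
              " summary (undefined ratio)", call. = FALSE)
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  })
  names(summ) <- c("accuracy", "tpr", "tnr")
  list(per_fold = per_fold, summary = summ)
}

#' Cross-treatment transfer accuracy matrix
#'
#' Trains one classifier per treatment (on a subject-disjoint training
#' split of that treatment, balanced by sub-sampling) and evaluates it on
#' every treatment's held-out animals, yielding the 3x3 accuracy matrix.
#' Diagonal cells are subject-disjoint by construction; off-diagonal cells
#' carry the subject-overlap flag from [cross_treatment_design()].
#'
#' @param design Specs from [cross_treatment_design()].
#' @param images Optional named in-memory image list.
#' @param arch,config As in [cross_validate()].
#' @param test_fraction Fraction of each treatment's animals held out.
#' @param seed Seed for the held-out animal choice.
#' @return List with `accuracy` (3x3 matrix, rows = train treatment),
#'   `subject_overlap` (logical 3x3), and `cells` (long data frame).
#' @export
cross_treatment_matrix <- function(design, images = NULL, arch = "own_cnn",
                                   config = train_config(),
                                   test_fraction = 0.25, seed = 1) {
  trs <- unique(vapply(design, `[[`, "", "train_treatment"))
  # one subject-disjoint holdout per treatment
  holdout <- lapply(setNames(trs, trs), function(tr) {
    recs <- design[[which(vapply(design, function(s)
      s$train_treatment == tr && s$test_treatment == tr, TRUE))]]$train_records
    animals <- unique(recs$animal_id)
    n_test <- max(1, round(test_fraction * length(animals)))
    test_a <- with_seed(derive_seed(seed, "holdout", tr),
                        sample(animals, n_test))
    list(train = recs[!recs$animal_id %in% test_a, , drop = FALSE],
         test = recs[recs$animal_id %in% test_a, , drop = FALSE])
  })
  fits <- lapply(setNames(trs, trs), function(tr) {
    trn <- balance_by_subsampling(holdout[[tr]]$train,
                                  seed = derive_seed(seed, "bal", tr))
    cfg <- config; cfg$seed <- derive_seed(config$seed, "ct", tr)
    train_classifier(trn, images, arch, cfg)
  })
  acc <- matrix(NA_real_, length(trs), length(trs), dimnames = list(trs, trs))
  so <- matrix(FALSE, length(trs), length(trs), dimnames = list(trs, trs))
  cells <- list()
  for (spec in design) {
    i <- spec$train_treatment; j <- spec$test_treatment
    te <- holdout[[j]]$test
    preds <- predict_records(fits[[i]], te, images)
    m <- metrics(confusion(preds$hard_label, te$binary_label))
    acc[i, j] <- m$accuracy
    so[i, j] <- spec$subject_overlap
    cells[[length(cells) + 1L]] <- data.frame(
      train = i, test = j, accuracy = m$accuracy, n_test = nrow(te),
      subject_overlap = spec$subject_overlap, stringsAsFactors = FALSE)
  }
  list(accuracy = acc, subject_overlap = so, cells = do.call(rbind, cells))
}

#' Box-plot statistics
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); whiskers are the most extreme data values no
#' further than 1.5 x IQR from the quartiles, and points beyond the
#' whiskers are listed as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @return List: `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(values) {
  if (length(values) == 0) stop("box_stats needs at least one value",
                                call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = values[values < lo | values > hi])
}

#' Effect-class confidence (and grimace score) over time
#'
#' Per (treatment, time point) box statistics of the effect-class
#' confidence, ordered along each treatment's canonical acquisition grid;
#' when the records carry a mean grimace score column it is summarized
#' alongside, mirroring the paired boxes of confidence-over-time figures.
#'
#' @param predictions Data frame from [predict_images()] aligned with
#'   `records`.
#' @param records Metadata rows (`treatment`, `time_label`, optionally
#'   `mean_mgs` or `mean_latent_score`).
#' @return Data frame: one row per (treatment, time_label) with confidence
#'   box statistics (and `mgs_*` columns when scores are present).
#' @export
confidence_over_time <- function(predictions, records) {
  if (nrow(predictions) != nrow(records))
    stop("predictions and records must align", call. = FALSE)
  mgs_col <- intersect(c("mean_mgs", "mean_latent_score"), names(records))[1]
  rows <- list()
  for (tr in intersect(names(treatment_time_grid),
                       unique(records$treatment))) {
    for (tl in intersect(treatment_time_grid[[tr]],
                         unique(records$time_label[records$treatment == tr]))) {
      sel <- records$treatment == tr & records$time_label == tl
      bs <- box_stats(predictions$conf_effect[sel])
      row <- data.frame(treatment = tr, time_label = tl, n = sum(sel),
                        conf_median = bs$median, conf_q25 = bs$q25,
                        conf_q75 = bs$q75, conf_whisker_low = bs$whisker_low,
                        conf_whisker_high = bs$whisker_high,
                        stringsAsFactors = FALSE)
      if (!is.na(mgs_col)) {
        ms <- box_stats(records[[mgs_col]][sel])
        row$mgs_median <- ms$median; row$mgs_q25 <- ms$q25
        row$mgs_q75 <- ms$q75
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Detection-rate report
#'
#' Per-stage and overall acceptance rates over detection results, computed
#' with exact integer counts before formatting.
#'
#' @param records Data frame with `accepted` (logical) and `source`
#'   (`"whole_face"` or `"parts_fallback"`) columns, one row per image.
#' @return List with `overall`, `stage1` (whole-face rate over all images),
#'   `stage2` (fall-back acceptance rate among stage-1 misses; `NA` if
#'   stage 1 accepted everything), and the underlying counts.
#' @export
detection_report <- function(records) {
  if (nrow(records) == 0) stop("no detection records", call. = FALSE)
  n <- nrow(records)
  s1 <- sum(records$accepted & records$source == "whole_face")
  s2_pool <- sum(records$source != "whole_face" | !records$accepted)
  s2 <- sum(records$accepted & records$source == "parts_fallback")
  list(overall = (s1 + s2) / n,
       stage1 = s1 / n,
       stage2 = if (s2_pool > 0) s2 / s2_pool else NA_real_,
       n = n, accepted = s1 + s2, stage1_accepted = s1, stage2_accepted = s2)
}
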