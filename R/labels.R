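# Binary label assignment, class balancing, and subject-disjoint splits.

#' Assign the binary effect label from treatment and acquisition time
#'
#' Time points at which group-level grimace scores were elevated carry the
#' label `"effect"`: 30 min after isoflurane anesthesia (IN); 30 and 150 min
#' after ketamine/xylazine anesthesia (KXN); 30, 150, and 300 min after
#' castration (C). Baselines, all later time points, and all untreated
#' records are `"no_effect"`. Unknown treatment/time pairs are a hard error,
#' never a silent `"no_effect"`.
#'
#' @param treatment Character vector of treatments.
#' @param time_label Character vector of time labels (recycled pairwise).
#' @return Character vector in `{"effect", "no_effect"}`.
#' @export
assign_binary_label <- function(treatment, time_label) {
  n <- max(length(treatment), length(time_label))
  treatment <- rep_len(treatment, n); time_label <- rep_len(time_label, n)
  mapply(function(tr, tl) {
    check_treatment_time(tr, tl)
    if (tl %in% effect_time_points[[tr]]) "effect" else "no_effect"
  }, treatment, time_label, USE.NAMES = FALSE)
}

#' Balance classes by sub-sampling the majority class
#'
#' Uniform sampling without replacement within the majority class; the
#' output is always a subset of the input and class counts come out exactly
#' equal. Deterministic given the seed.
#'
#' @param records Data frame with a `binary_label` column.
#' @param seed Integer seed.
#' @return The balanced subset (row order: original order within class).
#' @export
balance_by_subsampling <- function(records, seed = 1) {
  stopifnot(is.data.frame(records), "binary_label" %in% names(records))
  tab <- table(records$binary_label)
  for (cls in c("effect", "no_effect"))
    if (is.na(tab[cls]) || tab[cls] == 0)
      stop("cannot balance: class '", cls, "' absent", call. = FALSE)
  n_min <- min(tab)
  keep <- with_seed(seed, {
    unlist(lapply(names(tab), function(cls) {
      idx <- which(records$binary_label == cls)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  records[sort(keep), , drop = FALSE]
}

fold_spec <- function(fold_index, train_animals, test_animals) {
  stopifnot(length(intersect(train_animals, test_animals)) == 0)
  structure(list(fold_index = fold_index,
                 train_animals = train_animals,
                 test_animals = test_animals), class = "fold_spec")
}

#' Subject-disjoint k-fold split
#'
#' Animals (not images) are partitioned into k near-equal groups (sizes
#' differing by at most one); fold i tests group i and trains on all other
#' animals, so no individual ever contributes images to both sides of a
#' fold.
#'
#' @param records Data frame with an `animal_id` column.
#' @param k Number of folds.
#' @param seed Integer seed for the animal permutation.
#' @return List of `fold_spec` objects (`fold_index`, `train_animals`,
#'   `test_animals`).
#' @export
subject_kfold <- function(records, k = 10, seed = 1) {
  stopifnot(is.data.frame(records), "animal_id" %in% names(records))
  animals <- unique(records$animal_id)
  if (k > length(animals))
    stop("k = ", k, " exceeds the number of distinct animals (",
         length(animals), ")", call. = FALSE)
  perm <- with_seed(seed, sample(animals))
  grp <- rep(seq_len(k), length.out = length(perm))  # sizes differ by <= 1
  grp <- sort(grp)
  lapply(seq_len(k), function(i)
    fold_spec(i, perm[grp != i], perm[grp == i]))
}

#' Leave-one-animal-out split
#'
#' One fold per animal, testing all of that animal's images against a model
#' trained on all other animals.
#'
#' @inheritParams subject_kfold
#' @return List of `fold_spec` objects, one per animal.
#' @export
leave_one_animal_out <- function(records) {
  stopifnot(is.data.frame(records), "animal_id" %in% names(records))
  animals <- unique(records$animal_id)
  if (length(animals) < 2)
    stop("leave-one-animal-out needs at least 2 animals", call. = FALSE)
  lapply(seq_along(animals), function(i)
    fold_spec(i, animals[-i], animals[i]))
}

#' Cross-treatment experiment design
#'
#' Builds the full 3x3 matrix of (train treatment, test treatment)
#' experiment specs over IN, KXN, and C. For a fair comparison the KXN
#' subset is first sub-sampled at the animal level until its image count no
#' longer exceeds the larger of the two smaller subsets. Diagonal cells are
#' evaluated with subject-disjoint splits; off-diagonal cells carry a
#' subject-overlap flag when the same animal id appears in both treatments.
#'
#' @param records Data frame with `animal_id`, `treatment` columns; all of
#'   IN, KXN, C must be present.
#' @param seed Seed for the KXN sub-sampling.
#' @return List of specs: `train_treatment`, `test_treatment`,
#'   `train_records`, `test_records`, `subject_overlap`.
#' @export
cross_treatment_design <- function(records, seed = 1) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "treatment") %in% names(records)))
  trs <- c("IN", "KXN", "C")
  missing <- setdiff(trs, unique(records$treatment))
  if (length(missing))
    stop("missing treatment(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sub <- lapply(trs, function(tr) records[records$treatment == tr, , drop = FALSE])
  names(sub) <- trs
  target <- max(nrow(sub$IN), nrow(sub$C))
  if (nrow(sub$KXN) > target) {
    kxn_animals <- with_seed(seed, sample(unique(sub$KXN$animal_id)))
    keep <- character(0); n <- 0
    for (a in kxn_animals) {
      na <- sum(sub$KXN$animal_id == a)
      if (n + na > target && n > 0) break
      keep <- c(keep, a); n <- n + na
    }
    sub$KXN <- sub$KXN[sub$KXN$animal_id %in% keep, , drop = FALSE]
  }
  specs <- list()
  for (tr_train in trs) for (tr_test in trs) {
    overlap <- tr_train != tr_test &&
      length(intersect(unique(sub[[tr_train]]$animal_id),
                       unique(sub[[tr_test]]$animal_id))) > 0
    specs[[length(specs) + 1L]] <- list(
      train_treatment = tr_train, test_treatment = tr_test,
      train_records = sub[[tr_train]], test_records = sub[[tr_test]],
      subject_overlap = overlap)
  }
  specs
}

#' Serialize fold specs to a long-format data frame
#' @param folds List of fold specs from [subject_kfold()] or
#'   [leave_one_animal_out()].
#' @return Data frame with columns `fold_index`, `animal_id`, `role`.
#' @export
folds_to_table <- function(folds) {
  do.call(rbind, lapply(folds, function(f)
    data.frame(fold_index = f$fold_index,
               animal_id = c(f$train_animals, f$test_animals),
               role = rep(c("train", "test"),
                          c(length(f$train_animals), length(f$test_animals))),
               stringsAsFactors = FALSE)))
}
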