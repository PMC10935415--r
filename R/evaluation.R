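# Model evaluation: classification accuracy, screen precision
# (active-detected %) and database recall (hit rate), repeated
# stratified cross-validation, ROC/AUC by rank statistic, replicated
# train/internal-test splits with external validation, and learning
# curves.

#' Classification accuracy in percent
#'
#' `100 * (number correctly classified) / (total instances)`.
#'
#' @param predictions,truths equal-length label vectors.
#' @return Accuracy in percent.
#' @export
accuracy_pct <- function(predictions, truths) {
  if (!length(truths)) stop_param("empty input")
  if (length(predictions) != length(truths))
    stop_param("predictions and truths differ in length")
  100 * mean(predictions == truths)
}

#' Screen precision (active-detected %)
#'
#' `100 * TP / (TP + FP)`: the fraction of screen hits that are truly
#' active.
#'
#' @param tp,fp true- and false-positive counts.
#' @return Percentage, or an error when `TP + FP = 0` (no hits).
#' @export
active_detected_pct <- function(tp, fp) {
  if (tp + fp <= 0) stop_param("active_detected is undefined when TP + FP = 0")
  100 * tp / (tp + fp)
}

#' Database hit rate
#'
#' `100 * TP / A`, where `A` is the total number of active compounds
#' in the screened database.
#'
#' @param tp true-positive count.
#' @param a total actives in the database.
#' @return Percentage.
#' @export
hit_rate_pct <- function(tp, a) {
  if (a <= 0) stop_param("hit rate is undefined when A = 0")
  if (tp > a) stop_param("TP cannot exceed the number of actives")
  100 * tp / a
}

#' Confusion counts with "high" as the positive class
#'
#' @param predictions,truths label vectors.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predictions, truths) {
  c(TP = sum(predictions == "high" & truths == "high"),
    FP = sum(predictions == "high" & truths == "low"),
    TN = sum(predictions == "low" & truths == "low"),
    FN = sum(predictions == "low" & truths == "high"))
}

# stratified fold assignment: within each class, shuffled instances
# are dealt round-robin to folds
make_stratified_folds <- function(y, folds, seed) {
  withr::with_seed(seed, {
    fold_id <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_id
  })
}

#' Repeated stratified cross-validation
#'
#' Ten-fold cross-validation repeated with different random seeds; the
#' mean accuracy over repeats is the headline number.
#'
#' @param algorithm algorithm name for [fit_classifier()].
#' @param x descriptor data frame or matrix.
#' @param y activity labels.
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seeds optional integer vector of per-repeat seeds (length
#'   `repeats`); derived from `seed` when omitted.
#' @param seed root seed.
#' @param hyperparams passed to [fit_classifier()].
#' @return List: `cv_mean`, `cv_sd`, `per_repeat` (accuracy per
#'   repeat), `folds`, `repeats`.
#' @export
cross_validate <- function(algorithm, x, y, folds = 10L, repeats = 10L,
                           seeds = NULL, seed = 1L, hyperparams = list()) {
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  if (nrow(m) < folds) stop_param("need n >= folds")
  if (is.null(seeds))
    seeds <- derive_seed(seed, "cv") + seq_len(repeats)
  if (length(seeds) != repeats)
    stop_param("`seeds` must have length `repeats`")
  per_repeat <- vapply(seeds, function(s) {
    fold_id <- make_stratified_folds(y, folds, s)
    preds <- character(length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L)
        stop_param("a training fold lost one class; reduce `folds`")
      model <- fit_classifier(algorithm, m[tr, , drop = FALSE], y[tr],
                              hyperparams = hyperparams, seed = s)
      preds[!tr] <- predict(model, m[!tr, , drop = FALSE])
    }
    accuracy_pct(preds, y)
  }, numeric(1))
  list(cv_mean = mean(per_repeat), cv_sd = sd_pop(per_repeat),
       per_repeat = per_repeat, folds = folds, repeats = repeats)
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney rank statistic (ties get half credit),
#' which equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores, larger meaning more "high".
#' @param truths labels (`"high"` positive).
#' @return List: `auc`, and `curve` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truths) {
  truths <- check_labels(truths)
  pos <- truths == "high"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L)
    stop_param("ROC needs both classes present")
  r <- rank(scores)  # mean ranks handle ties with half credit
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # one curve point per distinct threshold
  last <- !duplicated(scores[ord], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n2), tpr = c(0, tp[last] / n1))
  list(auc = auc, curve = curve)
}

#' Replicated split modeling with external validation
#'
#' Generates `n_replicates` train/internal-test splits of the modeling
#' set (cluster-balanced 7:3), runs the descriptor selector and fits
#' the algorithm on each training set, and reports training (
#' resubstitution by default), internal-test and external-test
#' accuracies and AUCs.  The best replicate is the one with the
#' highest external accuracy (ties: higher external AUC, then lowest
#' replicate index); its external false positives are listed with
#' structures.
#'
#' @param dataset a `znbf_curated_dataset` from [split_dataset()] (the
#'   external split stays fixed across replicates).
#' @param descriptors descriptor data frame or matrix covering all
#'   entries.
#' @param algorithm algorithm name (default `"nb"`).
#' @param selector `NULL` for no selection, or one of `"cfs"`, `"gr"`,
#'   `"wrapper"`, `"cfs_wrapper"`.
#' @param n_replicates number of splits (default 10).
#' @param seeds optional per-replicate seeds.
#' @param seed root seed.
#' @param hyperparams passed to [fit_classifier()].
#' @param train_metric `"resubstitution"` (default) or `"cv"` for the
#'   training-set column.
#' @return List: `table` (one row per replicate with accuracies and
#'   AUCs), `best` (replicate index), `best_model`, `false_positives`
#'   (data frame), `selected_features` of the best replicate.
#' @export
replicate_splits <- function(dataset, descriptors, algorithm = "nb",
                             selector = "cfs_wrapper", n_replicates = 10L,
                             seeds = NULL, seed = 1L, hyperparams = list(),
                             train_metric = c("resubstitution", "cv")) {
  train_metric <- match.arg(train_metric)
  stopifnot(inherits(dataset, "znbf_curated_dataset"))
  m <- as_descriptor_matrix(descriptors)
  entries <- dataset$entries
  y_all <- setNames(entries$activity_class, entries$ligand_id)
  model_ids <- names(dataset$split_assignment)[
    dataset$split_assignment == "modeling"]
  ext_ids <- names(dataset$split_assignment)[
    dataset$split_assignment == "external_test"]
  if (is.null(seeds))
    seeds <- derive_seed(seed, "replicates") + seq_len(n_replicates)

  rows <- list()
  models <- list()
  feats <- list()
  for (r in seq_len(n_replicates)) {
    inner <- inner_split_cluster(model_ids, m, 0.7, seeds[r])
    tr_ids <- names(inner)[inner == "train"]
    it_ids <- names(inner)[inner == "internal_test"]
    res <- tryCatch({
      xtr <- m[tr_ids, , drop = FALSE]; ytr <- y_all[tr_ids]
      sel_names <- colnames(m)
      if (!is.null(selector)) {
        sel <- switch(selector,
                      cfs = cfs_select(xtr, ytr),
                      gr = gain_ratio_rank(xtr, ytr),
                      wrapper = wrapper_select(xtr, ytr, seed = seeds[r]),
                      cfs_wrapper = cfs_then_wrapper(xtr, ytr,
                                                     seed = seeds[r]),
                      stop_param("unknown selector '%s'", selector))
        if (length(sel$names)) sel_names <- sel$names
      }
      model <- fit_classifier(algorithm, xtr[, sel_names, drop = FALSE],
                              ytr, hyperparams = hyperparams,
                              seed = seeds[r])
      evalset <- function(ids) {
        p <- predict(model, m[ids, sel_names, drop = FALSE])
        s <- predict(model, m[ids, sel_names, drop = FALSE], type = "score")
        list(acc = accuracy_pct(p, y_all[ids]),
             auc = if (length(unique(y_all[ids])) == 2L)
               roc_auc(s, y_all[ids])$auc else NA_real_)
      }
      tr_perf <- if (train_metric == "resubstitution") evalset(tr_ids) else {
        cv <- cross_validate(algorithm, m[tr_ids, sel_names, drop = FALSE],
                             y_all[tr_ids], folds = 10L, repeats = 1L,
                             seed = seeds[r], hyperparams = hyperparams)
        list(acc = cv$cv_mean, auc = NA_real_)
      }
      it <- evalset(it_ids); ex <- evalset(ext_ids)
      models[[r]] <- model
      feats[[r]] <- sel_names
      data.frame(replicate = r, n_train = length(tr_ids),
                 n_internal = length(it_ids), n_external = length(ext_ids),
                 train_acc = tr_perf$acc, internal_acc = it$acc,
                 external_acc = ex$acc, train_auc = tr_perf$auc,
                 internal_auc = it$auc, external_auc = ex$auc)
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
              call. = FALSE)
      data.frame(replicate = r, n_train = NA, n_internal = NA,
                 n_external = NA, train_acc = NA, internal_acc = NA,
                 external_acc = NA, train_auc = NA, internal_auc = NA,
                 external_auc = NA)
    })
    rows[[r]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$external_acc))
  best <- ok[order(-tab$external_acc[ok], -tab$external_auc[ok],
                   tab$replicate[ok])][1]
  fp <- data.frame()
  if (length(best) && !is.na(best)) {
    preds <- predict(models[[best]],
                     m[ext_ids, feats[[best]], drop = FALSE])
    is_fp <- preds == "high" & y_all[ext_ids] == "low"
    fp <- entries[entries$ligand_id %in% ext_ids[is_fp],
                  c("ligand_id", "smiles", "lg_ki", "activity_class")]
  }
  list(table = tab, best = best, best_model = models[[best]],
       selected_features = feats[[best]], false_positives = fp)
}

#' Learning curve
#'
#' For each training fraction, subsamples the data (stratified,
#' seeded), trains on the subsample and scores the held-out remainder;
#' at fraction 1 a 10-fold CV estimate is substituted (there is no
#' held-out remainder).
#'
#' @inheritParams cross_validate
#' @param fractions training fractions in (0, 1] (default
#'   `seq(0.2, 1, 0.1)`).
#' @return Data frame: `fraction`, `mean_accuracy`, `sd_accuracy`.
#' @export
learning_curve <- function(algorithm, x, y, fractions = seq(0.2, 1, 0.1),
                           repeats = 5L, seed = 1L, hyperparams = list()) {
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  if (any(fractions <= 0 | fractions > 1))
    stop_param("fractions must lie in (0, 1]")
  rows <- lapply(fractions, function(fr) {
    accs <- vapply(seq_len(repeats), function(r) {
      s <- derive_seed(seed, "learning_curve") + 1000L * r
      if (fr == 1) {
        return(cross_validate(algorithm, m, y, folds = 10L, repeats = 1L,
                              seed = s, hyperparams = hyperparams)$cv_mean)
      }
      tr <- withr::with_seed(s, {
        unlist(lapply(unique(y), function(cls) {
          idx <- which(y == cls)
          sample(idx, max(1L, round(fr * length(idx))))
        }))
      })
      if (length(unique(y[tr])) < 2L)
        stop_param("fraction %.2f too small to contain both classes", fr)
      model <- fit_classifier(algorithm, m[tr, , drop = FALSE], y[tr],
                              hyperparams = hyperparams, seed = s)
      accuracy_pct(predict(model, m[-tr, , drop = FALSE]), y[-tr])
    }, numeric(1))
    data.frame(fraction = fr, mean_accuracy = mean(accs),
               sd_accuracy = sd_pop(accs))
  })
  do.call(rbind, rows)
}
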