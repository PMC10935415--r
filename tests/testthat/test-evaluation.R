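# Evaluation machinery: the three headline formulas, repeated
# stratified CV, rank-statistic AUC against a pairwise oracle,
# replicated splits with best-model selection, and learning curves.

test_that("accuracy is the exact correct fraction in percent", {
  p <- c(rep("high", 8), rep("low", 2))
  t8 <- c(rep("high", 8), rep("high", 2))
  expect_equal(accuracy_pct(p, t8), 80)
  expect_equal(accuracy_pct(p, p), 100)
  expect_equal(accuracy_pct(p, ifelse(p == "high", "low", "high")), 0)
  expect_error(accuracy_pct(character(0), character(0)), "empty")
  expect_error(accuracy_pct(p, t8[1:5]), "length")
})

test_that("active_detected is screen precision in percent", {
  expect_equal(active_detected_pct(3, 1), 75)
  expect_equal(active_detected_pct(5, 0), 100)
  expect_equal(active_detected_pct(0, 4), 0)
  expect_error(active_detected_pct(0, 0), "undefined")
})

test_that("hit rate is database recall in percent", {
  expect_equal(hit_rate_pct(3, 10), 30)
  expect_equal(hit_rate_pct(10, 10), 100)
  expect_equal(hit_rate_pct(0, 10), 0)
  expect_error(hit_rate_pct(1, 0), "undefined")
  expect_error(hit_rate_pct(11, 10), "exceed")
})

test_that("report metrics agree with confusion-matrix arithmetic", {
  for (s in 1:10) {
    n <- 30L
    pred <- withr::with_seed(s, sample(c("high", "low"), n, replace = TRUE))
    tru <- withr::with_seed(s + 50, sample(c("high", "low"), n,
                                           replace = TRUE))
    cc <- confusion_counts(pred, tru)
    expect_identical(sum(cc), n)
    expect_equal(accuracy_pct(pred, tru),
                 100 * (cc["TP"] + cc["TN"]) / n, ignore_attr = TRUE)
    if (cc["TP"] + cc["FP"] > 0)
      expect_equal(active_detected_pct(cc["TP"], cc["FP"]),
                   100 * cc["TP"] / (cc["TP"] + cc["FP"]),
                   ignore_attr = TRUE)
  }
})

test_that("stratified folds partition every instance once per repeat", {
  y <- c(rep("high", 23), rep("low", 17))
  for (s in 1:5) {
    f <- znscreen:::make_stratified_folds(y, 10, s)
    expect_identical(sort(unique(f)), 1:10)
    expect_identical(length(f), length(y))
    # each instance appears in exactly one test fold
    expect_identical(sum(tabulate(f)), length(y))
    # strata are balanced within one instance
    per_fold_high <- tapply(y == "high", f, sum)
    expect_lte(diff(range(per_fold_high)), 1)
  }
})

test_that("zeror cross-validates to the majority fraction", {
  tt <- make_toy_table(1, n = 100, p = 2)
  y <- c(rep("high", 63), rep("low", 37))
  cv <- cross_validate("zeror", tt$x[1:100, ], y, folds = 10, repeats = 3,
                       seed = 4)
  expect_equal(cv$cv_mean, 63, tolerance = 1)
})

test_that("cross-validation separates a strongly planted signal", {
  sp <- synthetic_spec(seed = 6, n_ligands = 200, effect_size = 3)
  lig <- generate_ligand_set(sp)
  base <- lig$ligands[is.na(lig$ligands$parent_id), ]
  dt <- generate_descriptor_table(sp, lig$ligands)
  keep <- match(base$ligand_id, dt$ligand_id)
  x <- dt[keep, c("ligand_id", electronic_descriptor_names())]
  cv <- cross_validate("nb", x, base$true_class, folds = 10, repeats = 2,
                       seed = 2)
  expect_gte(cv$cv_mean, 95)
})

test_that("identical seed lists reproduce cross-validation exactly", {
  tt <- make_toy_table(2, n = 60, p = 3, effect = 1)
  a <- cross_validate("nb", tt$x, tt$y, folds = 5, repeats = 3,
                      seeds = c(11, 12, 13))
  b <- cross_validate("nb", tt$x, tt$y, folds = 5, repeats = 3,
                      seeds = c(11, 12, 13))
  expect_identical(a, b)
})

test_that("roc_auc hits the perfect and reversed extremes", {
  y <- c(rep("high", 3), rep("low", 3))
  expect_equal(roc_auc(c(6, 5, 4, 3, 2, 1), y)$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6), y)$auc, 0)
  expect_error(roc_auc(1:3, rep("high", 3)), "both classes")
})

test_that("roc_auc equals the brute-force pairwise statistic with ties", {
  for (s in 1:25) {
    n1 <- withr::with_seed(s, sample(3:10, 1))
    n2 <- withr::with_seed(s + 1, sample(3:10, 1))
    scores <- withr::with_seed(s + 2,
                               sample(seq(0, 1, 0.1), n1 + n2,
                                      replace = TRUE))  # many ties
    y <- c(rep("high", n1), rep("low", n2))
    expect_equal(roc_auc(scores, y)$auc, oracle_auc_pairwise(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("replicate_splits reports one row per replicate", {
  sp <- synthetic_spec(seed = 3, n_ligands = 80, near_dup_rate = 0)
  lig <- generate_ligand_set(sp)
  dt <- generate_descriptor_table(sp, lig$ligands)
  cur <- curate_entries(lig$records, lig$ligands)
  ds <- split_dataset(cur$entries, descriptors = dt[
    match(cur$entries$ligand_id, dt$ligand_id), ], seed = 1)
  dsub <- dt[match(cur$entries$ligand_id, dt$ligand_id),
             c("ligand_id", electronic_descriptor_names())]
  reps <- replicate_splits(ds, dsub, algorithm = "nb", selector = NULL,
                           n_replicates = 4, seed = 2)
  expect_identical(nrow(reps$table), 4L)
  expect_true(reps$best %in% 1:4)
  expect_s3_class(reps$false_positives, "data.frame")
})

test_that("identically seeded replicates tie and selection returns the first", {
  sp <- synthetic_spec(seed = 4, n_ligands = 80, near_dup_rate = 0)
  lig <- generate_ligand_set(sp)
  dt <- generate_descriptor_table(sp, lig$ligands)
  cur <- curate_entries(lig$records, lig$ligands)
  ds <- split_dataset(cur$entries, seed = 1)
  dsub <- dt[match(cur$entries$ligand_id, dt$ligand_id),
             c("ligand_id", electronic_descriptor_names())]
  reps <- replicate_splits(ds, dsub, algorithm = "nb", selector = NULL,
                           n_replicates = 3, seeds = rep(99, 3))
  tab <- reps$table[, -1]
  expect_identical(tab[1, ], tab[2, ], ignore_attr = TRUE)
  expect_equal(unlist(tab[1, ]), unlist(tab[3, ]))
  expect_identical(reps$best, 1L)
})

test_that("learning curve has one row per fraction and rises with data", {
  sp <- synthetic_spec(seed = 5, n_ligands = 150, effect_size = 1.5)
  lig <- generate_ligand_set(sp)
  base <- lig$ligands[is.na(lig$ligands$parent_id), ]
  dt <- generate_descriptor_table(sp, lig$ligands)
  x <- dt[match(base$ligand_id, dt$ligand_id),
          c("ligand_id", electronic_descriptor_names())]
  lc <- learning_curve("nb", x, base$true_class,
                       fractions = c(0.2, 0.5, 1), repeats = 3, seed = 1)
  expect_identical(nrow(lc), 3L)
  expect_identical(lc$fraction, c(0.2, 0.5, 1))
  expect_gte(lc$mean_accuracy[3], lc$mean_accuracy[1] - 5)
  expect_error(learning_curve("nb", x, base$true_class, fractions = 1.5),
               "fractions")
})
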