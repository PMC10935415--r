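# Classifier contract: hand-checkable toys, decision-rule equivalence
# against independent brute-force oracles, and the stated invariants
# (posterior normalization, standardization invariance, min_obj
# monotonicity, attribute-selection pass-through).

test_that("zeror predicts the majority class everywhere", {
  x <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(rep("high", 7), rep("low", 3))
  m <- fit_classifier("zeror", x, y)
  q <- matrix(c(-100, 0, 100), ncol = 1, dimnames = list(NULL, "f"))
  expect_identical(predict(m, q), rep("high", 3))
  expect_equal(predict(m, q, type = "score"), rep(0.7, 3))
})

test_that("j48 with min_obj >= n degenerates to a single majority leaf", {
  tt <- make_toy_table(1, n = 12, p = 2, effect = 2)
  expect_warning(m <- fit_classifier("j48", tt$x, tt$y,
                                     list(min_obj = 12L)), "single leaf")
  expect_identical(m$fitted$tree$type, "leaf")
  q <- tt$x
  expect_identical(unique(predict(m, q)), znscreen:::majority_label(tt$y))
})

test_that("nb on a symmetric toy puts the boundary at zero", {
  x <- matrix(c(-1, -1.2, -0.8, 1, 1.2, 0.8), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c("high", "high", "high", "low", "low", "low")
  m <- fit_classifier("nb", x, y)
  q0 <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(predict(m, q0, type = "score"), 0.5, tolerance = 1e-10)
  q <- matrix(c(-0.5, 0.5), ncol = 1, dimnames = list(NULL, "f"))
  expect_identical(predict(m, q), c("high", "low"))
})

test_that("nb posterior follows Bayes' rule on a constructed model", {
  # priors 0.6 / 0.4; class densities at the query engineered to be
  # 0.5 and 0.1 => posterior(high) = 0.3 / 0.34 = 0.882
  sd_for_density <- function(d) 1 / (d * sqrt(2 * pi))
  fitted <- list(
    high = list(prior = 0.6, mean = c(f = 0), sd = c(f = sd_for_density(0.5))),
    low = list(prior = 0.4, mean = c(f = 0), sd = c(f = sd_for_density(0.1))))
  model <- structure(list(algorithm = "nb", hyperparams = list(),
                          feature_names = "f", fitted = fitted,
                          classes = c("high", "low")),
                     class = c("znbf_nb", "znbf_model"))
  q <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(predict(model, q, type = "score"),
               0.6 * 0.5 / (0.6 * 0.5 + 0.4 * 0.1), tolerance = 1e-10)
  expect_equal(predict(model, q, type = "score"), 0.882, tolerance = 1e-3)
})

test_that("nb posteriors sum to one and are monotone in the prior", {
  tt <- make_toy_table(2, n = 30, p = 3, effect = 1)
  m <- fit_classifier("nb", tt$x, tt$y)
  post <- znscreen:::nb_posterior(m$fitted, tt$x)
  expect_equal(unname(rowSums(post)), rep(1, nrow(tt$x)), tolerance = 1e-12)
  # raise the high prior at fixed likelihoods: posterior(high) rises
  f2 <- m$fitted
  f2$high$prior <- 0.9
  f2$low$prior <- 0.1
  post2 <- znscreen:::nb_posterior(f2, tt$x)
  expect_true(all(post2[, "high"] >= post[, "high"] - 1e-12))
})

test_that("ibk nails k = 1 on a training point and k = n gives the majority", {
  x <- matrix(c(0, 1, 2, 3, 10), ncol = 1, dimnames = list(NULL, "f"))
  y <- c("high", "high", "low", "low", "low")
  m1 <- fit_classifier("ibk", x, y, list(k = 1))
  expect_identical(predict(m1, x[2, , drop = FALSE]), "high")
  mn <- fit_classifier("ibk", x, y, list(k = 5))
  q <- matrix(c(-50, 50), ncol = 1, dimnames = list(NULL, "f"))
  expect_identical(predict(mn, q), c("low", "low"))
  expect_error(fit_classifier("ibk", x, y, list(k = 6)), "k <= n")
})

test_that("ibk is invariant to feature order and affine rescaling", {
  tt <- make_toy_table(3, n = 40, p = 3, effect = 1)
  q <- make_toy_table(103, n = 10, p = 3)$x
  m <- fit_classifier("ibk", tt$x, tt$y, list(k = 3))
  base <- predict(m, q)
  # permuted columns
  perm <- c(3, 1, 2)
  m_p <- fit_classifier("ibk", tt$x[, perm], tt$y, list(k = 3))
  expect_identical(predict(m_p, q[, perm]), base)
  # common affine rescale of one feature (min-max standardization
  # removes it)
  x_s <- tt$x; x_s[, 2] <- 100 * x_s[, 2] - 7
  q_s <- q; q_s[, 2] <- 100 * q_s[, 2] - 7
  m_s <- fit_classifier("ibk", x_s, tt$y, list(k = 3))
  expect_identical(predict(m_s, q_s), base)
})

test_that("j48_best_split matches hand entropy on the canonical toy", {
  s <- j48_best_split(c(1, 2, 3, 4), c("high", "high", "low", "low"),
                      min_obj = 1)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 1, tolerance = 1e-12)       # one full bit
  expect_equal(s$gain_ratio, 1, tolerance = 1e-12)
  expect_null(j48_best_split(c(1, 2, 3, 4), rep("high", 4)))
  expect_null(j48_best_split(rep(2, 5), c("high", "high", "low", "low",
                                          "low")))
})

test_that("j48_best_split equals the brute-force midpoint maximizer", {
  for (s in 1:20) {
    col <- withr::with_seed(s, round(rnorm(20), 1))
    y <- withr::with_seed(s + 1000,
                          sample(c("high", "low"), 20, replace = TRUE))
    if (length(unique(y)) < 2) next
    got <- j48_best_split(col, y, min_obj = 2)
    want <- oracle_best_split(col, y, min_obj = 2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-10)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("j48 training accuracy is non-increasing in min_obj", {
  for (s in 1:8) {
    n <- 60
    x <- withr::with_seed(s, matrix(rnorm(n * 3), n, 3,
                                    dimnames = list(NULL, paste0("f", 1:3))))
    y <- withr::with_seed(s + 30,
                          ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.8) > 0,
                                 "high", "low"))
    if (length(unique(y)) < 2) next
    accs <- vapply(c(2L, 4L, 8L, 16L), function(mo) {
      m <- fit_classifier("j48", x, y, list(min_obj = mo, pruned = FALSE))
      accuracy_pct(predict(m, x), y)
    }, numeric(1))
    expect_true(all(diff(accs) <= 1e-9))
  }
})

test_that("oner picks the lowest-error single-feature rule", {
  tt <- make_toy_table(4, n = 60, p = 3, effect = 0)
  x <- tt$x
  x[, 2] <- ifelse(tt$y == "high", 1, 0) + rnorm(60, 0, 0.01)
  m <- fit_classifier("oner", x, tt$y)
  expect_identical(m$fitted$feature, 2L)
  expect_lte(m$fitted$error, 0.05)
})

test_that("asc with the pass-through selector reproduces its base learner", {
  tt <- make_toy_table(5, n = 50, p = 4, effect = 1)
  q <- make_toy_table(105, n = 15, p = 4)$x
  for (alg in c("nb", "ibk", "j48")) {
    base <- fit_classifier(alg, tt$x, tt$y, list(k = 3, min_obj = 2))
    asc <- fit_classifier(paste0("asc_", alg), tt$x, tt$y,
                          list(k = 3, min_obj = 2, selector = "all"))
    expect_identical(predict(asc, q), predict(base, q))
  }
})

test_that("asc restricts itself to CFS-selected features", {
  tt <- make_toy_table(6, n = 80, p = 6, effect = 2)
  m <- fit_classifier("asc_nb", tt$x, tt$y)
  expect_true(all(m$fitted$selected %in% colnames(tt$x)))
  expect_lte(length(m$fitted$selected), ncol(tt$x))
})

test_that("every learner matches its brute-force oracle on random toys", {
  agree <- TRUE
  for (s in 1:40) {
    tt <- make_toy_table(s + 700, n = withr::with_seed(s, sample(8:20, 1)),
                         p = 2, effect = withr::with_seed(s + 1, runif(1, 0, 2)))
    if (length(unique(tt$y)) < 2) next
    q <- make_toy_table(s + 800, n = 6, p = 2)$x
    k <- withr::with_seed(s + 2, sample(1:3, 1))
    m_nb <- fit_classifier("nb", tt$x, tt$y)
    m_ib <- fit_classifier("ibk", tt$x, tt$y, list(k = k))
    m_j <- fit_classifier("j48", tt$x, tt$y, list(min_obj = 2))
    m_or <- fit_classifier("oner", tt$x, tt$y, list(min_bucket = 3))
    m_zr <- fit_classifier("zeror", tt$x, tt$y)
    agree <- agree &&
      identical(unname(predict(m_nb, q)),
                unname(oracle_nb_predict(tt$x, tt$y, q))) &&
      identical(unname(predict(m_ib, q)),
                unname(oracle_ibk_predict(tt$x, tt$y, q, k))) &&
      identical(unname(predict(m_j, q)),
                unname(oracle_tree_predict(m_j$fitted$tree, q))) &&
      identical(unname(predict(m_or, q)),
                unname(oracle_oner_predict(m_or$fitted, q))) &&
      identical(unname(predict(m_zr, q)),
                unname(oracle_zeror_predict(tt$y, nrow(q))))
  }
  expect_true(agree)
})

test_that("fit rejects malformed inputs", {
  tt <- make_toy_table(7, n = 10, p = 2)
  expect_error(fit_classifier("svm", tt$x, tt$y), "unknown algorithm")
  expect_error(fit_classifier("nb", tt$x, tt$y[1:5]), "labels")
  expect_error(fit_classifier("nb", tt$x, rep("high", 10)), "both classes")
  m <- fit_classifier("nb", tt$x, tt$y)
  bad <- matrix(0, 1, 1, dimnames = list(NULL, "zzz"))
  expect_error(predict(m, bad), "lacks model features")
})

test_that("models serialize to JSON", {
  tt <- make_toy_table(8, n = 20, p = 2, effect = 1)
  m <- fit_classifier("j48", tt$x, tt$y, list(min_obj = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$algorithm, "j48")
  expect_identical(unlist(back$feature_names), colnames(tt$x))
})
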