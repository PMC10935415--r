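# The eight classification algorithms under one training/prediction
# contract: Gaussian naive Bayes (nb), k-nearest neighbours on min-max
# standardized features (ibk), a C4.5-style gain-ratio decision tree
# with pessimistic pruning (j48), the majority-class baseline (zeror),
# the single-attribute rule learner (oner), and attribute-selected
# variants (asc_nb / asc_ibk / asc_j48) that run CFS before fitting
# the base learner.  Labels are "high" (scored class) and "low".

ALGORITHMS <- c("nb", "ibk", "j48", "asc_nb", "asc_ibk", "asc_j48",
                "zeror", "oner")

#' Fit a classification model
#'
#' @param algorithm one of `"nb"`, `"ibk"`, `"j48"`, `"asc_nb"`,
#'   `"asc_ibk"`, `"asc_j48"`, `"zeror"`, `"oner"`.
#' @param x descriptor data frame or numeric matrix (rows = ligands).
#' @param y activity labels (`"high"`/`"low"`).
#' @param hyperparams list: `k` (ibk neighbours, default 1),
#'   `min_obj` (j48 minimum instances per leaf, default 2), `pruned`
#'   (j48 pessimistic pruning, default `TRUE`), `cf` (pruning
#'   confidence, default 0.25), `min_bucket` (oner, default 6),
#'   `selector` for `asc_*` (`"cfs"`, the default, or `"all"`).
#' @param seed integer seed (used by embedded selectors).
#' @return Object of class `znbf_model` with a [predict()] method.
#' @export
fit_classifier <- function(algorithm, x, y, hyperparams = list(),
                           seed = 1L) {
  if (!algorithm %in% ALGORITHMS)
    stop_param("unknown algorithm '%s' (expected one of %s)", algorithm,
               paste(ALGORITHMS, collapse = ", "))
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  if (nrow(m) < 2L) stop_param("need at least 2 training instances")
  if (nrow(m) != length(y))
    stop_param("x has %d rows but y has %d labels", nrow(m), length(y))
  if (algorithm != "zeror" && length(unique(y)) < 2L)
    stop_param("training data must contain both classes")

  fitted <- switch(
    algorithm,
    nb = fit_nb(m, y),
    ibk = fit_ibk(m, y, hyperparams),
    j48 = fit_j48(m, y, hyperparams),
    zeror = list(majority = majority_label(y),
                 p_high = mean(y == "high")),
    oner = fit_oner(m, y, hyperparams),
    fit_asc(algorithm, m, y, hyperparams, seed))

  structure(list(algorithm = algorithm, hyperparams = hyperparams,
                 feature_names = colnames(m), fitted = fitted,
                 classes = sort(unique(y))),
            class = c(paste0("znbf_", algorithm), "znbf_model"))
}

# ---- naive Bayes ------------------------------------------------------------

fit_nb <- function(m, y, sd_floor = 1e-6) {
  classes <- sort(unique(y))
  stats <- lapply(classes, function(cls) {
    sub <- m[y == cls, , drop = FALSE]
    list(prior = mean(y == cls),
         mean = apply(sub, 2, mean),
         sd = pmax(apply(sub, 2, sd_pop), sd_floor))
  })
  names(stats) <- classes
  stats
}

nb_posterior <- function(fitted, m) {
  loglik <- vapply(names(fitted), function(cls) {
    st <- fitted[[cls]]
    ll <- rep(log(st$prior), nrow(m))
    for (j in seq_len(ncol(m)))
      ll <- ll + dnorm(m[, j], st$mean[j], st$sd[j], log = TRUE)
    ll
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) loglik <- matrix(loglik, nrow = 1,
                                      dimnames = list(NULL, names(fitted)))
  mx <- apply(loglik, 1, max)
  p <- exp(loglik - mx)
  p / rowSums(p)
}

# ---- IBK --------------------------------------------------------------------

fit_ibk <- function(m, y, hp) {
  k <- hp$k %||% 1L
  if (k < 1 || k > nrow(m))
    stop_param("ibk needs 1 <= k <= n (k = %s, n = %d)", format(k), nrow(m))
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  list(k = as.integer(k), lo = rng[1, ], span = span,
       train = sweep(sweep(m, 2, rng[1, ]), 2, span, "/"), y = y)
}

ibk_predict_row <- function(fitted, v) {
  z <- (v - fitted$lo) / fitted$span
  d <- sqrt(rowSums(sweep(fitted$train, 2, z)^2))
  nn <- order(d)[seq_len(fitted$k)]
  votes <- table(fitted$y[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    # tie: class with the nearer mean neighbour distance, then
    # lexicographic label order
    md <- vapply(top, function(cls) mean(d[nn][fitted$y[nn] == cls]),
                 numeric(1))
    top <- top[order(md, top)]
  }
  c(label = top[1L],
    score = mean(fitted$y[nn] == "high"))
}

# ---- J48 --------------------------------------------------------------------

#' Best binary split of one feature by gain ratio
#'
#' Candidate thresholds are midpoints between consecutive sorted
#' distinct values; the returned threshold maximizes the gain ratio
#' subject to at least `min_obj` instances on each side.
#'
#' @param values numeric feature column.
#' @param labels activity labels.
#' @param min_obj minimum instances on each side of the split.
#' @return List with `threshold`, `gain`, `gain_ratio`, or `NULL` when
#'   no admissible split exists (constant column, zero gain, or
#'   `min_obj` unsatisfiable).
#' @export
j48_best_split <- function(values, labels, min_obj = 2L) {
  y01 <- as.numeric(check_labels(labels) == "high")
  s <- best_binary_split(values, y01, min_each = min_obj)
  if (is.null(s) || s$gain_ratio <= 0) return(NULL)
  s
}

grow_tree <- function(m, y, min_obj) {
  n <- length(y)
  counts <- c(high = sum(y == "high"), low = sum(y == "low"))
  leaf <- list(type = "leaf", counts = counts,
               label = majority_label(y), p_high = mean(y == "high"),
               n = n, errors = n - max(counts))
  if (length(unique(y)) == 1L || n < 2L * min_obj) return(leaf)
  splits <- lapply(seq_len(ncol(m)), function(j)
    j48_best_split(m[, j], y, min_obj))
  grs <- vapply(splits, function(s) if (is.null(s)) -Inf else s$gain_ratio,
                numeric(1))
  if (all(!is.finite(grs))) return(leaf)
  j <- which.max(grs)
  t <- splits[[j]]$threshold
  left <- m[, j] <= t
  list(type = "node", feature = j, threshold = t,
       gain_ratio = splits[[j]]$gain_ratio, counts = counts, n = n,
       left = grow_tree(m[left, , drop = FALSE], y[left], min_obj),
       right = grow_tree(m[!left, , drop = FALSE], y[!left], min_obj))
}

# C4.5 pessimistic error estimate: upper confidence bound on the
# number of misclassified instances at a leaf with n cases and e
# observed errors, at confidence cf.
add_errs <- function(n, e, cf = 0.25) {
  if (e < 1) {
    base <- n * (1 - cf^(1 / n))
    if (e == 0) return(base)
    return(base + e * (add_errs(n, 1, cf) - base))
  }
  if (e + 0.5 >= n) return(max(n - e, 0))
  z <- qnorm(1 - cf)
  f <- (e + 0.5) / n
  r <- (f + z^2 / (2 * n) +
          z * sqrt(f / n - f^2 / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  r * n - e
}

prune_tree <- function(node, cf = 0.25) {
  if (node$type == "leaf") return(node)
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_err <- est_errors(node$left, cf) + est_errors(node$right, cf)
  leaf_err <- add_errs(node$n, node$n - max(node$counts), cf) +
    (node$n - max(node$counts))
  if (leaf_err <= subtree_err + 0.1) {
    return(list(type = "leaf", counts = node$counts,
                label = names(node$counts)[which.max(node$counts)],
                p_high = node$counts[["high"]] / node$n,
                n = node$n, errors = node$n - max(node$counts)))
  }
  node
}

est_errors <- function(node, cf) {
  if (node$type == "leaf")
    return(node$errors + add_errs(node$n, node$errors, cf))
  est_errors(node$left, cf) + est_errors(node$right, cf)
}

fit_j48 <- function(m, y, hp) {
  min_obj <- hp$min_obj %||% 2L
  if (min_obj < 1) stop_param("min_obj must be positive")
  if (2L * min_obj > nrow(m))
    warning("min_obj too large for the training set; ",
            "tree degenerates to a single leaf", call. = FALSE)
  tree <- grow_tree(m, y, min_obj)
  if (hp$pruned %||% TRUE) tree <- prune_tree(tree, hp$cf %||% 0.25)
  list(tree = tree, min_obj = as.integer(min_obj))
}

tree_predict_row <- function(node, v) {
  while (node$type != "leaf")
    node <- if (v[node$feature] <= node$threshold) node$left else node$right
  c(label = node$label, score = node$p_high)
}

# ---- OneR -------------------------------------------------------------------

# Holte-style single-attribute rule: sort by value, open a new bucket
# once the current one holds >= min_bucket instances of its majority
# class and the next value differs; merge adjacent buckets that
# predict the same class.
oner_discretize <- function(v, y, min_bucket) {
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  cuts <- numeric(0)
  labels <- character(0)
  start <- 1L
  n <- length(vs)
  i <- 1L
  while (i <= n) {
    seg <- ys[start:i]
    tab <- table(seg)
    if (max(tab) >= min_bucket && i < n && vs[i + 1L] > vs[i]) {
      cuts <- c(cuts, (vs[i] + vs[i + 1L]) / 2)
      labels <- c(labels, majority_label(seg))
      start <- i + 1L
    }
    i <- i + 1L
  }
  labels <- c(labels, majority_label(ys[start:n]))
  # merge adjacent buckets with identical predictions
  keep <- which(diff(match(labels, c("high", "low"))) != 0)
  list(cuts = cuts[keep], labels = labels[c(keep, length(labels))])
}

oner_apply <- function(rule, v) {
  idx <- findInterval(v, rule$cuts) + 1L
  rule$labels[idx]
}

fit_oner <- function(m, y, hp) {
  min_bucket <- hp$min_bucket %||% 6L
  best <- NULL
  for (j in seq_len(ncol(m))) {
    rule <- oner_discretize(m[, j], y, min_bucket)
    err <- mean(oner_apply(rule, m[, j]) != y)
    if (is.null(best) || err < best$error - 1e-12) {
      p_high <- vapply(seq_along(rule$labels), function(b) {
        idx <- findInterval(m[, j], rule$cuts) + 1L
        inb <- idx == b
        if (any(inb)) mean(y[inb] == "high") else 0.5
      }, numeric(1))
      best <- list(feature = j, rule = rule, error = err, p_high = p_high)
    }
  }
  best
}

# ---- attribute-selected classifier ------------------------------------------

fit_asc <- function(algorithm, m, y, hp, seed) {
  base <- sub("^asc_", "", algorithm)
  selector <- hp$selector %||% "cfs"
  sel_names <- if (selector == "all") colnames(m) else {
    res <- cfs_select(m, y)
    if (length(res$names)) res$names else colnames(m)
  }
  sub <- fit_classifier(base, m[, sel_names, drop = FALSE], y,
                        hyperparams = hp, seed = seed)
  list(selected = sel_names, submodel = sub)
}

# ---- prediction -------------------------------------------------------------

#' Predict activity classes (or scores) from a fitted model
#'
#' @param object a `znbf_model` from [fit_classifier()].
#' @param newdata descriptor data frame or matrix whose columns cover
#'   the model's `feature_names`.
#' @param type `"class"` for labels (default) or `"score"` for the
#'   numeric score of the `"high"` class.
#' @param ... unused.
#' @return Character vector of labels, or numeric scores in \[0, 1\].
#' @export
predict.znbf_model <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  m <- as_descriptor_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(m))
  if (length(missing))
    stop_param("newdata lacks model features: %s",
               paste(missing, collapse = ", "))
  m <- m[, object$feature_names, drop = FALSE]

  res <- switch(
    object$algorithm,
    nb = {
      post <- nb_posterior(object$fitted, m)
      p_high <- if ("high" %in% colnames(post)) post[, "high"] else
        1 - post[, "low"]
      labels <- colnames(post)[max.col(post, ties.method = "first")]
      list(label = labels, score = p_high)
    },
    ibk = {
      out <- t(apply(m, 1, function(v) ibk_predict_row(object$fitted, v)))
      list(label = out[, "label"], score = as.numeric(out[, "score"]))
    },
    j48 = {
      out <- t(apply(m, 1, function(v)
        tree_predict_row(object$fitted$tree, v)))
      list(label = out[, "label"], score = as.numeric(out[, "score"]))
    },
    zeror = list(label = rep(object$fitted$majority, nrow(m)),
                 score = rep(object$fitted$p_high, nrow(m))),
    oner = {
      f <- object$fitted
      v <- m[, f$feature]
      idx <- findInterval(v, f$rule$cuts) + 1L
      list(label = f$rule$labels[idx], score = f$p_high[idx])
    },
    {
      sub <- object$fitted$submodel
      list(label = predict(sub, m, type = "class"),
           score = predict(sub, m, type = "score"))
    })
  if (type == "class") unname(res$label) else unname(res$score)
}

#' @export
print.znbf_model <- function(x, ...) {
  cat(sprintf("znscreen classifier: %s (%d features)\n", x$algorithm,
              length(x$feature_names)))
  if (length(x$hyperparams))
    cat("  hyperparams:",
        paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `znbf_model`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(algorithm = model$algorithm, hyperparams = model$hyperparams,
         feature_names = model$feature_names, fitted = model$fitted),
    path, auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(path)
}
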