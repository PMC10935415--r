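# Descriptor selection: correlation-based feature selection (CFS) with
# best-first search, gain-ratio ranking with supervised binary
# discretization, wrapper selection scored by cross-validated naive
# Bayes accuracy, and the CFS-then-wrapper combination.

# ---- best-first subset search ----------------------------------------------
# Forward best-first with backtracking: an open list of evaluated
# subsets, always expanding the best unexpanded one by single-feature
# additions; stops after `stale_limit` consecutive expansions that do
# not improve the global best.
best_first_search <- function(p, evaluate, stale_limit = 5L) {
  key <- function(s) paste0("s", paste(s, collapse = ","))
  open <- list(list(subset = integer(0), score = evaluate(integer(0))))
  seen <- new.env(parent = emptyenv())
  assign(key(integer(0)), TRUE, envir = seen)
  best <- open[[1L]]
  stale <- 0L
  trace <- list()
  while (length(open) && stale < stale_limit) {
    scores <- vapply(open, `[[`, numeric(1), "score")
    i <- which.max(scores)
    node <- open[[i]]
    open[[i]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$subset)) {
      child <- sort(c(node$subset, f))
      k <- key(child)
      if (exists(k, envir = seen)) next
      assign(k, TRUE, envir = seen)
      sc <- evaluate(child)
      open[[length(open) + 1L]] <- list(subset = child, score = sc)
      if (sc > best$score + 1e-12) {
        best <- list(subset = child, score = sc)
        improved <- TRUE
      }
    }
    trace[[length(trace) + 1L]] <-
      list(expanded = node$subset, score = node$score, best = best$score)
    stale <- if (improved) 0L else stale + 1L
  }
  best$trace <- trace
  best
}

cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(r_cf[subset])
  rff <- if (k == 1L) 0 else
    mean(r_ff[subset, subset][upper.tri(diag(k))])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

new_feature_subset <- function(method, names, score, trace = NULL) {
  structure(list(method = method, names = names, score = score,
                 trace = trace), class = "znbf_feature_subset")
}

#' @export
print.znbf_feature_subset <- function(x, ...) {
  cat(sprintf("Feature subset [%s]: %d descriptors, score %.4f\n",
              x$method, length(x$names), x$score))
  if (length(x$names)) cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-based feature selection (CFS)
#'
#' Best-first forward search (with backtracking, stopped after 5
#' consecutive non-improving expansions) maximizing the CFS merit
#' `k * r_cf / sqrt(k + k (k - 1) * r_ff)`, where `r_cf` is the mean
#' absolute feature-class (point-biserial) correlation of the subset
#' and `r_ff` the mean absolute feature-feature correlation.
#'
#' @param x descriptor data frame or numeric matrix.
#' @param y activity class labels (`"high"`/`"low"`).
#' @param stale_limit best-first stopping patience (default 5).
#' @return A `znbf_feature_subset` (method `"cfs"`) with the merit as
#'   score and the search trace.
#' @export
cfs_select <- function(x, y, stale_limit = 5L) {
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  if (ncol(m) < 2L) stop_param("CFS needs at least 2 candidate features")
  if (length(unique(y)) < 2L) stop_param("CFS needs both classes present")
  const <- apply(m, 2, var) == 0
  if (any(const)) {
    warning("ignoring constant features: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  y01 <- as.numeric(y == "high")
  r_cf <- abs(as.numeric(cor(m, y01)))
  r_ff <- abs(cor(m))
  res <- best_first_search(ncol(m),
                           function(s) cfs_merit(s, r_cf, r_ff),
                           stale_limit = stale_limit)
  new_feature_subset("cfs", colnames(m)[res$subset], res$score, res$trace)
}

# ---- gain ratio -------------------------------------------------------------

entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# best binary split of a numeric feature against binary labels:
# candidate thresholds are midpoints between consecutive sorted
# distinct values; returns gain, split information and gain ratio
best_binary_split <- function(v, y01, min_each = 1L) {
  ux <- sort(unique(v))
  if (length(ux) < 2L) return(NULL)
  n <- length(v)
  h0 <- entropy(c(sum(y01), n - sum(y01)))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  for (t in cuts) {
    left <- v <= t
    nl <- sum(left)
    if (nl < min_each || n - nl < min_each) next
    hl <- entropy(c(sum(y01[left]), nl - sum(y01[left])))
    hr <- entropy(c(sum(y01[!left]), (n - nl) - sum(y01[!left])))
    gain <- h0 - (nl / n) * hl - ((n - nl) / n) * hr
    si <- entropy(c(nl, n - nl))
    gr <- if (si > 0 && gain > 1e-12) gain / si else 0
    if (is.null(best) || gr > best$gain_ratio + 1e-12)
      best <- list(threshold = t, gain = gain, split_info = si,
                   gain_ratio = gr)
  }
  best
}

#' Gain-ratio descriptor ranking
#'
#' Each feature is discretized by the supervised binary split
#' maximizing information gain; its gain ratio is the gain divided by
#' the split information.  Features are ranked in descending gain
#' ratio; by default all features with positive gain ratio are
#' selected, or the top `top_k`.
#'
#' @inheritParams cfs_select
#' @param top_k optional number of top-ranked features to keep.
#' @return A `znbf_feature_subset` (method `"gr"`) whose score is the
#'   best gain ratio and whose trace holds the full ranking.
#' @export
gain_ratio_rank <- function(x, y, top_k = NULL) {
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  y01 <- as.numeric(y == "high")
  gr <- vapply(seq_len(ncol(m)), function(j) {
    s <- best_binary_split(m[, j], y01)
    if (is.null(s)) 0 else s$gain_ratio
  }, numeric(1))
  ord <- order(gr, decreasing = TRUE)
  ranking <- data.frame(name = colnames(m)[ord], gain_ratio = gr[ord])
  sel <- if (is.null(top_k)) ranking$name[ranking$gain_ratio > 0] else
    head(ranking$name, top_k)
  new_feature_subset("gr", sel, if (nrow(ranking)) ranking$gain_ratio[1] else 0,
                     ranking)
}

#' Wrapper descriptor selection
#'
#' Greedy forward best-first search scored by the seeded
#' cross-validated accuracy of a base learner (naive Bayes by
#' default).  Fold assignments are drawn once from the seed and reused
#' for every candidate subset, so the search is deterministic.
#'
#' @inheritParams cfs_select
#' @param base_learner algorithm name passed to [fit_classifier()]
#'   (default `"nb"`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return A `znbf_feature_subset` (method `"wrapper"`) whose score is
#'   the CV accuracy (percent) of the selected subset.
#' @export
wrapper_select <- function(x, y, base_learner = "nb", folds = 5L,
                           seed = 1L, stale_limit = 5L) {
  m <- as_descriptor_matrix(x)
  y <- check_labels(y)
  if (nrow(m) < folds) stop_param("need n >= folds for wrapper selection")
  fold_id <- make_stratified_folds(y, folds, derive_seed(seed, "wrapper_cv"))
  majority_pct <- 100 * max(table(y)) / length(y)
  evaluate <- function(subset) {
    if (!length(subset)) return(majority_pct)
    preds <- character(length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      model <- fit_classifier(base_learner, m[tr, subset, drop = FALSE],
                              y[tr], seed = seed)
      preds[!tr] <- predict(model, m[!tr, subset, drop = FALSE])
    }
    accuracy_pct(preds, y)
  }
  res <- best_first_search(ncol(m), evaluate, stale_limit = stale_limit)
  new_feature_subset("wrapper", colnames(m)[res$subset], res$score,
                     res$trace)
}

#' CFS followed by wrapper selection
#'
#' Runs [wrapper_select()] restricted to the descriptors chosen by
#' [cfs_select()].
#'
#' @inheritParams wrapper_select
#' @return A `znbf_feature_subset` with method `"cfs_wrapper"`.
#' @export
cfs_then_wrapper <- function(x, y, base_learner = "nb", folds = 5L,
                             seed = 1L) {
  m <- as_descriptor_matrix(x)
  cfs <- cfs_select(m, y)
  if (!length(cfs$names)) {
    warning("CFS returned an empty subset; nothing for the wrapper to search",
            call. = FALSE)
    return(new_feature_subset("cfs_wrapper", character(0), 0))
  }
  wr <- wrapper_select(m[, cfs$names, drop = FALSE], y,
                       base_learner = base_learner, folds = folds,
                       seed = seed)
  new_feature_subset("cfs_wrapper", wr$names, wr$score,
                     list(cfs = cfs, wrapper = wr$trace))
}
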