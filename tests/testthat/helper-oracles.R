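# Independent brute-force implementations of the decision rules, used
# as oracles against the package's classifiers and statistics.  These
# deliberately share no code with the implementation under test.

# Gaussian naive Bayes: longhand priors, per-class densities, argmax.
oracle_nb_predict <- function(xtr, ytr, xte, sd_floor = 1e-6) {
  classes <- sort(unique(ytr))
  apply(xte, 1, function(v) {
    post <- sapply(classes, function(cls) {
      sub <- xtr[ytr == cls, , drop = FALSE]
      p <- sum(ytr == cls) / length(ytr)
      for (j in seq_along(v)) {
        mu <- mean(sub[, j])
        s <- if (nrow(sub) > 1) stats::sd(sub[, j]) else 0
        s <- max(s, sd_floor)
        p <- p * stats::dnorm(v[j], mu, s)
      }
      p
    })
    classes[which.max(post)]
  })
}

# k-nearest neighbours on min-max standardized features; tie broken
# toward the class with nearer mean neighbour distance, then
# lexicographic.
oracle_ibk_predict <- function(xtr, ytr, xte, k) {
  lo <- apply(xtr, 2, min)
  hi <- apply(xtr, 2, max)
  span <- ifelse(hi - lo == 0, 1, hi - lo)
  ztr <- sweep(sweep(xtr, 2, lo), 2, span, "/")
  apply(xte, 1, function(v) {
    z <- (v - lo) / span
    d <- apply(ztr, 1, function(row) sqrt(sum((row - z)^2)))
    nn <- order(d)[seq_len(k)]
    votes <- table(ytr[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    md <- sapply(top, function(cls) mean(d[nn][ytr[nn] == cls]))
    top[order(md, top)][1L]
  })
}

# independent traversal of a fitted j48 tree structure
oracle_tree_predict <- function(tree, xte) {
  apply(xte, 1, function(v) {
    node <- tree
    while (node$type == "node") {
      node <- if (v[node$feature] <= node$threshold) node$left else
        node$right
    }
    node$label
  })
}

# independent application of a fitted oner rule (linear scan over cuts)
oracle_oner_predict <- function(fitted, xte) {
  apply(xte, 1, function(v) {
    val <- v[fitted$feature]
    b <- 1L
    for (cut in fitted$rule$cuts) if (val > cut) b <- b + 1L
    fitted$rule$labels[b]
  })
}

oracle_zeror_predict <- function(ytr, n) {
  tab <- table(ytr)
  top <- names(tab)[tab == max(tab)]
  rep(sort(top)[1L], n)
}

# AUC as the brute-force pairwise probability over all positive x
# negative score pairs, ties counted half
oracle_auc_pairwise <- function(scores, truths) {
  pos <- scores[truths == "high"]
  neg <- scores[truths == "low"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# CFS merit recomputed independently, and the exhaustive 2^k optimum
oracle_cfs_merit <- function(subset, x, y01) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(abs(as.numeric(stats::cor(x[, subset, drop = FALSE], y01))))
  rff <- if (k == 1L) 0 else {
    cc <- abs(stats::cor(x[, subset, drop = FALSE]))
    mean(cc[upper.tri(cc)])
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

oracle_cfs_exhaustive <- function(x, y01) {
  k <- ncol(x)
  rcf <- abs(as.numeric(stats::cor(x, y01)))
  rff <- abs(stats::cor(x))
  best <- 0
  for (mask in seq_len(2^k - 1)) {
    sub <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    m <- length(sub)
    mean_cf <- mean(rcf[sub])
    mean_ff <- if (m == 1L) 0 else {
      cc <- rff[sub, sub]
      mean(cc[upper.tri(cc)])
    }
    best <- max(best, m * mean_cf / sqrt(m + m * (m - 1) * mean_ff))
  }
  best
}

# brute-force best gain-ratio midpoint split of one column
oracle_best_split <- function(v, y, min_obj = 2L) {
  ent <- function(p) {
    p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }
  ux <- sort(unique(v))
  if (length(ux) < 2L) return(NULL)
  n <- length(v)
  h0 <- ent(table(y))
  best <- NULL
  for (t in (ux[-1] + ux[-length(ux)]) / 2) {
    l <- v <= t
    if (sum(l) < min_obj || sum(!l) < min_obj) next
    gain <- h0 - sum(l) / n * ent(table(y[l])) -
      sum(!l) / n * ent(table(y[!l]))
    si <- ent(c(sum(l), sum(!l)))
    gr <- if (si > 0 && gain > 1e-12) gain / si else 0
    if (is.null(best) || gr > best$gain_ratio)
      best <- list(threshold = t, gain = gain, gain_ratio = gr)
  }
  if (!is.null(best) && best$gain_ratio <= 0) return(NULL)
  best
}
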