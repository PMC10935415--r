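# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that individual stages (structures, activities,
#' descriptors, splits, ...) are reproducible in isolation.
#'
#' @param seed integer root seed.
#' @param stream character name of the substream.
#' @return An integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 997L
  as.integer((abs(as.numeric(seed)) %% 1000000) * 2048 + h)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_param("`%s` must be a proportion strictly between 0 and 1 (got %s)",
               name, format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_param("`%s` must be an integer >= %d (got %s)", name, min, format(x))
  invisible(as.integer(x))
}

# Binary labels used throughout: "high" (active) and "low" (inactive).
check_labels <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("high", "low"))
  if (length(bad))
    stop_param("activity labels must be 'high' or 'low' (found: %s)",
               paste(bad, collapse = ", "))
  y
}

majority_label <- function(y) {
  tab <- table(factor(y, levels = sort(unique(y))))
  names(tab)[which.max(tab)]  # ties -> lexicographically first
}

as_descriptor_matrix <- function(desc) {
  if (is.matrix(desc)) return(desc)
  stopifnot(is.data.frame(desc))
  if ("ligand_id" %in% names(desc)) {
    ids <- as.character(desc$ligand_id)
    m <- as.matrix(desc[, setdiff(names(desc), "ligand_id"), drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(desc)
  }
  storage.mode(m) <- "double"
  m
}
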