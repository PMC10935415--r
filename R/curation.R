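# Activity curation: merge multi-source Ki records on the log scale,
# assign activity classes, prune structurally redundant ligands by
# MACCS fingerprint similarity, and split into modeling / external
# test sets (with a cluster-balanced 7:3 inner split).

#' Merge multi-source Ki records for one ligand
#'
#' Records are merged on the decadic log scale: if the spread
#' `max(lg Ki) - min(lg Ki)` is at most 1, the merged activity is the
#' arithmetic mean of the per-record lg(Ki); a larger spread marks the
#' ligand as unreliable and it is discarded.
#'
#' @param ki_nM numeric vector of Ki values in nM (one per record), or
#'   a data frame with a `ki_nM` column.
#' @param max_spread maximum tolerated lg(Ki) spread (default 1).
#' @return The merged lg(Ki), or `NA_real_` as the discard signal.
#' @export
merge_activity <- function(ki_nM, max_spread = 1) {
  if (is.data.frame(ki_nM)) ki_nM <- ki_nM$ki_nM
  if (!length(ki_nM)) stop_param("need at least one Ki record")
  bad <- which(!is.finite(ki_nM) | ki_nM <= 0)
  if (length(bad))
    stop_param("Ki must be positive and finite (record %d has %s)",
               bad[1], format(ki_nM[bad[1]]))
  lg <- log10(ki_nM)
  if (max(lg) - min(lg) > max_spread) return(NA_real_)
  mean(lg)
}

#' Assign an activity class from lg(Ki)
#'
#' Strict cut-offs: `lg_ki < 2` is high activity, `lg_ki > 3` low
#' activity; values in the closed interval \[2, 3\] (including the
#' boundaries) are excluded from modeling.
#'
#' @param lg_ki numeric vector of merged lg(Ki) values.
#' @return Character vector in `c("high", "low", "excluded")`.
#' @export
assign_class <- function(lg_ki) {
  if (any(!is.finite(lg_ki)))
    stop_param("lg_ki must be finite (use merge_activity's NA discard first)")
  ifelse(lg_ki < 2, "high", ifelse(lg_ki > 3, "low", "excluded"))
}

#' Build curated ligand entries from raw records and structures
#'
#' Applies [merge_activity()] per ligand and [assign_class()] to the
#' merged values; ligands with a discordant Ki spread or a class of
#' `"excluded"` are dropped (and reported).
#'
#' @param records data frame with `ligand_id`, `source_id`, `ki_nM`.
#' @param structures named character vector of SMILES or data frame
#'   with `ligand_id` and `smiles`.
#' @param max_spread maximum tolerated lg(Ki) spread (default 1).
#' @return List with `entries` (data frame: `ligand_id`, `smiles`,
#'   `lg_ki`, `activity_class`, `n_sources`) containing only retained
#'   high/low ligands, and `dropped` (data frame: `ligand_id`,
#'   `reason`).
#' @export
curate_entries <- function(records, structures, max_spread = 1) {
  if (is.data.frame(structures))
    structures <- setNames(structures$smiles, structures$ligand_id)
  ids <- unique(records$ligand_id)
  dropped <- list()
  rows <- list()
  for (id in ids) {
    ki <- records$ki_nM[records$ligand_id == id]
    lg <- merge_activity(ki, max_spread = max_spread)
    if (is.na(lg)) {
      dropped[[id]] <- "discordant Ki records"
      next
    }
    cls <- assign_class(lg)
    if (cls == "excluded") {
      dropped[[id]] <- sprintf("lg_ki %.3f in [2, 3]", lg)
      next
    }
    if (!id %in% names(structures)) {
      dropped[[id]] <- "no structure"
      next
    }
    rows[[id]] <- data.frame(ligand_id = id,
                             smiles = unname(structures[id]),
                             lg_ki = lg, activity_class = cls,
                             n_sources = length(ki),
                             stringsAsFactors = FALSE)
  }
  list(entries = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(),
       dropped = data.frame(ligand_id = names(dropped),
                            reason = unlist(dropped) %||% character(0),
                            row.names = NULL))
}

#' Prune structurally redundant ligands
#'
#' Within each activity class, greedily removes one of every ligand
#' pair whose MACCS-fingerprint Tanimoto similarity exceeds the
#' threshold (strictly).  Ligands are processed in ascending
#' `ligand_id` order and kept iff their similarity to every
#' already-kept same-class ligand is at most the threshold, which makes
#' the "arbitrary" removal deterministic and idempotent.
#'
#' @param entries curated entry data frame (`ligand_id`, `smiles`,
#'   `activity_class`, ...).
#' @param threshold similarity above which a pair is redundant
#'   (default 0.75; a pair at exactly the threshold is kept).
#' @param within_class prune within each activity class separately
#'   (default `TRUE`); set `FALSE` to prune across classes too.
#' @return The retained entries, with attributes `"removed"` (data
#'   frame: `ligand_id`, `similar_to`, `similarity`) and
#'   `"n_removed"`.
#' @export
prune_redundant <- function(entries, threshold = 0.75, within_class = TRUE) {
  if (!nrow(entries)) return(entries)
  parsed_ok <- !is.na(vapply(entries$smiles, function(s) {
    p <- suppressWarnings(parse_smiles(setNames(s, "x")))
    if (is.null(p[[1]])) NA_character_ else "ok"
  }, character(1)))
  if (any(!parsed_ok))
    warning("excluding unparseable structures: ",
            paste(entries$ligand_id[!parsed_ok], collapse = ", "),
            call. = FALSE)
  entries <- entries[parsed_ok, , drop = FALSE]
  sim <- maccs_similarity(setNames(entries$smiles, entries$ligand_id))
  ord <- order(entries$ligand_id)
  kept <- character(0)
  removed <- list()
  for (i in ord) {
    id <- entries$ligand_id[i]
    rivals <- if (within_class)
      kept[kept %in% entries$ligand_id[entries$activity_class ==
                                         entries$activity_class[i]]]
    else kept
    if (length(rivals)) {
      s <- sim[id, rivals]
      if (any(s > threshold)) {
        j <- rivals[which.max(s)]
        removed[[id]] <- data.frame(ligand_id = id, similar_to = j,
                                    similarity = max(s))
        next
      }
    }
    kept <- c(kept, id)
  }
  out <- entries[entries$ligand_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(ligand_id = character(), similar_to = character(),
               similarity = numeric())
  attr(out, "n_removed") <- length(removed)
  out
}

# cluster-balanced 7:3 allocation: k-means-style clustering on
# standardized descriptor vectors, then a seeded 7:3 draw inside each
# cluster, so train and internal test cover the same structural space
inner_split_cluster <- function(ids, desc_matrix, train_fraction, seed) {
  n <- length(ids)
  withr::with_seed(seed, {
    if (is.null(desc_matrix) || n < 4L) {
      train <- sample(ids, round(train_fraction * n))
    } else {
      m <- desc_matrix[ids, , drop = FALSE]
      keep <- apply(m, 2, function(v) is.finite(var(v)) && var(v) > 0)
      m <- scale(m[, keep, drop = FALSE])
      k <- max(2L, round(n / 10))
      cl <- kmeans(m, centers = min(k, n - 1L), nstart = 5)$cluster
      train <- character(0)
      for (g in unique(cl)) {
        members <- ids[cl == g]
        n_tr <- round(train_fraction * length(members))
        train <- c(train, if (n_tr) sample(members, n_tr) else character(0))
      }
      # rebalance to the global 7:3 target
      target <- round(train_fraction * n)
      if (length(train) > target)
        train <- setdiff(train, sample(train, length(train) - target))
      else if (length(train) < target)
        train <- c(train, sample(setdiff(ids, train), target - length(train)))
    }
    setNames(ifelse(ids %in% train, "train", "internal_test"), ids)
  })
}

#' Split curated entries into modeling and external test sets
#'
#' The external split is a seeded random draw stratified by activity
#' class; the modeling subset is further divided 7:3 into training and
#' internal test sets by cluster analysis on standardized descriptors
#' (falling back to a stratified draw when no descriptors are given).
#'
#' @param entries curated (pruned) entry data frame.
#' @param modeling_fraction fraction of entries in the modeling set
#'   (default 165/208).
#' @param descriptors optional descriptor data frame/matrix used for
#'   the cluster-balanced inner split.
#' @param train_fraction training share of the modeling set
#'   (default 0.7).
#' @param seed integer seed.
#' @return List of class `znbf_curated_dataset`: `entries`,
#'   `split_assignment` (named vector, `modeling`/`external_test`),
#'   `inner_split` (named vector over the modeling set,
#'   `train`/`internal_test`), and `seed`.
#' @export
split_dataset <- function(entries, modeling_fraction = 165 / 208,
                          descriptors = NULL, train_fraction = 0.7,
                          seed = 1L) {
  if (nrow(entries) < 10L) stop_param("need at least 10 entries to split")
  check_proportion(modeling_fraction, "modeling_fraction")
  tab <- table(entries$activity_class)
  if (any(tab < 2L))
    stop_param("every activity class needs at least 2 members (got %s)",
               paste(names(tab), tab, sep = "=", collapse = ", "))
  n_model <- round(modeling_fraction * nrow(entries))
  assignment <- withr::with_seed(derive_seed(seed, "external_split"), {
    modeling <- character(0)
    for (cls in names(tab)) {
      ids <- entries$ligand_id[entries$activity_class == cls]
      n_cls <- round(length(ids) * n_model / nrow(entries))
      modeling <- c(modeling, sample(ids, min(n_cls, length(ids))))
    }
    # fix rounding drift to hit the modeling count exactly
    pool <- setdiff(entries$ligand_id, modeling)
    if (length(modeling) > n_model)
      modeling <- setdiff(modeling, sample(modeling, length(modeling) - n_model))
    else if (length(modeling) < n_model)
      modeling <- c(modeling, sample(pool, n_model - length(modeling)))
    setNames(ifelse(entries$ligand_id %in% modeling, "modeling",
                    "external_test"), entries$ligand_id)
  })
  model_ids <- names(assignment)[assignment == "modeling"]
  dm <- if (!is.null(descriptors)) as_descriptor_matrix(descriptors) else NULL
  inner <- inner_split_cluster(model_ids, dm, train_fraction,
                               derive_seed(seed, "inner_split"))
  structure(list(entries = entries, split_assignment = assignment,
                 inner_split = inner, seed = as.integer(seed)),
            class = "znbf_curated_dataset")
}

#' Curate a raw ligand set end to end
#'
#' Convenience wrapper: [curate_entries()], then [prune_redundant()],
#' then [split_dataset()].
#'
#' @inheritParams curate_entries
#' @inheritParams prune_redundant
#' @inheritParams split_dataset
#' @return A `znbf_curated_dataset` (see [split_dataset()]) with an
#'   extra `report` element summarizing drops and prunes.
#' @export
curate_dataset <- function(records, structures, threshold = 0.75,
                           modeling_fraction = 165 / 208,
                           descriptors = NULL, seed = 1L) {
  cur <- curate_entries(records, structures)
  pruned <- prune_redundant(cur$entries, threshold = threshold)
  ds <- split_dataset(pruned, modeling_fraction = modeling_fraction,
                      descriptors = descriptors, seed = seed)
  ds$report <- list(dropped = cur$dropped,
                    pruned = attr(pruned, "removed"),
                    n_retained = nrow(pruned))
  ds
}
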