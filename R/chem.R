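# Light wrappers around ChemmineR/ChemmineOB (OpenBabel) for structure
# parsing, MACCS fingerprints and SMARTS substructure matching, plus an
# internal hydrogen-suppressed molecular-graph representation used by
# the 2D descriptor provider.

# Single heavy-atom SMILES (e.g. "O", "C", "[NH3]") come back from
# OpenBabel as SDF blocks ChemmineR flags invalid, so they are graphed
# directly here.
single_atom_element <- function(smiles) {
  s <- trimws(smiles)
  m <- regmatches(s, regexec("^\\[?([A-GI-Za-gi-z][a-z]?)[H0-9+-]*\\]?$", s))[[1]]
  if (length(m) == 2L && !grepl("[()=#\\.]", s)) {
    el <- m[2]
    el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
    if (el %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"))
      return(el)
  }
  NA_character_
}

#' Parse SMILES into molecular graphs
#'
#' Parses SMILES strings via OpenBabel into hydrogen-suppressed
#' molecular graphs (element per heavy atom, bond list with orders).
#' Unparseable structures yield `NULL` entries with a warning.
#'
#' @param smiles named character vector of SMILES strings; names are
#'   used as molecule identifiers.
#' @return A named list of `mol_graph` objects (`elements`, `bonds`
#'   data frame with columns `a1`, `a2`, `order`, and `natoms`);
#'   `NULL` for failed parses.
#' @export
parse_smiles <- function(smiles) {
  smiles <- unlist(smiles)
  if (is.null(names(smiles)) || any(names(smiles) == ""))
    names(smiles) <- paste0("M", seq_along(smiles))
  out <- setNames(vector("list", length(smiles)), names(smiles))

  single <- vapply(smiles, single_atom_element, character(1))
  for (i in which(!is.na(single))) {
    out[[i]] <- structure(list(
      elements = single[[i]],
      bonds = data.frame(a1 = integer(), a2 = integer(), order = integer()),
      natoms = 1L), class = "mol_graph")
  }
  todo <- which(is.na(single))
  if (!length(todo)) return(out)

  parsed <- smiles_to_sdfset(smiles[todo])
  for (nm in parsed$dropped)
    warning(sprintf("could not parse SMILES for '%s'; molecule dropped", nm),
            call. = FALSE)
  for (j in seq_along(parsed$ids)) {
    mol <- parsed$sdf[[j]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- data.frame(a1 = as.integer(bb[, 1]),
                        a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    out[[parsed$ids[j]]] <- structure(
      list(elements = elements, bonds = bonds, natoms = length(elements)),
      class = "mol_graph")
  }
  out
}

# SDFset of the parseable, multi-atom molecules plus an index map back
# to the input; single-atom molecules are handled by the callers.  A
# batch parse failure (e.g. every SMILES malformed) falls back to
# per-molecule probing so one bad structure never poisons the set.
smiles_to_sdfset <- function(smiles) {
  smiles <- unlist(smiles)
  if (is.null(names(smiles)) || any(names(smiles) == ""))
    names(smiles) <- paste0("M", seq_along(smiles))
  batch <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(batch)) {
    # a malformed SMILES can abort the whole batch: probe one by one
    good <- vapply(seq_along(smiles), function(i) {
      tryCatch({
        s <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
        isTRUE(suppressWarnings(ChemmineR::validSDF(s)))
      }, error = function(e) FALSE)
    }, logical(1))
    if (!any(good))
      return(list(sdf = NULL, ids = character(0), dropped = names(smiles)))
    batch <- suppressWarnings(ChemmineR::smiles2sdf(smiles[good]))
  }
  # smiles2sdf may itself drop molecules, so map back through the
  # molecule ids it kept rather than by position
  ok <- suppressWarnings(ChemmineR::validSDF(batch))
  kept_ids <- ChemmineR::cid(batch)[ok]
  list(sdf = batch[ok], ids = kept_ids,
       dropped = setdiff(names(smiles), kept_ids))
}

#' MACCS fingerprint Tanimoto similarity matrix
#'
#' Computes MACCS structural-key fingerprints (via OpenBabel) for a set
#' of SMILES and returns the pairwise Tanimoto similarity matrix.
#' Molecules that cannot be fingerprinted (e.g. single atoms) get
#' similarity 0 to everything and 1 to themselves.
#'
#' @param smiles named character vector of SMILES.
#' @return Symmetric numeric matrix with molecule ids as dimnames.
#' @export
maccs_similarity <- function(smiles) {
  smiles <- unlist(smiles)
  if (is.null(names(smiles)) || any(names(smiles) == ""))
    names(smiles) <- paste0("M", seq_along(smiles))
  ids <- names(smiles)
  n <- length(ids)
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  parsed <- smiles_to_sdfset(smiles)
  if (length(parsed$ids) >= 2L) {
    fp <- ChemmineR::fingerprintOB(parsed$sdf, "MACCS")
    for (i in seq_along(parsed$ids)) {
      s <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
      sim[parsed$ids[i], parsed$ids] <- as.numeric(s)
    }
    diag(sim) <- 1
    sim <- (sim + t(sim)) / 2  # fpSim is symmetric up to rounding
  }
  sim
}

#' Count SMARTS matches in a set of molecules
#'
#' @param smiles named character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @return Named integer vector of (unique) match counts, 0 for
#'   molecules that do not match or cannot be parsed.
#' @export
smarts_match_count <- function(smiles, smarts) {
  smiles <- unlist(smiles)
  if (!length(smiles)) return(setNames(integer(0), character(0)))
  if (is.null(names(smiles)) || any(names(smiles) == ""))
    names(smiles) <- paste0("M", seq_along(smiles))
  counts <- setNames(integer(length(smiles)), names(smiles))
  parsed <- smiles_to_sdfset(smiles)
  if (length(parsed$ids)) {
    hits <- tryCatch(
      ChemmineR::smartsSearchOB(parsed$sdf, smarts, uniqueMatches = TRUE),
      error = function(e) stop_param("invalid SMARTS pattern '%s': %s",
                                     smarts, conditionMessage(e)))
    counts[parsed$ids] <- as.integer(hits)
  }
  counts
}

# Implicit hydrogen counts from default valences (organic subset).
default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
                     Cl = 1, Br = 1, I = 1, B = 3, H = 1)

implicit_h <- function(mol) {
  deg <- integer(mol$natoms)
  if (nrow(mol$bonds)) {
    ord <- mol$bonds$order
    for (k in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + ord[k]
      deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + ord[k]
    }
  }
  val <- default_valence[mol$elements]
  val[is.na(val)] <- 0
  pmax(0L, as.integer(val) - deg)
}

adjacency_matrix <- function(mol, weighted = FALSE) {
  n <- mol$natoms
  A <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      w <- if (weighted) mol$bonds$order[k] else 1
      A[mol$bonds$a1[k], mol$bonds$a2[k]] <- w
      A[mol$bonds$a2[k], mol$bonds$a1[k]] <- w
    }
  }
  A
}

topo_distances <- function(mol) {
  n <- mol$natoms
  if (n == 1L) return(matrix(0, 1, 1))
  g <- igraph::graph_from_data_frame(
    mol$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  d <- igraph::distances(g)
  d <- d[order(as.integer(rownames(d))), order(as.integer(colnames(d)))]
  unname(d)
}
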