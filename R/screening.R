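# Fragment-library screening: classifier prediction AND an electronic
# descriptor gate (mu +/- 1.96 sigma over the high-activity reference
# ligands), zinc-binding substructure search, and metal-binding-atom
# extraction from 3D complexes (O/N/S/F within 2.8 A of the metal).

#' Load the ZnBF SMARTS pattern table
#'
#' Zinc-binding fragments encoded as SMARTS with their metal-binding
#' atom positions and denticity.  The shipped table contains
#' best-effort encodings of known zinc chelators (hydroxamic acid,
#' sulfonamide, urea, phosphonate and congeners) plus additional
#' candidate fragments; `provenance` distinguishes `"known"` chelators
#' from `"candidate"` encodings.
#'
#' @param path optional CSV with columns `id`, `smarts`,
#'   `binding_atoms`, `denticity`, `provenance`; defaults to the table
#'   shipped with the package.
#' @return Data frame of validated patterns (unparseable SMARTS are
#'   rejected with an error).
#' @export
znbf_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "znbf_smarts.csv", package = "znscreen")
  pat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smarts", "binding_atoms", "denticity", "provenance")
  if (!all(need %in% names(pat)))
    stop_param("pattern table must have columns: %s",
               paste(need, collapse = ", "))
  # validate each SMARTS against a trivial molecule; OpenBabel raises
  # on malformed patterns
  for (i in seq_len(nrow(pat)))
    smarts_match_count(c(probe = "CC(=O)NO"), pat$smarts[i])
  pat
}

#' Build the electronic-descriptor gate
#'
#' For each gated descriptor the closed interval
#' `[mu - multiplier * sigma, mu + multiplier * sigma]` computed from
#' the reference-ligand profiles.  A zero-sigma descriptor yields the
#' degenerate interval `[mu, mu]` (with a warning): only exact matches
#' pass.
#'
#' @param profiles data frame from [profile_descriptors()].
#' @param gated_names descriptors to gate; defaults to the electronic
#'   descriptors present in the profiles.
#' @param multiplier half-width in standard deviations (default 1.96).
#' @return Data frame of class `znbf_gate`: `name`, `mu`, `sigma`,
#'   `lower`, `upper`.
#' @export
build_gate <- function(profiles, gated_names = NULL, multiplier = 1.96) {
  if (is.null(gated_names))
    gated_names <- intersect(electronic_descriptor_names(), profiles$name)
  missing <- setdiff(gated_names, profiles$name)
  if (length(missing))
    stop_param("profiles lack gated descriptors: %s",
               paste(missing, collapse = ", "))
  if (!length(gated_names)) stop_param("no descriptors to gate")
  p <- profiles[match(gated_names, profiles$name), ]
  if (any(p$sigma == 0))
    warning("zero-sigma gate for: ",
            paste(p$name[p$sigma == 0], collapse = ", "),
            " (degenerate interval; only exact matches pass)",
            call. = FALSE)
  out <- data.frame(name = p$name, mu = p$mu, sigma = p$sigma,
                    lower = p$mu - multiplier * p$sigma,
                    upper = p$mu + multiplier * p$sigma,
                    check.names = FALSE, row.names = NULL)
  class(out) <- c("znbf_gate", class(out))
  out
}

#' Screen a library by model prediction and descriptor gate
#'
#' Two-stage AND filter: molecules predicted `"high"` by the model are
#' further required to have every gated descriptor inside its
#' `[lower, upper]` interval (bounds inclusive).  All molecules are
#' reported with per-stage outcomes; `overall_pass` marks the retained
#' set.  Molecules lacking a gated descriptor fail the gate.
#'
#' @param library_desc descriptor data frame or matrix for the library
#'   (must cover the model features; gate descriptors may be missing,
#'   which fails the gate).
#' @param model a `znbf_model`.
#' @param gate a `znbf_gate` from [build_gate()].
#' @return Data frame: `molecule_id`, `predicted_class`, `model_score`,
#'   `gate_pass`, `gate_fail_reason`, `overall_pass`; per-descriptor
#'   gate outcomes in attribute `"gate_detail"`.
#' @export
screen_library <- function(library_desc, model, gate) {
  m <- as_descriptor_matrix(library_desc)
  ids <- rownames(m) %||% paste0("M", seq_len(nrow(m)))
  preds <- predict(model, m)
  scores <- predict(model, m, type = "score")
  present <- intersect(gate$name, colnames(m))
  absent <- setdiff(gate$name, colnames(m))
  pass_mat <- matrix(TRUE, nrow(m), length(gate$name),
                     dimnames = list(ids, gate$name))
  for (nm in present) {
    g <- gate[gate$name == nm, ]
    pass_mat[, nm] <- m[, nm] >= g$lower & m[, nm] <= g$upper
  }
  if (length(absent)) pass_mat[, absent] <- FALSE
  gate_pass <- rowSums(!pass_mat) == 0L
  reason <- apply(pass_mat, 1, function(r)
    if (all(r)) NA_character_ else
      paste(names(r)[!r], collapse = ";"))
  out <- data.frame(molecule_id = ids, predicted_class = preds,
                    model_score = scores, gate_pass = gate_pass,
                    gate_fail_reason = reason,
                    overall_pass = preds == "high" & gate_pass,
                    row.names = NULL)
  attr(out, "gate_detail") <- pass_mat
  out
}

#' Substructure search against ZnBF patterns
#'
#' A molecule is a hit iff at least one pattern matches.  Hits are
#' ranked for follow-up by model score (when given) with the matched
#' pattern count as tiebreak.
#'
#' @param library data frame with `molecule_id` and `smiles`, or a
#'   named character vector of SMILES.
#' @param patterns pattern data frame (see [znbf_patterns()]).
#' @param scores optional named numeric vector of model scores used
#'   for ranking.
#' @return Data frame: `molecule_id`, `n_patterns_matched`,
#'   `matched_patterns` (`;`-separated ids), `hit`; per-pattern counts
#'   in attribute `"pattern_counts"`.
#' @export
substructure_search <- function(library, patterns, scores = NULL) {
  if (is.data.frame(library))
    smiles <- setNames(library$smiles, library$molecule_id)
  else smiles <- library
  if (!length(smiles))
    return(data.frame(molecule_id = character(),
                      n_patterns_matched = integer(),
                      matched_patterns = character(), hit = logical()))
  counts <- sapply(patterns$id, function(pid)
    smarts_match_count(smiles, patterns$smarts[patterns$id == pid]))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(names(smiles), patterns$id))
  matched <- apply(counts, 1, function(r)
    paste(colnames(counts)[r > 0], collapse = ";"))
  out <- data.frame(molecule_id = names(smiles),
                    n_patterns_matched = rowSums(counts > 0),
                    matched_patterns = matched,
                    hit = rowSums(counts > 0) > 0, row.names = NULL)
  if (!is.null(scores)) {
    out$model_score <- unname(scores[out$molecule_id])
    out <- out[order(-out$hit, -out$model_score, -out$n_patterns_matched), ]
    rownames(out) <- NULL
  }
  attr(out, "pattern_counts") <- colSums(counts > 0)
  out
}

#' Extract metal-binding atoms from a 3D complex
#'
#' Reads a PDB-format structure and returns, for each atom of the
#' requested metal element, all O/N/S/F atoms within the distance
#' cutoff (default 2.8 Angstrom), with exact Euclidean distances.  The
#' denticity of a ligand equals its count of binding atoms to one
#' metal.
#'
#' @param path PDB file.
#' @param metal_element element symbol of the metal (default `"Zn"`).
#' @param cutoff distance cutoff in Angstrom (default 2.8, inclusive).
#' @return List of class `znbf_metal_site` per metal atom:
#'   `metal_element`, `metal_coordinates`, and `candidate_atoms` (data
#'   frame: `element`, `x`, `y`, `z`, `distance`, `residue`,
#'   `denticity` per residue tag).
#' @export
extract_binding_atoms <- function(path, metal_element = "Zn",
                                  cutoff = 2.8) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_param("cannot parse PDB file '%s': %s", path,
                               conditionMessage(e)))
  at <- pdb$atom
  elesy <- toupper(trimws(at$elesy))
  metal_rows <- which(elesy == toupper(metal_element))
  if (!length(metal_rows))
    stop_param("no %s atom found in '%s'", metal_element, path)
  donors <- which(elesy %in% c("O", "N", "S", "F"))
  sites <- lapply(metal_rows, function(i) {
    mxyz <- as.numeric(at[i, c("x", "y", "z")])
    if (any(!is.finite(mxyz)))
      stop_param("malformed coordinates for metal atom %d", i)
    d <- sqrt((at$x[donors] - mxyz[1])^2 + (at$y[donors] - mxyz[2])^2 +
                (at$z[donors] - mxyz[3])^2)
    sel <- donors[d <= cutoff]
    cand <- data.frame(element = elesy[sel], x = at$x[sel], y = at$y[sel],
                       z = at$z[sel], distance = d[d <= cutoff],
                       residue = paste(at$resid[sel], at$resno[sel]),
                       row.names = NULL)
    dent <- if (nrow(cand)) table(cand$residue) else table(character(0))
    cand$denticity <- if (nrow(cand)) as.integer(dent[cand$residue]) else
      integer(0)
    structure(list(metal_element = metal_element,
                   metal_coordinates = mxyz, candidate_atoms = cand),
              class = "znbf_metal_site")
  })
  if (length(sites) == 1L) sites[[1]] else sites
}
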