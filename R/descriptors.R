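# 2D descriptor computation and the descriptor filter cascade.
#
# The provider computes a broad hydrogen-suppressed-graph panel with an
# emphasis on the electronic descriptors that drive the screening gate:
# topological charge indices (JGI), polarizability-weighted Burden
# eigenvalues (BCUTp), PEOE partial-charge-binned van der Waals surface
# sums (PEOE_VSA), the largest pi-system size (nAtomP) and H-bond
# acceptor counts.  Externally computed tables (e.g. DFT descriptors)
# are ingested via CSV.

# ---- element property tables ------------------------------------------------

atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                 Br = 79.904, I = 126.904)

# atomic polarizabilities (A^3), standard tabulated values
atomic_polarizability <- c(H = 0.67, B = 3.03, C = 1.76, N = 1.10, O = 0.80,
                           F = 0.56, P = 3.63, S = 2.90, Cl = 2.18,
                           Br = 3.05, I = 5.35)

bondi_radius <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
                  F = 1.47, P = 1.80, S = 1.80, Cl = 1.75,
                  Br = 1.85, I = 1.98)

covalent_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02,
                     Br = 1.20, I = 1.39)

# PEOE (Gasteiger-Marsili) electronegativity coefficients a, b, c by
# element and hybridization; chi(q) = a + b q + c q^2.
peoe_params <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  S.sp2  = c(10.14, 9.13, 1.38),
  P.sp3  = c(8.90, 8.24, 0.96),
  B      = c(7.98, 9.18, 1.88))

#' Names of the electronic descriptors used for gating
#'
#' The eight descriptors found most relevant to metal binding:
#' topological charge indices `JGI8`/`JGI9`, the highest
#' polarizability-weighted Burden eigenvalue `BCUTp-1h`, the PEOE
#' charge-binned surface sums `PEOE_VSA-4` / `PEOE_VSA+1` /
#' `PEOE_VSA-0` (charge bins \[-0.25, -0.20), \[0.05, 0.10) and
#' \[-0.05, 0.00)), the largest pi-system atom count `nAtomP`, and the
#' hydrogen-bond acceptor count `HBA_Count`.
#'
#' @return Character vector of length 8.
#' @export
electronic_descriptor_names <- function() {
  c("JGI8", "JGI9", "BCUTp-1h", "PEOE_VSA-4", "PEOE_VSA+1", "PEOE_VSA-0",
    "nAtomP", "HBA_Count")
}

# ---- atom-level computations ------------------------------------------------

hybridization <- function(mol) {
  hyb <- rep("sp3", mol$natoms)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      for (a in c(mol$bonds$a1[k], mol$bonds$a2[k])) {
        if (o == 2 && hyb[a] == "sp3") hyb[a] <- "sp2"
        else if (o == 2 && hyb[a] == "sp2") hyb[a] <- "sp"  # cumulene
        else if (o >= 3) hyb[a] <- "sp"
      }
    }
  }
  hyb
}

peoe_key <- function(element, hyb) {
  key <- switch(element,
                C = paste0("C.", hyb), N = paste0("N.", hyb),
                O = if (hyb == "sp3") "O.sp3" else "O.sp2",
                S = if (hyb == "sp3") "S.sp3" else "S.sp2",
                P = "P.sp3", element)
  if (!key %in% names(peoe_params)) key <- "C.sp3"
  key
}

# PEOE partial charges by iterative partial equalization (6 cycles,
# damping 0.5^n), on the hydrogen-completed graph.  Returns charges for
# heavy atoms and attached implicit hydrogens.
gasteiger_charges <- function(mol) {
  nh <- implicit_h(mol)
  hyb <- hybridization(mol)
  n_heavy <- mol$natoms
  elements <- c(mol$elements, rep("H", sum(nh)))
  keys <- c(mapply(peoe_key, mol$elements, hyb), rep("H", sum(nh)))
  bonds <- mol$bonds[, c("a1", "a2"), drop = FALSE]
  # attach implicit hydrogens
  if (sum(nh)) {
    hidx <- n_heavy + seq_len(sum(nh))
    owner <- rep(seq_len(n_heavy), nh)
    bonds <- rbind(bonds, data.frame(a1 = owner, a2 = hidx))
  }
  n <- length(elements)
  par <- do.call(rbind, peoe_params[keys])
  chi_plus <- rowSums(par)
  chi_plus[elements == "H"] <- 20.02
  q <- numeric(n)
  if (nrow(bonds)) {
    for (iter in 1:6) {
      damp <- 0.5^iter
      chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
      dq <- numeric(n)
      for (k in seq_len(nrow(bonds))) {
        i <- bonds$a1[k]; j <- bonds$a2[k]
        if (chi[j] > chi[i]) {
          d <- (chi[j] - chi[i]) / chi_plus[i] * damp
          dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
        } else if (chi[i] > chi[j]) {
          d <- (chi[i] - chi[j]) / chi_plus[j] * damp
          dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
        }
      }
      q <- q + dq
    }
  }
  list(q = q, elements = elements, n_heavy = n_heavy, bonds = bonds)
}

# Approximate per-atom accessible van der Waals surface contributions
# (A^2): sphere area minus spherical caps buried by bonded neighbours,
# with ideal bond lengths from covalent radii.
vsa_contributions <- function(elements, bonds, orders = NULL) {
  n <- length(elements)
  R <- bondi_radius[elements]; R[is.na(R)] <- 1.7
  cr <- covalent_radius[elements]; cr[is.na(cr)] <- 0.77
  area <- 4 * pi * R^2
  if (nrow(bonds)) {
    if (is.null(orders)) orders <- rep(1, nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      d <- max(cr[i] + cr[j] - 0.1 * (orders[k] - 1), 1e-3)
      d <- min(d, R[i] + R[j] - 1e-3)  # spheres must overlap
      for (ij in list(c(i, j), c(j, i))) {
        a <- ij[1]; b <- ij[2]
        # height of the cap of sphere a cut off by sphere b
        h <- R[a] - (d^2 + R[a]^2 - R[b]^2) / (2 * d)
        h <- min(max(h, 0), 2 * R[a])
        area[a] <- area[a] - 2 * pi * R[a] * h
      }
    }
  }
  pmax(area, 0)
}

pi_atoms <- function(mol) {
  ispi <- rep(FALSE, mol$natoms)
  if (nrow(mol$bonds)) {
    multi <- mol$bonds$order >= 2
    ispi[unique(c(mol$bonds$a1[multi], mol$bonds$a2[multi]))] <- TRUE
  }
  ispi
}

largest_pi_system <- function(mol) {
  ispi <- pi_atoms(mol)
  if (!any(ispi)) return(0L)
  keep <- which(ispi)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    b[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = keep))
  max(igraph::components(g)$csize)
}

jgi_indices <- function(mol, orders = 1:10) {
  out <- setNames(numeric(length(orders)), paste0("JGI", orders))
  n <- mol$natoms
  if (n < 2L) return(out)
  A <- adjacency_matrix(mol, weighted = FALSE)
  D <- topo_distances(mol)
  Dstar <- ifelse(is.finite(D) & D > 0, 1 / D^2, 0)
  M <- A %*% Dstar
  CT <- M - t(M)
  for (k in seq_along(orders)) {
    sel <- D == orders[k]
    out[k] <- 0.5 * sum(abs(CT[sel])) / (n - 1)
  }
  out
}

bcut_polarizability <- function(mol) {
  n <- mol$natoms
  alpha <- atomic_polarizability[mol$elements]
  alpha[is.na(alpha)] <- 1.76
  if (n == 1L) return(c(`BCUTp-1h` = alpha, `BCUTp-1l` = alpha))
  B <- matrix(0.001, n, n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      w <- 0.1 * mol$bonds$order[k]
      B[mol$bonds$a1[k], mol$bonds$a2[k]] <- w
      B[mol$bonds$a2[k], mol$bonds$a1[k]] <- w
    }
  }
  diag(B) <- alpha
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  c(`BCUTp-1h` = max(ev), `BCUTp-1l` = min(ev))
}

descriptors_for_mol <- function(mol) {
  el <- mol$elements
  nh <- implicit_h(mol)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = mol$natoms)
  D <- topo_distances(mol)
  finD <- D[is.finite(D) & upper.tri(D)]

  g <- gasteiger_charges(mol)
  ords <- c(mol$bonds$order, rep(1, length(g$elements) - mol$natoms))
  vsa <- vsa_contributions(g$elements, g$bonds, ords)
  in_bin <- function(lo, hi) sum(vsa[g$q >= lo & g$q < hi])

  ncomp <- if (mol$natoms == 1L) 1L else {
    gg <- igraph::graph_from_data_frame(
      mol$bonds[, c("a1", "a2")], directed = FALSE,
      vertices = data.frame(name = seq_len(mol$natoms)))
    igraph::components(gg)$no
  }
  nring <- nrow(mol$bonds) - mol$natoms + ncomp

  c(jgi_indices(mol),
    bcut_polarizability(mol),
    `PEOE_VSA-4` = in_bin(-0.25, -0.20),
    `PEOE_VSA+1` = in_bin(0.05, 0.10),
    `PEOE_VSA-0` = in_bin(-0.05, 0.00),
    PEOE_VSA_NEG = sum(vsa[g$q < 0]),
    PEOE_VSA_POS = sum(vsa[g$q >= 0]),
    Q_MIN = if (length(g$q)) min(g$q) else 0,
    Q_MAX = if (length(g$q)) max(g$q) else 0,
    nAtomP = largest_pi_system(mol),
    HBA_Count = sum(el %in% c("N", "O")),
    HBD_Count = sum(el %in% c("N", "O") & nh > 0),
    MW = sum(atomic_mass[el], na.rm = TRUE) + sum(nh) * atomic_mass[["H"]],
    nAtom = mol$natoms,
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nS = sum(el == "S"),
    nHal = sum(el %in% c("F", "Cl", "Br", "I")),
    nRing = nring,
    Wiener = sum(finD),
    Zagreb = sum(deg^2),
    MeanDist = if (length(finD)) mean(finD) else 0,
    FracPi = largest_pi_system(mol) / mol$natoms)
}

# ---- public operations ------------------------------------------------------

#' Compute a 2D descriptor table for a set of structures
#'
#' @param structures named character vector of SMILES (names are ligand
#'   ids), or a data frame with columns `ligand_id` and `smiles`.
#' @param provider `"graph2d"` for the built-in hydrogen-suppressed
#'   graph panel, or `"csv"` to ingest an externally computed table.
#' @param csv_path path to the external table when `provider = "csv"`
#'   (first column must be `ligand_id`).
#' @return Data frame with `ligand_id` first and one numeric column per
#'   descriptor.  Molecules that fail to parse are dropped with a
#'   warning.
#' @export
compute_descriptors <- function(structures, provider = c("graph2d", "csv"),
                                csv_path = NULL) {
  provider <- match.arg(provider)
  if (provider == "csv") {
    if (is.null(csv_path)) stop_param("`csv_path` is required for provider 'csv'")
    return(read_descriptor_csv(csv_path))
  }
  if (is.data.frame(structures))
    structures <- setNames(structures$smiles, structures$ligand_id)
  mols <- parse_smiles(structures)
  mols <- Filter(Negate(is.null), mols)
  if (!length(mols)) stop_param("no parseable structures")
  rows <- lapply(mols, descriptors_for_mol)
  values <- do.call(rbind, rows)
  bad <- apply(values, 2, function(v) all(!is.finite(v)))
  if (any(bad)) {
    warning("dropping all-missing descriptor columns: ",
            paste(colnames(values)[bad], collapse = ", "), call. = FALSE)
    values <- values[, !bad, drop = FALSE]
  }
  out <- data.frame(ligand_id = names(mols), values,
                    check.names = FALSE, row.names = NULL)
  out
}

#' Read a descriptor table from CSV
#'
#' Columns with more than `max_missing` missing values are dropped;
#' remaining missing values are median-imputed (with an audit
#' attribute).
#'
#' @param path CSV file whose first column is `ligand_id`.
#' @param max_missing maximum tolerated fraction of missing values per
#'   column (default 0.2).
#' @return Descriptor data frame (`ligand_id` + numeric columns) with an
#'   `"imputation"` attribute describing any imputed columns.
#' @export
read_descriptor_csv <- function(path, max_missing = 0.2) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ligand_id") names(df)[1] <- "ligand_id"
  num <- df[, -1, drop = FALSE]
  frac_na <- vapply(num, function(v) mean(!is.finite(as.numeric(v))),
                    numeric(1))
  drop <- names(num)[frac_na > max_missing]
  keep <- setdiff(names(num), drop)
  if (length(drop))
    warning("dropping descriptor columns with >",
            round(max_missing * 100), "% missing: ",
            paste(drop, collapse = ", "), call. = FALSE)
  imputed <- character(0)
  for (nm in keep) {
    v <- as.numeric(num[[nm]])
    if (anyNA(v)) {
      v[is.na(v)] <- median(v, na.rm = TRUE)
      imputed <- c(imputed, nm)
    }
    num[[nm]] <- v
  }
  out <- data.frame(ligand_id = as.character(df$ligand_id),
                    num[, keep, drop = FALSE],
                    check.names = FALSE, row.names = NULL)
  attr(out, "imputation") <- imputed
  out
}

#' Three-stage descriptor filter cascade
#'
#' Removes (1) zero-variance descriptors, (2) descriptors whose
#' absolute correlation with `lg_ki` is below `r_min` (0.15), and
#' (3) one of each descriptor pair with absolute pairwise correlation
#' above `r_pair` (0.8), keeping the member better correlated with
#' `lg_ki`.  Pairs are processed in descending absolute pairwise
#' correlation; ties on the activity correlation drop the
#' lexicographically later name.
#'
#' @param desc descriptor data frame (`ligand_id` + numeric columns) or
#'   numeric matrix.
#' @param lg_ki numeric activity vector aligned with the rows.
#' @param r_min minimum absolute correlation to activity (default 0.15).
#' @param r_pair maximum tolerated absolute pairwise correlation
#'   (default 0.8).
#' @param method correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return List with `matrix` (the reduced descriptor data frame) and
#'   `log` (a data frame auditing each removal: name, stage, reason,
#'   statistic).
#' @export
filter_cascade <- function(desc, lg_ki, r_min = 0.15, r_pair = 0.8,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_descriptor_matrix(desc)
  if (nrow(m) < 2L) stop_param("need at least 2 ligands for the cascade")
  if (nrow(m) != length(lg_ki))
    stop_param("descriptor rows (%d) do not match activity length (%d)",
               nrow(m), length(lg_ki))
  log <- list()
  note <- function(name, stage, reason, stat)
    log[[length(log) + 1L]] <<- data.frame(
      name = name, stage = stage, reason = reason, statistic = stat)

  # stage 1: zero variance
  v <- apply(m, 2, var)
  for (nm in colnames(m)[v == 0]) note(nm, 1L, "zero variance", 0)
  m <- m[, v > 0, drop = FALSE]

  # stage 2: weak correlation to activity
  if (ncol(m)) {
    r <- abs(as.numeric(cor(m, lg_ki, method = method)))
    weak <- r < r_min
    for (i in which(weak)) note(colnames(m)[i], 2L,
                                sprintf("|r to lg_ki| < %g", r_min), r[i])
    m <- m[, !weak, drop = FALSE]
    r <- r[!weak]
  } else r <- numeric(0)

  # stage 3: pairwise redundancy
  if (ncol(m) >= 2L) {
    names(r) <- colnames(m)
    cc <- abs(cor(m, method = method))
    pairs <- which(upper.tri(cc) & cc > r_pair, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(cc[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      alive <- setNames(rep(TRUE, ncol(m)), colnames(m))
      for (k in seq_len(nrow(pairs))) {
        a <- colnames(m)[pairs[k, 1]]; b <- colnames(m)[pairs[k, 2]]
        if (!alive[a] || !alive[b]) next
        drop <- if (r[a] < r[b]) a
                else if (r[b] < r[a]) b
                else max(a, b)  # tie: lexicographically later name
        alive[drop] <- FALSE
        note(drop, 3L, sprintf("pairwise |r| > %g with %s", r_pair,
                               if (drop == a) b else a),
             cc[pairs[k, 1], pairs[k, 2]])
      }
      m <- m[, alive, drop = FALSE]
    }
  }

  out <- data.frame(ligand_id = rownames(m) %||% seq_len(nrow(m)), m,
                    check.names = FALSE, row.names = NULL)
  list(matrix = out,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(name = character(), stage = integer(),
                    reason = character(), statistic = numeric()))
}

#' Mann-Whitney U test wrapper
#'
#' Exact enumeration when the smaller group has at most 8 untied
#' observations; normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples for the two groups.
#' @return List with `U` (statistic for group `x`) and `p_value`
#'   (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-descriptor statistical profiles
#'
#' For each descriptor: the mean and standard deviation over the
#' reference class (default the high-activity ligands, the population
#' the screening gate characterizes), the point-biserial correlation
#' with the activity class, a two-sided Mann-Whitney U p-value, an
#' electronic flag, and a "highly correlated" flag (|r| > 0.3 and
#' p < 0.05).
#'
#' @param desc descriptor data frame or matrix.
#' @param class_labels character vector of `"high"`/`"low"` aligned
#'   with rows.
#' @param reference class over which `mu`/`sigma` are computed
#'   (default `"high"`); use `"all"` for the pooled set.
#' @return Data frame with one row per descriptor: `name`, `mu`,
#'   `sigma`, `r_activity`, `p_value`, `is_electronic`, `category`,
#'   `highly_correlated`.
#' @export
profile_descriptors <- function(desc, class_labels,
                                reference = c("high", "low", "all")) {
  reference <- match.arg(reference)
  m <- as_descriptor_matrix(desc)
  y <- check_labels(class_labels)
  if (length(unique(y)) < 2L)
    stop_param("profiling needs both activity classes present")
  ref <- if (reference == "all") rep(TRUE, nrow(m)) else y == reference
  y01 <- as.numeric(y == "high")
  categories <- c(JGI8 = "topological charge", JGI9 = "topological charge",
                  `BCUTp-1h` = "polarizability",
                  `PEOE_VSA-4` = "local charge", `PEOE_VSA+1` = "local charge",
                  `PEOE_VSA-0` = "local charge",
                  nAtomP = "count", HBA_Count = "count")
  rows <- lapply(colnames(m), function(nm) {
    v <- m[, nm]
    r <- if (var(v) == 0) 0 else suppressWarnings(cor(v, y01))
    if (!is.finite(r)) r <- 0
    if (var(v) == 0) {
      p <- 1
    } else {
      p <- mann_whitney_u(v[y == "high"], v[y == "low"])$p_value
    }
    data.frame(name = nm, mu = mean(v[ref]), sigma = sd_pop(v[ref]),
               r_activity = r, p_value = p,
               is_electronic = nm %in% electronic_descriptor_names(),
               category = if (nm %in% names(categories))
                 unname(categories[nm]) else "other",
               highly_correlated = abs(r) > 0.3 & p < 0.05,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# sd with n-1 denominator; 0 for a single observation
sd_pop <- function(v) if (length(v) < 2L) 0 else sd(v)
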