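# Synthetic ligand sets, activity records and fragment libraries with
# planted ground truth.  Structures come from a closed fragment grammar
# (scaffold x linker x cap) so that fingerprints and SMARTS behave
# chemically sensibly; activities come from a two-component lg(Ki)
# distribution (high activity below 2, low above 3); descriptor signal
# is planted class-conditionally on named electronic descriptors.

# grammar pieces; each scaffold has a one-atom ring mutation used to
# build structural near-duplicates
.scaffolds <- data.frame(
  smiles = c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccsc1",
             "c1ccc2ccccc2c1", "C1CCNCC1", "c1ccc(F)cc1", "C1CCOCC1",
             "c1ccc(C)cc1", "c1ccoc1", "c1ccc2[nH]ccc2c1", "C1CCCC1"),
  mutant = c("c1ccncc1", "c1ccnnc1", "C1CCNCC1", "c1ccsc1C",
             "c1ccc2ccncc2c1", "C1CCOCC1", "c1ccc(Cl)cc1", "C1CCSCC1",
             "c1ccc(N)cc1", "c1ccsc1", "c1ccc2occc2c1", "C1CCNC1"),
  stringsAsFactors = FALSE)

.linkers <- c("", "C", "CC", "CCC", "CC(C)", "C=C", "COC", "CNC",
              "CC(=O)")

# zinc-binding caps (hydroxamic acid, sulfonamide, urea, phosphonate),
# each with homologous variants to diversify the emitted structures
.znbf_caps <- list(hydroxamate = c("C(=O)NO", "CC(=O)NO"),
                   sulfonamide = c("S(=O)(=O)N", "S(=O)(=O)NC"),
                   urea        = c("NC(=O)N", "NC(=O)NC"),
                   phosphonate = c("P(=O)(O)O", "CP(=O)(O)O"))

.decoy_caps <- c(methyl = "C", ethyl = "CC", isopropyl = "C(C)C",
                 methoxy = "OC", phenyl = "c1ccccc1", nitrile = "C#N",
                 dimethylamino = "N(C)C", hydroxymethyl = "CO",
                 trifluoromethyl = "C(F)(F)F")

#' Specification for the synthetic data generators
#'
#' Captures the statistical structure the pipeline assumes: a ~131:77
#' high/low activity split, lg(Ki) spanning -4 to 7, a fraction of
#' ligands with multiple (possibly discordant) Ki records, structural
#' near-duplicates with MACCS similarity above 0.75, and a descriptor
#' signal concentrated in named electronic descriptors.
#'
#' @param seed root seed; all generator randomness flows from it via
#'   named substreams.
#' @param n_ligands number of base ligands (near-duplicates are extra).
#' @param high_fraction target fraction of high-activity ligands
#'   (default 131/208).
#' @param lg_ki_range interval containing every generated lg(Ki).
#' @param dup_entry_rate fraction of ligands given 2-4 Ki records.
#' @param discordant_rate fraction of multi-record ligands whose lg(Ki)
#'   spread exceeds 1 (these are discarded at curation).
#' @param near_dup_rate fraction of ligands emitted with a structural
#'   near-duplicate (single-atom ring substitution on a copy).
#' @param boundary_rate fraction of ligands with lg(Ki) inside \[2, 3\]
#'   (excluded at curation); default 0.
#' @param n_informative number of class-informative descriptors,
#'   named to overlap the electronic descriptor panel.
#' @param n_noise number of pure-noise descriptors.
#' @param effect_size standardized mean difference between classes on
#'   informative descriptors.
#' @param noise_sd dispersion of uninformative descriptors.
#' @param planted_znbf_ids zinc-binding cap identifiers guaranteed
#'   present in active synthetic structures (subset of
#'   `c("hydroxamate", "sulfonamide", "urea", "phosphonate")`).
#' @return Object of class `znbf_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_ligands = 208L,
                           high_fraction = 131 / 208,
                           lg_ki_range = c(-4, 7),
                           dup_entry_rate = 0.3,
                           discordant_rate = 0.15,
                           near_dup_rate = 0.12,
                           boundary_rate = 0,
                           n_informative = 8L,
                           n_noise = 42L,
                           effect_size = 1.5,
                           noise_sd = 1,
                           planted_znbf_ids = names(.znbf_caps)) {
  n_ligands <- check_count(n_ligands, "n_ligands", min = 10L)
  check_proportion(high_fraction, "high_fraction")
  if (!is.numeric(lg_ki_range) || length(lg_ki_range) != 2L ||
      lg_ki_range[1] >= lg_ki_range[2])
    stop_param("`lg_ki_range` must be an increasing interval")
  for (nm in c("dup_entry_rate", "discordant_rate", "near_dup_rate",
               "boundary_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_param("`%s` must be in [0, 1]", nm)
  }
  check_count(n_informative, "n_informative", min = 1L)
  check_count(n_noise, "n_noise", min = 0L)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop_param("`effect_size` must be non-negative")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_param("`noise_sd` must be positive")
  bad <- setdiff(planted_znbf_ids, names(.znbf_caps))
  if (length(bad))
    stop_param("unknown planted ZnBF ids: %s", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), n_ligands = n_ligands,
                 high_fraction = high_fraction, lg_ki_range = lg_ki_range,
                 dup_entry_rate = dup_entry_rate,
                 discordant_rate = discordant_rate,
                 near_dup_rate = near_dup_rate,
                 boundary_rate = boundary_rate,
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size, noise_sd = noise_sd,
                 planted_znbf_ids = planted_znbf_ids),
            class = "znbf_synthetic_spec")
}

# assemble one structure from grammar indices
assemble_smiles <- function(scaf_idx, linker_idx, cap, mutated = FALSE) {
  scaf <- if (mutated) .scaffolds$mutant[scaf_idx] else
    .scaffolds$smiles[scaf_idx]
  paste0(scaf, .linkers[linker_idx], cap)
}

# lg(Ki) centers are kept 0.5 away from the class cut-offs and 0.8
# inside the global range so that per-record jitter and discordant
# offsets never cross a class boundary or leave the range
sample_lg_ki <- function(n, class, range) {
  lo_hi <- c(max(range[1] + 0.9, -3.5), 1.95)
  lo_lo <- c(3.05, min(range[2] - 0.9, 6.5))
  out <- numeric(n)
  hi <- class == "high"
  out[hi] <- pmin(pmax(rnorm(sum(hi), 0.6, 1.3), lo_hi[1]), lo_hi[2])
  out[!hi] <- pmin(pmax(rnorm(sum(!hi), 4.6, 1.1), lo_lo[1]), lo_lo[2])
  out
}

#' Generate a synthetic ligand set with activity records
#'
#' Emits per-ligand structures (valid SMILES from the fragment grammar,
#' zinc-binding caps on high-activity ligands) and one or more
#' `(source_id, ki_nM)` records per ligand.  Multi-record ligands have
#' either a concordant lg(Ki) spread (strictly below 1, mean equal to
#' the true value) or a planted discordant spread above 1.  A fraction
#' of ligands is emitted with a structural near-duplicate (single-atom
#' ring substitution, same activity class).
#'
#' @param spec a [synthetic_spec()].
#' @return List with `ligands` (data frame: `ligand_id`, `smiles`,
#'   `true_class`, `true_lg_ki`, `has_znbf`, `znbf_id`, `parent_id`)
#'   and `records` (data frame: `ligand_id`, `source_id`, `ki_nM`).
#' @export
generate_ligand_set <- function(spec) {
  stopifnot(inherits(spec, "znbf_synthetic_spec"))
  n <- spec$n_ligands
  n_boundary <- round(spec$boundary_rate * n)
  n_main <- n - n_boundary
  n_high <- round(n_main * spec$high_fraction)

  ligands <- with_stream(spec$seed, "structures", {
    class <- sample(c(rep("high", n_high), rep("low", n_main - n_high),
                      rep("excluded", n_boundary)))
    scaf <- sample.int(nrow(.scaffolds), n, replace = TRUE)
    link <- sample.int(length(.linkers), n, replace = TRUE)
    znbf <- ifelse(class == "high",
                   sample(spec$planted_znbf_ids, n, replace = TRUE),
                   NA_character_)
    cap <- sample(.decoy_caps, n, replace = TRUE)
    hi <- which(class == "high")
    cap[hi] <- vapply(znbf[hi], function(id) sample(.znbf_caps[[id]], 1L),
                      character(1))
    data.frame(ligand_id = sprintf("LIG%04d", seq_len(n)),
               smiles = mapply(assemble_smiles, scaf, link, cap),
               true_class = class,
               scaf = scaf, link = link, cap = cap,
               has_znbf = class == "high",
               znbf_id = znbf, parent_id = NA_character_,
               stringsAsFactors = FALSE)
  })

  ligands$true_lg_ki <- with_stream(spec$seed, "activities", {
    lg <- sample_lg_ki(n, ligands$true_class, spec$lg_ki_range)
    lg[ligands$true_class == "excluded"] <- runif(n_boundary, 2, 3)
    lg
  })

  # structural near-duplicates: single-atom edits on a copy of a base
  # ligand, same class, activity jittered within the class band.  Each
  # candidate edit (ring-atom substitution, one-carbon linker
  # extension, terminal methyl) is verified against the parent's MACCS
  # fingerprint at generation time, so emitted near-duplicates are
  # guaranteed above 0.75 similarity; parents on which no single-atom
  # edit stays that similar are skipped.
  ligands <- with_stream(spec$seed, "near_dups", {
    n_nd <- round(spec$near_dup_rate * n)
    if (n_nd > 0) {
      order_try <- sample.int(n)
      nd_rows <- list()
      for (i in order_try) {
        if (length(nd_rows) >= n_nd) break
        cand <- unique(c(
          assemble_smiles(ligands$scaf[i], ligands$link[i], ligands$cap[i],
                          mutated = TRUE),
          paste0(.scaffolds$smiles[ligands$scaf[i]], "C",
                 .linkers[ligands$link[i]], ligands$cap[i]),
          paste0("C", ligands$smiles[i])))
        sim <- maccs_similarity(c(parent = ligands$smiles[i],
                                  setNames(cand, paste0("c", seq_along(cand)))))
        s <- sim["parent", -1]
        if (!any(s > 0.75)) next
        nd <- ligands[i, ]
        nd$ligand_id <- sprintf("%sD", ligands$ligand_id[i])
        nd$parent_id <- ligands$ligand_id[i]
        nd$smiles <- cand[which.max(s)]
        nd$true_lg_ki <- min(max(nd$true_lg_ki + rnorm(1, 0, 0.15),
                                 if (nd$true_class == "high") -3.5 else 3.05),
                             if (nd$true_class == "high") 1.95 else 6.5)
        nd_rows[[length(nd_rows) + 1L]] <- nd
      }
      if (length(nd_rows) < n_nd)
        warning("only ", length(nd_rows), " of ", n_nd,
                " requested near-duplicates admit a similar single-atom edit",
                call. = FALSE)
      rbind(ligands, do.call(rbind, nd_rows))
    } else ligands
  })
  ligands$scaf <- ligands$link <- ligands$cap <- NULL
  rownames(ligands) <- NULL

  records <- with_stream(spec$seed, "records", {
    rows <- lapply(seq_len(nrow(ligands)), function(i) {
      multi <- runif(1) < spec$dup_entry_rate
      k <- if (multi) sample(2:4, 1) else 1L
      lg <- ligands$true_lg_ki[i]
      if (k == 1L) {
        offs <- 0
      } else if (runif(1) < spec$discordant_rate) {
        # spread is at least 1.6 > 1, so the ligand is discarded at merge
        offs <- c(-0.8, 0.8, if (k > 2L) runif(k - 2L, -0.5, 0.5))
      } else {
        offs <- runif(k, -0.45, 0.45)
        offs <- offs - mean(offs)  # merged mean equals the true lg(Ki)
      }
      data.frame(ligand_id = ligands$ligand_id[i],
                 source_id = sprintf("%s_E%d", ligands$ligand_id[i],
                                     seq_len(k)),
                 ki_nM = 10^(lg + offs), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(records) <- NULL
  list(ligands = ligands, records = records)
}

# per-column location/scale for descriptor columns, shared between the
# ligand table and the fragment library so that gate and library live
# on the same scale
descriptor_params <- function(spec) {
  with_stream(spec$seed, "desc_params", {
    p <- spec$n_informative + spec$n_noise
    info_names <- electronic_descriptor_names()
    if (spec$n_informative > length(info_names))
      info_names <- c(info_names,
                      sprintf("INFO_%d", seq_len(spec$n_informative -
                                                   length(info_names)) + 8L))
    list(info_names = info_names[seq_len(spec$n_informative)],
         noise_names = if (spec$n_noise)
           sprintf("D%03d", seq_len(spec$n_noise)) else character(0),
         loc = runif(p, -2, 2), scale = runif(p, 0.5, 3))
  })
}

draw_descriptor_rows <- function(spec, class, stream) {
  par <- descriptor_params(spec)
  n <- length(class)
  with_stream(spec$seed, stream, {
    p_info <- length(par$info_names)
    shift <- ifelse(class == "high", spec$effect_size,
                    ifelse(class == "low", 0, spec$effect_size / 2))
    info <- matrix(rnorm(n * p_info), n, p_info) + shift
    noise <- matrix(rnorm(n * spec$n_noise, sd = spec$noise_sd), n,
                    spec$n_noise)
    raw <- cbind(info, noise)
    scaled <- sweep(sweep(raw, 2, par$scale, "*"), 2, par$loc, "+")
    colnames(scaled) <- c(par$info_names, par$noise_names)
    # planted cascade exercisers: a zero-variance column and a
    # collinear pair (|r| > 0.8 by construction)
    base <- rnorm(n)
    coll_b <- 0.95 * base + 0.05 * rnorm(n)
    cbind(scaled, DZV = 3.14, DCOLL_A = base, DCOLL_B = coll_b)
  })
}

#' Generate a descriptor table with planted class signal
#'
#' Informative columns are drawn class-conditionally with the spec's
#' standardized effect size and named to overlap the electronic
#' descriptor panel; uninformative columns are pure noise.  One
#' zero-variance column (`DZV`) and one collinear pair
#' (`DCOLL_A`/`DCOLL_B`, |r| > 0.8) are always planted to exercise the
#' filter cascade.
#'
#' @param spec a [synthetic_spec()].
#' @param ligands ligand data frame from [generate_ligand_set()].
#' @return Descriptor data frame (`ligand_id` + numeric columns).
#' @export
generate_descriptor_table <- function(spec, ligands) {
  stopifnot(inherits(spec, "znbf_synthetic_spec"))
  if (!nrow(ligands)) stop_param("`ligands` must be nonempty")
  vals <- draw_descriptor_rows(spec, ligands$true_class, "descriptors")
  data.frame(ligand_id = ligands$ligand_id, vals,
             check.names = FALSE, row.names = NULL)
}

#' Generate a fragment library with planted actives
#'
#' Builds a screening library in which exactly `n_actives` molecules
#' carry a planted zinc-binding substructure and descriptor values
#' drawn from the high-activity distribution (hence inside the
#' mu +/- 1.96 sigma gate in expectation); the remainder are decoys
#' with low-activity-like descriptors.  Truth labels are retained for
#' enrichment tests.
#'
#' @param spec a [synthetic_spec()].
#' @param n_molecules library size (default 2000).
#' @param n_actives number of planted actives (default 5% of
#'   `n_molecules`).
#' @return List with `molecules` (data frame: `molecule_id`, `smiles`,
#'   `is_active`, `znbf_id`) and `descriptors` (data frame).
#' @export
generate_fragment_library <- function(spec, n_molecules = 2000L,
                                      n_actives = round(0.05 * n_molecules)) {
  stopifnot(inherits(spec, "znbf_synthetic_spec"))
  n_molecules <- check_count(n_molecules, "n_molecules", min = 1L)
  n_actives <- check_count(n_actives, "n_actives", min = 0L)
  if (n_actives > n_molecules)
    stop_param("`n_actives` cannot exceed `n_molecules`")
  mols <- with_stream(spec$seed, "library", {
    active <- sample(c(rep(TRUE, n_actives),
                       rep(FALSE, n_molecules - n_actives)))
    scaf <- sample.int(nrow(.scaffolds), n_molecules, replace = TRUE)
    link <- sample.int(length(.linkers), n_molecules, replace = TRUE)
    znbf <- ifelse(active, sample(spec$planted_znbf_ids, n_molecules,
                                  replace = TRUE), NA_character_)
    cap <- sample(.decoy_caps, n_molecules, replace = TRUE)
    act <- which(active)
    cap[act] <- vapply(znbf[act], function(id) sample(.znbf_caps[[id]], 1L),
                       character(1))
    data.frame(molecule_id = sprintf("FRAG%05d", seq_len(n_molecules)),
               smiles = mapply(assemble_smiles, scaf, link, cap),
               is_active = active, znbf_id = znbf,
               stringsAsFactors = FALSE)
  })
  vals <- draw_descriptor_rows(
    spec, ifelse(mols$is_active, "high", "low"), "library_descriptors")
  desc <- data.frame(ligand_id = mols$molecule_id, vals,
                     check.names = FALSE, row.names = NULL)
  list(molecules = mols, descriptors = desc)
}

#' Write synthetic outputs to disk
#'
#' Writes structures as a `.smi` file (`SMILES<TAB>id`), activity
#' records and descriptors as CSV, and ground-truth labels as a JSON
#' sidecar.
#'
#' @param ligand_set output of [generate_ligand_set()].
#' @param descriptors optional descriptor data frame.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_set <- function(ligand_set, descriptors = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(smi = file.path(dir, "structures.smi"),
             activity = file.path(dir, "activity.csv"),
             truth = file.path(dir, "ground_truth.json"))
  writeLines(paste(ligand_set$ligands$smiles, ligand_set$ligands$ligand_id,
                   sep = "\t"), paths["smi"])
  write.csv(ligand_set$records, paths["activity"], row.names = FALSE)
  jsonlite::write_json(
    ligand_set$ligands[, c("ligand_id", "true_class", "true_lg_ki",
                           "has_znbf", "znbf_id", "parent_id")],
    paths["truth"], dataframe = "rows", na = "null")
  if (!is.null(descriptors)) {
    paths["descriptors"] <- file.path(dir, "descriptors.csv")
    write.csv(descriptors, paths["descriptors"], row.names = FALSE)
  }
  invisible(paths)
}
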