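# Screening: the mu +/- 1.96 sigma descriptor gate, the two-stage
# prediction+gate library filter, SMARTS substructure search against
# the ZnBF table, and metal-binding-atom extraction from PDB files.

test_that("gate intervals follow mu +/- 1.96 sigma", {
  prof <- data.frame(name = c("JGI8", "HBA_Count"), mu = c(10, 3),
                     sigma = c(2, 1))
  g <- build_gate(prof, gated_names = c("JGI8", "HBA_Count"))
  expect_equal(g$lower, c(10 - 1.96 * 2, 3 - 1.96))
  expect_equal(g$upper, c(13.92, 4.96))
  g2 <- build_gate(prof, gated_names = c("JGI8", "HBA_Count"))
  expect_identical(g, g2)
})

test_that("zero-sigma descriptors gate to a degenerate interval", {
  prof <- data.frame(name = "nAtomP", mu = 6, sigma = 0)
  expect_warning(g <- build_gate(prof, gated_names = "nAtomP"),
                 "degenerate")
  expect_equal(g$lower, 6)
  expect_equal(g$upper, 6)
})

test_that("build_gate validates its inputs", {
  prof <- data.frame(name = "JGI8", mu = 1, sigma = 1)
  expect_error(build_gate(prof, gated_names = "missing_one"), "lack")
})

# a permissive stub model so gate behaviour can be tested in isolation
all_high_model <- function(features) {
  x <- matrix(rep(c(0, 1), each = 2), ncol = 1,
              dimnames = list(NULL, features[1]))
  structure(list(algorithm = "zeror", hyperparams = list(),
                 feature_names = features[1],
                 fitted = list(majority = "high", p_high = 1),
                 classes = c("high", "low")),
            class = c("znbf_zeror", "znbf_model"))
}

test_that("gate passes values at mu and fails values at mu + 2 sigma", {
  prof <- data.frame(name = c("JGI8", "HBA_Count"), mu = c(10, 3),
                     sigma = c(2, 1))
  gate <- build_gate(prof, gated_names = c("JGI8", "HBA_Count"))
  model <- all_high_model(c("JGI8", "HBA_Count"))
  lib <- data.frame(ligand_id = c("at_mu", "at_2sigma", "boundary"),
                    `JGI8` = c(10, 10 + 2 * 2, 10 + 1.96 * 2),
                    `HBA_Count` = c(3, 3, 3), check.names = FALSE)
  hits <- screen_library(lib, model, gate)
  expect_identical(hits$overall_pass,
                   c(TRUE, FALSE, TRUE))  # inclusive bounds
  expect_identical(hits$gate_fail_reason[2], "JGI8")
})

test_that("molecules lacking a gated descriptor fail the gate", {
  prof <- data.frame(name = c("JGI8", "HBA_Count"), mu = c(0, 3),
                     sigma = c(1, 1))
  gate <- build_gate(prof, gated_names = c("JGI8", "HBA_Count"))
  model <- all_high_model("JGI8")
  lib <- data.frame(ligand_id = "m1", JGI8 = 0, check.names = FALSE)
  hits <- screen_library(lib, model, gate)
  expect_false(hits$overall_pass)
  expect_match(hits$gate_fail_reason, "HBA_Count")
})

test_that("tightening the gate multiplier only shrinks the retained set", {
  sp <- synthetic_spec(seed = 9, n_ligands = 150, effect_size = 1.5)
  lig <- generate_ligand_set(sp)
  base <- lig$ligands[is.na(lig$ligands$parent_id), ]
  dt <- generate_descriptor_table(sp, lig$ligands)
  x <- dt[match(base$ligand_id, dt$ligand_id), ]
  prof <- profile_descriptors(x, base$true_class)
  model <- fit_classifier("nb", x[, c("ligand_id",
                                      electronic_descriptor_names())],
                          base$true_class)
  lib <- generate_fragment_library(sp, 400, 40)
  wide <- screen_library(lib$descriptors, model,
                         build_gate(prof, multiplier = 1.96))
  narrow <- screen_library(lib$descriptors, model,
                           build_gate(prof, multiplier = 1.0))
  expect_true(all(narrow$molecule_id[narrow$overall_pass] %in%
                    wide$molecule_id[wide$overall_pass]))
})

test_that("screen enriches planted actives over prevalence", {
  sp <- synthetic_spec(seed = 10, n_ligands = 200, effect_size = 1.5)
  lig <- generate_ligand_set(sp)
  base <- lig$ligands[is.na(lig$ligands$parent_id), ]
  dt <- generate_descriptor_table(sp, lig$ligands)
  x <- dt[match(base$ligand_id, dt$ligand_id), ]
  prof <- profile_descriptors(x, base$true_class)
  model <- fit_classifier("nb", x, base$true_class)
  lib <- generate_fragment_library(sp, 1000, 50)
  hits <- screen_library(lib$descriptors, model, build_gate(prof))
  kept <- hits$molecule_id[hits$overall_pass]
  truth <- setNames(lib$molecules$is_active, lib$molecules$molecule_id)
  expect_gt(length(kept), 0)
  precision <- mean(truth[kept])
  expect_gte(precision / 0.05, 5)
  # a library with no planted actives yields no true actives
  lib0 <- generate_fragment_library(sp, 200, 0)
  hits0 <- screen_library(lib0$descriptors, model, build_gate(prof))
  truth0 <- setNames(lib0$molecules$is_active, lib0$molecules$molecule_id)
  expect_identical(sum(truth0[hits0$molecule_id[hits0$overall_pass]]), 0L)
})

test_that("the shipped ZnBF pattern table loads and validates", {
  pat <- znbf_patterns()
  expect_identical(nrow(pat), 15L)
  expect_true(all(pat$denticity %in% c("monodentate", "bidentate")))
  expect_true(all(pat$provenance %in% c("known", "candidate")))
  expect_true(all(c("hydroxamic_acid", "sulfonamide", "urea",
                    "phosphonate") %in% pat$id[pat$provenance == "known"]))
})

test_that("a hydroxamate drug matches and methane matches nothing", {
  pat <- znbf_patterns()
  res <- substructure_search(
    c(vorinostat = "O=C(Nc1ccccc1)CCCCCCC(=O)NO", methane = "C"), pat)
  expect_true(res$hit[res$molecule_id == "vorinostat"])
  expect_match(res$matched_patterns[res$molecule_id == "vorinostat"],
               "hydroxamic_acid")
  expect_false(res$hit[res$molecule_id == "methane"])
})

test_that("a constructed 10-molecule library yields exactly the planted hits", {
  pat <- znbf_patterns()
  smiles <- c(
    h1 = "c1ccccc1CC(=O)NO",          # hydroxamate
    h2 = "C1CCCCC1S(=O)(=O)N",        # sulfonamide
    h3 = "c1ccccc1NC(=O)N",           # urea
    h4 = "CCP(=O)(O)O",               # phosphonate
    d1 = "c1ccccc1CC", d2 = "C1CCCCC1C", d3 = "CCCCC",
    d4 = "c1ccc2ccccc2c1", d5 = "CC(C)CC", d6 = "CCCl")
  res <- substructure_search(smiles, pat)
  expect_identical(sum(res$hit), 4L)
  expect_setequal(res$molecule_id[res$hit], c("h1", "h2", "h3", "h4"))
  # independent check: every flagged hit matches at least one pattern
  for (id in res$molecule_id[res$hit]) {
    n <- sum(vapply(pat$smarts, function(p)
      smarts_match_count(smiles[id], p) > 0, logical(1)))
    expect_gte(n, 1)
  }
})

test_that("substructure search is order-invariant and unions per-pattern hits", {
  pat <- znbf_patterns()[1:4, ]
  smiles <- c(a = "c1ccccc1CC(=O)NO", b = "CCCC", c = "CCS(=O)(=O)N",
              d = "CCO")
  fwd <- substructure_search(smiles, pat)
  rev <- substructure_search(rev(smiles), pat)
  expect_setequal(fwd$molecule_id[fwd$hit], rev$molecule_id[rev$hit])
  per_pattern <- lapply(seq_len(nrow(pat)), function(i)
    names(which(smarts_match_count(smiles, pat$smarts[i]) > 0)))
  expect_setequal(fwd$molecule_id[fwd$hit],
                  unique(unlist(per_pattern)))
})

test_that("invalid SMARTS are rejected at load", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "bad", smarts = "[CX3](=[OX1]",
                       binding_atoms = "1", denticity = "monodentate",
                       provenance = "candidate"), path, row.names = FALSE)
  expect_error(znbf_patterns(path), "invalid SMARTS")
})

test_that("metal-site extraction applies the 2.8 A O/N/S/F rule exactly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_metal_pdb(path)
  site <- extract_binding_atoms(path, "Zn", cutoff = 2.8)
  cand <- site$candidate_atoms
  # exactly the O at 2.5, N at sqrt(6), S at 2.8 (inclusive boundary);
  # carbon excluded by element, O at 3.0 and F at 2.806 by distance
  expect_setequal(cand$element, c("O", "N", "S"))
  expect_equal(sort(cand$distance), sort(c(2.5, sqrt(6), 2.8)),
               tolerance = 1e-6)
  # denticity counts binding atoms per residue tag
  expect_identical(cand$denticity[cand$residue == "LIG 2"], c(2L, 2L))
  expect_identical(cand$denticity[cand$residue == "HIS 3"], 1L)
  expect_error(extract_binding_atoms(path, "Fe"), "no Fe atom")
})
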