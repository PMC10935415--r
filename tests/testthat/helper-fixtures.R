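# Fixture builders shared across test files.  Everything is generated
# in code; nothing is read from disk.

# random two-class toy table with an optional planted signal column
make_toy_table <- function(seed, n = 20L, p = 2L, effect = 0) {
  withr::with_seed(seed, {
    y <- rep(c("high", "low"), length.out = n)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    if (effect != 0) x[, 1] <- x[, 1] + ifelse(y == "high", effect, 0)
    list(x = x, y = y)
  })
}

# The hand-enumerated 12-ligand curation fixture:
#   L01 high, kept                L07 low, kept
#   L02 high, near-dup of L01 (MACCS 0.865) -> pruned
#   L03 low, near-dup of L01 (cross-class) -> kept
#   L04, L05 high, kept           L08 low, kept
#   L06 low, kept
#   L09 lg(Ki) = 2.5 -> excluded  L10 lg(Ki) = 2.0 -> excluded (boundary)
#   L11, L12 discordant Ki spread > 1 -> discarded
# Expected retained ids: L01 L03 L04 L05 L06 L07 L08 (7 entries).
curation_fixture <- function() {
  structures <- c(
    L01 = "c1ccccc1CCC(=O)NO",
    L02 = "c1ccncc1CCC(=O)NO",
    L03 = "Cc1ccccc1CCC(=O)NO",
    L04 = "C1CCCCC1CS(=O)(=O)N",
    L05 = "c1ccsc1NC(=O)N",
    L06 = "c1ccc2ccccc2c1CCCC",
    L07 = "C1CCOCC1CC(C)C",
    L08 = "c1ccc(F)cc1COC",
    L09 = "c1ccccc1CC#N",
    L10 = "C1CCCCC1CCO",
    L11 = "c1ccncc1CC(=O)NO",
    L12 = "C1CCNCC1CS(=O)(=O)N")
  records <- data.frame(
    ligand_id = c("L01", "L02", "L02", "L03", "L04", "L05", "L06", "L07",
                  "L08", "L09", "L10", "L11", "L11", "L12", "L12"),
    source_id = paste0("E", 1:15),
    ki_nM = c(1,            # L01: lg 0 -> high
              10, 50,       # L02: merged lg 1.349 -> high
              10^4.2,       # L03: low
              5,            # L04: high
              0.5,          # L05: high
              10^5,         # L06: low
              10^3.8,       # L07: low
              10^4.5,       # L08: low
              10^2.5,       # L09: excluded
              10^2,         # L10: boundary, excluded
              10, 10^4,     # L11: spread 3 -> discarded
              1, 500))      # L12: spread 2.7 -> discarded
  list(structures = structures, records = records,
       expected_ids = c("L01", "L03", "L04", "L05", "L06", "L07", "L08"))
}

# constructed PDB with a zinc atom at the origin and donor/non-donor
# atoms at exactly known distances
write_metal_pdb <- function(path) {
  row <- function(serial, name, resid, resno, x, y, z, el)
    sprintf("HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resid, resno, x, y, z, 1, 0, el)
  writeLines(c(
    row(1, "ZN", "ZN", 1, 0, 0, 0, "ZN"),
    row(2, "O1", "LIG", 2, 2.5, 0, 0, "O"),        # in: d = 2.5
    row(3, "C1", "LIG", 2, 2.0, 0, 0, "C"),        # out: carbon
    row(4, "O2", "LIG", 2, 3.0, 0, 0, "O"),        # out: d = 3.0
    row(5, "N1", "LIG", 2, 1.0, 2.0, 1.0, "N"),    # in: d = sqrt(6)
    row(6, "S1", "HIS", 3, 0, 0, 2.8, "S"),        # in: d = 2.8 (boundary)
    row(7, "F1", "LIG", 2, 1.62, 1.62, 1.62, "F"), # out: d = 2.806 > 2.8
    "END"), path)
  invisible(path)
}
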