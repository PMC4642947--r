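# Shared fixtures.  Expensive objects (reference bundle, null libraries)
# are built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

# the reference synthetic bundle: N = 300, L = 120, 8 planted pairs at
# coupling 0.9 on two 6-residue segments, seed 11
refBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generateMSA(syntheticSpec(seed = 11L))
  .fixtures$bundle
}

refMatrix <- function() {
  if (is.null(.fixtures$D))
    .fixtures$D <- coevolutionMatrix(refBundle()$alignment)
  .fixtures$D
}

refNull <- function(K = 20L) {
  key <- paste0("null", K)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildNullLibrary(refBundle()$alignment, K = K,
                                         seed = 42L, keepMatrices = TRUE)
  .fixtures[[key]]
}

# small alignment from literal strings
msaFrom <- function(..., ids = NULL) {
  ProteinMSA(c(...), ids = ids)
}

# tiny PDB fixture: three residues (ALA/GLY/SER), chain A, one with a
# second altloc Calpha at lower occupancy; optionally a residue with no
# Calpha, or a residue-type switch for mismatch tests
writeTinyPDB <- function(path, altloc = FALSE, missingCA = FALSE,
                         aa3 = c("ALA", "GLY", "SER")) {
  lines <- c(
    sprintf("ATOM      1  N   %s A   1       0.000   1.000   0.000  1.00  0.00           N", aa3[1]),
    sprintf("ATOM      2  CA  %s A   1       0.000   0.000   0.000  1.00  0.00           C", aa3[1]),
    if (altloc)
      sprintf("ATOM      3  CA B%s A   1       9.000   9.000   9.000  0.30  0.00           C", aa3[1]),
    sprintf("ATOM      4  CA  %s A   2       3.000   4.000   0.000  1.00  0.00           C", aa3[2]),
    if (!missingCA)
      sprintf("ATOM      5  CA  %s A   3       6.000   8.000   0.000  1.00  0.00           C", aa3[3]),
    if (missingCA)
      sprintf("ATOM      5  CB  %s A   3       6.000   8.000   0.000  1.00  0.00           C", aa3[3]),
    "END")
  writeLines(lines, path)
  path
}

# altloc variant where the A record carries the alt flag too
expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M)), na.rm = TRUE), tol)
}
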