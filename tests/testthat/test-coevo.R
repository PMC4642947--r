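# Coupling-matrix estimation: frequencies, MI, APC, graphical lasso,
# direct information, normalization, thresholding.

test_that("pair frequencies: joint tables, weighting, independence", {
  aln <- msaFrom("AR", "AR", ids = c("a", "b"))
  pf <- pairFrequencies(aln, weighting = "none", pseudocount = 0)
  jt <- jointTable(pf, 1L, 2L)
  expect_equal(jt["A", "R"], 1)
  expect_equal(sum(jt), 1)

  # three identical sequences at theta = 0.62: weights 1/3, neff 1
  aln3 <- msaFrom("ACDE", "ACDE", "ACDE", ids = c("a", "b", "c"))
  pf3 <- pairFrequencies(aln3, weighting = "identity_cluster",
                         theta = 0.62)
  expect_equal(unname(pf3$weights), rep(1 / 3, 3))
  expect_equal(pf3$neff, 1)

  # independent columns: joint = product of marginals (counts by hand)
  aln4 <- msaFrom("AR", "AK", "CR", "CK", ids = letters[1:4])
  pf4 <- pairFrequencies(aln4, weighting = "none", pseudocount = 0)
  jt4 <- jointTable(pf4, 1L, 2L)
  expect_equal(jt4["A", "R"], 0.25)
  expect_equal(jt4["C", "K"], 0.25)
  expect_equal(rowSums(jt4)[["A"]] * colSums(jt4)[["R"]], jt4["A", "R"])
})

test_that("MI matrix reproduces hand-computed 2x2 joint-table cases", {
  # perfectly covarying binary columns: AR/AR/RA/RA
  aln <- msaFrom("AR", "AR", "RA", "RA", ids = letters[1:4])
  pf <- pairFrequencies(aln, weighting = "none", pseudocount = 0)
  MI <- miMatrix(pf, normalized = FALSE)
  expect_equal(MI[1L, 2L], 1)                 # MI = 1 bit
  nMI <- miMatrix(pf, normalized = TRUE)
  expect_equal(nMI[1L, 2L], 1)                # S_joint = 1 -> nMI = 1
  # diagonal carries the self-information S_i
  expect_equal(MI[1L, 1L], 1)
  expect_symmetric(MI)
})

test_that("MI of independent uniform columns vanishes with depth", {
  set.seed(7)
  m <- cbind(sample(c("A", "R"), 1000, TRUE),
             sample(c("A", "R"), 1000, TRUE))
  aln <- ProteinMSA(m)
  pf <- pairFrequencies(aln, weighting = "none", pseudocount = 0)
  MI <- miMatrix(pf, normalized = FALSE)
  # sampling bias of a 2x2 table at N = 1000 is ~ 1/(2N ln 2) << 0.01
  expect_lt(MI[1L, 2L], 0.01)
})

test_that("APC correction matches hand arithmetic and edge cases", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.4
  M[1, 3] <- M[3, 1] <- 0.2
  M[2, 3] <- M[3, 2] <- 0.2
  out <- apcCorrect(M)
  # mean_1 = 0.3, mean_2 = 0.3, grand = 0.2667
  expect_equal(out[1, 2], 0.4 - 0.3 * 0.3 / (0.8 / 3), tolerance = 1e-12)
  expect_equal(out[1, 2], 0.0625)
  expect_symmetric(out)

  # constant off-diagonal: correction annihilates it
  Mc <- matrix(0.7, 4, 4)
  outc <- apcCorrect(Mc)
  off <- outc[upper.tri(outc)]
  expect_true(all(abs(off) < 1e-12))

  expect_warning(apcCorrect(matrix(0, 3, 3)), "skipped")
})

test_that("graphical lasso at rho = 0 equals the closed-form inverse", {
  M <- matrix(c(1, 0.5, 0.5, 1), 2)
  P <- sparseInverse(M, rho = 0)
  expect_equal(P$W, matrix(c(4, -2, -2, 4) / 3, 2), tolerance = 1e-6)

  # random 6x6 SPD matrices against the dense-inverse oracle
  set.seed(21)
  for (r in 1:10) {
    A <- matrix(rnorm(36), 6)
    S <- crossprod(A) / 6 + diag(6) * 0.5
    P6 <- sparseInverse(S, rho = 0)
    expect_equal(P6$W, solve(S), tolerance = 1e-6)
  }
})

test_that("graphical lasso shrinks off-diagonals at large rho", {
  M <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(sparseInverse(diag(4), rho = 0.1)$W, diag(4),
               tolerance = 1e-8)
  Pbig <- sparseInverse(M, rho = 10)
  expect_lt(abs(Pbig$W[1, 2]), 1e-8)
  # indefinite input gets shrunk to the eigenvalue floor first
  Mi <- matrix(c(1, 2, 2, 1), 2)
  P <- sparseInverse(Mi, rho = 0)
  expect_gt(P$lambda, 0)
})

test_that("direct information follows the precision-ratio formula", {
  P <- structure(list(W = matrix(c(4, -2, -2, 4) / 3, 2)),
                 class = "PrecisionMatrix")
  D <- directInformation(P)
  expect_equal(couplingMatrix(D)[1, 2], (-2 / 3) / (16 / 9))
  expect_equal(couplingMatrix(D)[1, 2], -0.375)
  expect_true(all(is.na(diag(couplingMatrix(D)))))

  # identity precision: no coupling
  Pi <- structure(list(W = diag(3)), class = "PrecisionMatrix")
  expect_true(all(couplingMatrix(directInformation(Pi)) == 0,
                  na.rm = TRUE))
  # homogeneity: scaling the precision by k scales D by 1/k
  Pk <- structure(list(W = 3 * matrix(c(4, -2, -2, 4) / 3, 2)),
                  class = "PrecisionMatrix")
  expect_equal(couplingMatrix(directInformation(Pk))[1, 2], -0.375 / 3)
  Pbad <- structure(list(W = diag(c(1, -1))), class = "PrecisionMatrix")
  expect_error(directInformation(Pbad), "positive")
})

test_that("column-mean normalization centres and preserves structure", {
  # constant matrix -> all zeros
  Mc <- matrix(5, 4, 4)
  Dc <- normalizeMatrix(CoevolutionMatrix(Mc))
  expect_true(all(abs(couplingMatrix(Dc)) < 1e-12, na.rm = TRUE))

  # a dominant entry stays the matrix maximum
  M <- matrix(0.1, 5, 5)
  M[2, 4] <- M[4, 2] <- 3
  Dn <- couplingMatrix(normalizeMatrix(CoevolutionMatrix(M)))
  expect_equal(max(Dn, na.rm = TRUE), Dn[2, 4])
  expect_symmetric(Dn)

  # repeated normalization contracts the off-diagonal column means by
  # the exact factor L / (2 (L - 1)) per pass
  set.seed(5)
  L <- 10
  R <- matrix(rnorm(L^2), L); R <- R + t(R)
  D1 <- couplingMatrix(normalizeMatrix(CoevolutionMatrix(R)))
  D2 <- couplingMatrix(normalizeMatrix(CoevolutionMatrix(D1)))
  spread <- function(X) diff(range(colMeans(X, na.rm = TRUE)))
  expect_equal(spread(D2), spread(D1) * L / (2 * (L - 1)),
               tolerance = 1e-9)
})

test_that("3-sigma threshold flags planted couplings only", {
  null <- refNull()
  D <- refMatrix()
  hs <- highScoringThreshold(D, null)
  expect_equal(hs$threshold, null@entryMean + 3 * null@entrySigma)
  expect_false(any(diag(hs$mask)))
  expect_symmetric(hs$mask * 1)
  pairs <- refBundle()$truth$pairs
  hits <- mapply(function(i, j) hs$mask[i, j], pairs$i, pairs$j)
  expect_gte(sum(hits), 6L)
  # a fabricated null far above the data gives an empty mask
  hi <- null
  hi@entryMean <- max(couplingMatrix(D), na.rm = TRUE) + 1
  expect_false(any(highScoringThreshold(D, hi)$mask))
})

test_that("planted covarying pairs rank at the top of the matrix", {
  D <- couplingMatrix(refMatrix())
  pairs <- refBundle()$truth$pairs
  iu <- which(upper.tri(D), arr.ind = TRUE)
  rk <- rank(-D[iu])
  planted <- mapply(function(i, j)
    rk[iu[, 1] == pmin(i, j) & iu[, 2] == pmax(i, j)],
    pairs$i, pairs$j)
  # recovery: planted pairs in the top 2 x (number planted); the two
  # pairs sharing columns dilute each other and are exempt
  expect_gte(sum(planted <= 2L * nrow(pairs)), 6L)
})

test_that("matrix stays symmetric with a masked diagonal end to end", {
  D <- refMatrix()
  M <- couplingMatrix(D)
  expect_symmetric(M)
  expect_true(all(is.na(diag(M))))
  expect_true(all(is.finite(M[upper.tri(M)])))
})

test_that("matrix and edge-list export round-trips", {
  D <- refMatrix()
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeCoevolutionMatrix(D, f, g)
  M2 <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                    row.names = 1, check.names = FALSE))
  expect_equal(unname(M2), unname(couplingMatrix(D)), tolerance = 1e-12)
  edges <- utils::read.table(g, header = TRUE, sep = "\t")
  expect_equal(nrow(edges), choose(matrixSize(D), 2))
  expect_true(all(edges$pos_i < edges$pos_j))
})
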