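# Structure mapping: PDB reading, residue maps, distances, contact
# statistics, accessibility, patches, superposition.

test_that("PDB reading extracts residues, altlocs, chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(f)
  m <- readStructure(f, chain = "A")
  res <- structureResidues(m)
  expect_equal(nrow(res), 3L)
  expect_equal(res$aa, c("A", "G", "S"))
  expect_equal(unname(unlist(res[2L, c("x", "y", "z")])), c(3, 4, 0))

  # altloc resolved to the highest occupancy
  fa <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(fa, altloc = TRUE)
  ma <- readStructure(fa)
  expect_equal(nrow(structureResidues(ma)), 3L)
  expect_equal(structureResidues(ma)$x[1L], 0)

  # residue without a Calpha is excluded with a message
  fm <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(fm, missingCA = TRUE)
  expect_message(mm <- readStructure(fm), "lacking a Calpha")
  expect_equal(nrow(structureResidues(mm)), 2L)

  expect_error(readStructure(f, chain = "Q"), "available chains")
})

test_that("structure mapping verifies residue types", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(f)    # AGS
  aln <- msaFrom("AGS", "AGT", "CGS", ids = c("ref", "s2", "s3"))
  rm1 <- mapStructure(aln, readStructure(f), refId = "ref")
  expect_equal(nrow(rm1$table), 3L)
  expect_equal(rm1$coverage, 1)
  expect_equal(rm1$table$resno, 1:3)

  # deliberate mismatch in the named reference row is a hard error
  alnBad <- msaFrom("ARS", "AGT", "CGS", ids = c("ref", "s2", "s3"))
  expect_error(mapStructure(alnBad, readStructure(f), refId = "ref"),
               "mismatch")
})

test_that("distance matrices are Euclidean and rigid-motion invariant", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPDB(f)
  m <- readStructure(f)
  d <- distanceMatrix(m)
  expect_equal(d[1, 2], 5)          # 3-4-5 triangle
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_symmetric(d)
  # translation invariance
  m2 <- m
  m2@residues$x <- m2@residues$x + 100
  expect_equal(distanceMatrix(m2), d)
})

test_that("contact statistics partition pairs by distance class", {
  set.seed(3)
  L <- 10
  M <- matrix(abs(rnorm(L^2)), L); M <- (M + t(M)) / 2
  D <- CoevolutionMatrix(M)
  dist <- matrix(30, L, L); diag(dist) <- 0
  dist[1, 2] <- dist[2, 1] <- 5      # one contact pair
  dist[3, 4] <- dist[4, 3] <- 12     # exactly at the boundary
  dist[5, 6] <- dist[6, 5] <- 20     # exactly at the long boundary
  cs <- contactStats(D, dist)
  expect_equal(sum(cs$classes$count), choose(L, 2))
  expect_equal(cs$classes$count[cs$classes$class == "contact"], 1L)
  # 12.0 is non-contact, 20.0 is not long-range (strict inequalities)
  expect_equal(cs$classes$count[cs$classes$class == "intermediate"], 2L)
  expect_equal(cs$twoWay$count[cs$twoWay$class == "non-contact"],
               choose(L, 2) - 1L)

  # planted geometry: strong couplings placed in contact
  M2 <- matrix(0.1, L, L)
  M2[1, 2] <- M2[2, 1] <- 5
  cs2 <- contactStats(CoevolutionMatrix(M2), dist)
  cc <- cs2$twoWay
  expect_gt(cc$mean[cc$class == "contact"],
            cc$mean[cc$class == "non-contact"])

  # all pairs in contact: non-contact class empty with zero count
  dist0 <- matrix(5, L, L); diag(dist0) <- 0
  cs3 <- contactStats(D, dist0)
  expect_equal(cs3$twoWay$count[2], 0L)
  expect_true(is.na(cs3$twoWay$mean[2]))
})

test_that("accessibility matches the closed-form isolated sphere", {
  one <- new("StructureModel",
             residues = data.frame(chain = "A", resno = 1L, aa = "G",
                                   x = 0, y = 0, z = 0),
             atoms = data.frame(chain = "A", resno = 1L, elety = "CA",
                                element = "C", x = 0, y = 0, z = 0),
             source = "synthetic")
  a <- solventAccessibility(one, nPoints = 500L)
  expect_equal(a$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # two far-apart atoms: additive; two coincident atoms: occluded
  two <- one
  two@atoms <- rbind(one@atoms,
                     data.frame(chain = "A", resno = 2L, elety = "CA",
                                element = "C", x = 100, y = 0, z = 0))
  two@residues <- rbind(one@residues,
                        data.frame(chain = "A", resno = 2L, aa = "G",
                                   x = 100, y = 0, z = 0))
  a2 <- solventAccessibility(two, nPoints = 500L)
  expect_equal(sum(a2$area), 2 * 4 * pi * 3.1^2, tolerance = 0.01)

  near <- two
  near@atoms$x[2] <- 0.5
  near@residues$x[2] <- 0.5
  a3 <- solventAccessibility(near, nPoints = 500L)
  expect_lt(sum(a3$area), 2 * 4 * pi * 3.1^2 * 0.9)

  # convergence: doubling the sampling changes areas by < 2 percent
  hel <- generateStructure(L = 30L, contacts = data.frame(i = 5L, j = 20L),
                           farPairs = data.frame(i = 1L, j = 30L),
                           foldPoint = 15L)$model
  c1 <- solventAccessibility(hel, nPoints = 960L)$area
  c2 <- solventAccessibility(hel, nPoints = 1920L)$area
  expect_lt(max(abs(c1 - c2) / c2), 0.02)
})

test_that("surface patches require >4 contiguous above-mean columns", {
  L <- 30
  cons <- rep(0.2, L)
  acc <- rep(10, L)
  # both constant: nothing strictly exceeds the mean
  expect_equal(nrow(surfacePatches(cons, acc)), 0L)

  cons[10:15] <- 0.9; acc[10:15] <- 50        # planted 6-run
  p <- surfacePatches(cons, acc)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(10L, 15L))
  expect_equal(p$length, 6L)

  # a 4-run fails, a 5-run passes
  cons2 <- rep(0.2, L); acc2 <- rep(10, L)
  cons2[3:6] <- 0.9; acc2[3:6] <- 50
  expect_equal(nrow(surfacePatches(cons2, acc2)), 0L)
  cons2[3:7] <- 0.9; acc2[3:7] <- 50
  expect_equal(nrow(surfacePatches(cons2, acc2)), 1L)
})

test_that("Kabsch superposition is exact, invariant and oracle-checked", {
  set.seed(77)
  P <- matrix(rnorm(30), 10)
  expect_equal(as.numeric(superposeRmsd(P, P)), 0, tolerance = 1e-10)

  # rigid motion of a copy: RMSD 0
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Q <- P %*% t(Rz) + matrix(rep(c(5, -3, 2), each = 10), 10)
  expect_equal(as.numeric(superposeRmsd(P, Q)), 0, tolerance = 1e-6)

  # symmetric in its arguments, invariant to pre-rotation
  A <- matrix(rnorm(12), 4)
  B <- A + matrix(rnorm(12, sd = 0.3), 4)
  r1 <- as.numeric(superposeRmsd(A, B))
  r2 <- as.numeric(superposeRmsd(B, A))
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(as.numeric(superposeRmsd(A %*% t(Rz), B)), r1,
               tolerance = 1e-9)

  # independent oracle: bio3d's least-squares fit
  xyzA <- as.vector(t(A))
  xyzB <- as.vector(t(B))
  fitted <- bio3d::fit.xyz(fixed = xyzA, mobile = xyzB,
                           fixed.inds = 1:12, mobile.inds = 1:12)
  oracle <- sqrt(mean(colSums(matrix((fitted - xyzA)^2, nrow = 3))))
  expect_equal(r1, oracle, tolerance = 1e-6)

  expect_error(superposeRmsd(A[1:2, ], B[1:2, ]), "3")
})

test_that("edge maps annotate the high-scoring pairs", {
  L <- 8
  M <- matrix(0.1, L, L)
  M[2, 6] <- M[6, 2] <- 4
  M[3, 7] <- M[7, 3] <- 3
  D <- CoevolutionMatrix(M)
  mask <- couplingMatrix(D) > 1
  mask[is.na(mask)] <- FALSE
  dist <- matrix(25, L, L); diag(dist) <- 0
  dist[2, 6] <- dist[6, 2] <- 8
  em <- edgeMap(D, mask, distances = dist)
  expect_equal(nrow(em), sum(mask) / 2)
  expect_equal(em$col_i[1], 2L)
  expect_equal(em$class, c("contact", "long-range"))
  # empty mask: empty list
  expect_equal(nrow(edgeMap(D, mask & FALSE)), 0L)
})
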