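# Centrality, node weights, difference profiles, primary nodes,
# strength/connectivity arithmetic, sub-matrices, autocorrelation.

test_that("eigenvector centrality matches closed forms", {
  e <- eigenCentrality(matrix(c(0, 1, 1, 0), 2))
  expect_equal(e$E, rep(sqrt(0.5), 2), tolerance = 1e-9)
  expect_equal(e$lambda, 1, tolerance = 1e-9)

  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  e3 <- eigenCentrality(path3)
  expect_equal(e3$E, c(0.5, sqrt(0.5), 0.5), tolerance = 1e-8)
  expect_equal(e3$lambda, sqrt(2), tolerance = 1e-8)

  # scaling the matrix scales lambda, not E
  e3k <- eigenCentrality(7 * path3)
  expect_equal(e3k$E, e3$E, tolerance = 1e-8)
  expect_equal(e3k$lambda, 7 * e3$lambda, tolerance = 1e-7)

  expect_warning(ez <- eigenCentrality(matrix(0, 4, 4)), "all-zero")
  expect_equal(ez$E, rep(0.5, 4))
  expect_equal(ez$lambda, 0)
})

test_that("centrality agrees with the dense eigendecomposition oracle", {
  set.seed(31)
  for (r in 1:20) {
    M <- matrix(runif(400), 20)
    M <- M + t(M)
    e <- eigenCentrality(M)
    ed <- eigen(M, symmetric = TRUE)
    v <- abs(ed$vectors[, 1])
    expect_lt(max(abs(e$E - v / sqrt(sum(v^2)))), 1e-8)
    expect_equal(e$lambda, ed$values[1], tolerance = 1e-8)
    expect_equal(sum(e$E^2), 1, tolerance = 1e-12)
    expect_true(all(e$E >= 0))
  }
})

test_that("node weights are sliding-window means", {
  expect_equal(unname(nodeWeights(rep(0.1, 10), 6)), rep(0.1, 5))
  E <- c(0, 0, 0, 6 * 0.2, 0, 0, 0, 0, 0, 0)
  W <- nodeWeights(E, 6)
  expect_equal(unname(W[1:4]), rep(0.2, 4))
  expect_equal(unname(W[5]), 0)
  expect_equal(unname(nodeWeights(E, 1)), E)
  expect_error(nodeWeights(E, 11), "window")
})

test_that("difference profile is scaled and zero-mean", {
  null <- refNull()
  ER <- null@ER
  # proportional profiles cancel exactly
  p <- differenceProfile(2 * ER, null)
  expect_equal(p$scale, 2)
  expect_true(all(abs(p$deltaW) < 1e-12))
  # a spike shows up positive at its position, mean stays 0
  spike <- ER
  spike[50] <- spike[50] + 0.3
  p2 <- differenceProfile(spike, null)
  expect_gt(p2$deltaW[50], 0)
  expect_lt(abs(mean(p2$deltaW)), 1e-9)
  # length mismatch
  expect_error(differenceProfile(ER[-1], null), "length")
})

test_that("difference profile of the real matrix is zero-mean", {
  prof <- differenceProfile(eigenCentrality(refMatrix()), refNull())
  expect_lt(abs(mean(prof$deltaW)), 1e-9)
})

test_that("primary nodes recover the planted segments", {
  D <- refMatrix()
  null <- refNull()
  prof <- differenceProfile(eigenCentrality(D), null)
  nodes <- detectPrimaryNodes(prof, null)
  segs <- refBundle()$truth$nodeSegments
  expect_gte(nrow(nodes), nrow(segs))
  for (s in seq_len(nrow(segs))) {
    hit <- any(nodes$peak >= segs$start[s] - 2L &
                 nodes$peak <= segs$end[s] + 2L)
    expect_true(hit, label = paste("segment", s, "recovered"))
  }
  # a flat profile yields no nodes
  flat <- prof
  flat$deltaW <- rep(0, length(flat$deltaW))
  expect_equal(nrow(detectPrimaryNodes(flat, null)), 0L)
})

test_that("two well-separated planted segments give two nodes", {
  null <- refNull()
  prof <- differenceProfile(eigenCentrality(refMatrix()), null)
  nodes <- detectPrimaryNodes(prof, null)
  # the reference layout plants segments at 30-35 and 80-85, far apart
  expect_gte(nrow(nodes), 2L)
  expect_gt(diff(range(nodes$peak)), 6L)
})

test_that("metric arithmetic reproduces the published network rows", {
  agg <- referenceAggregates()
  for (grp in unique(agg$matrix)) {
    rows <- agg[agg$matrix == grp, ]
    rand <- rows[rows$label == "randomized", ]
    ref <- metricsFromAggregates(rand$sum_pos, rand$n_corr, rand$n_pos,
                                 rand$n_matrix, label = "randomized")
    expect_equal(ref$C, 1)
    expect_equal(ref$S_M, 1)
    for (r in which(rows$label != "randomized")) {
      m <- metricsFromAggregates(rows$sum_pos[r], rows$n_corr[r],
                                 rows$n_pos[r], rows$n_matrix[r],
                                 nullRef = ref, label = rows$label[r])
      # agreement to one unit in the last printed digit
      expect_lt(abs(m$C - rows$C[r]),
                1.05 * 10^-rows$C_digits[r] + 1e-9,
                label = paste(grp, rows$label[r], "C"))
      if (!rows$mutation_network[r])
        expect_lt(abs(m$S_M - rows$S_M[r]),
                  1.05 * 10^-rows$S_M_digits[r] + 1e-9,
                  label = paste(grp, rows$label[r], "S_M"))
    }
  }
})

test_that("published spot values come out at 2 decimal places", {
  ref2 <- metricsFromAggregates(17621.4, 116900, 53348, 152100)
  m <- metricsFromAggregates(9776.6, 24142, 16538, 33124, nullRef = ref2)
  expect_equal(round(m$S_M, 2), 1.79)
  expect_equal(round(m$C, 2), 0.95)
  ref3 <- metricsFromAggregates(11423.3, 76887, 34532, 103041)
  m3 <- metricsFromAggregates(832.5, 2300, 1466, 3969, nullRef = ref3)
  expect_equal(round(m3$S_M, 2), 1.72)
  expect_equal(round(m3$C, 2), 0.78)
})

test_that("selection counting follows the symmetric convention", {
  M <- matrix(1, 6, 6)
  D <- CoevolutionMatrix(M)
  m <- networkMetrics(D, 1:6, 1:6)
  expect_equal(m$n_matrix, 36)          # dim1 * dim2
  expect_equal(m$n_corr, 30)            # diagonal masked
  expect_equal(m$n_pos, 30)
  expect_equal(m$sum_pos, 30)
  # an off-diagonal block has no masked entries
  mi <- networkMetrics(D, 1:2, 4:6)
  expect_equal(mi$n_matrix, 6)
  expect_equal(mi$n_corr, 6)
  expect_error(networkMetrics(D, 5:9, 5:9), "bounds")
})

test_that("sub-matrix blocks keep labels and block centrality", {
  D <- refMatrix()
  full <- subMatrix(D, seq_len(matrixSize(D)))
  expect_equal(couplingMatrix(full), unname(couplingMatrix(D)),
               ignore_attr = TRUE)
  blk <- subMatrix(D, 1:4, 5:10)
  expect_equal(dim(blk), c(4L, 6L))
  expect_equal(as.integer(rownames(blk)), 1:4)

  # block centrality of an isolated domain equals its stand-alone
  # centrality when there is no inter-block signal
  set.seed(8)
  A <- matrix(runif(100, 0, 1), 10); A <- A + t(A)
  B <- matrix(runif(64, 0, 1), 8); B <- B + t(B)
  comp <- matrix(0, 18, 18)
  comp[1:10, 1:10] <- A
  comp[11:18, 11:18] <- B
  eBlock <- eigenCentrality(subMatrix(CoevolutionMatrix(comp), 1:10))
  eAlone <- eigenCentrality(CoevolutionMatrix(A))
  expect_gt(cor(eBlock$E, eAlone$E, method = "spearman"), 0.999)
})

test_that("intra-domain strength exceeds inter when planted so", {
  # two-domain toy matrix: strong intra blocks, weak inter block
  set.seed(12)
  L <- 40
  M <- matrix(abs(rnorm(L^2, 0.1, 0.02)), L); M <- (M + t(M)) / 2
  M[1:20, 1:20] <- M[1:20, 1:20] + 0.5
  M[21:40, 21:40] <- M[21:40, 21:40] + 0.5
  D <- CoevolutionMatrix(M)
  ref <- networkMetrics(D)
  intra <- networkMetrics(D, 1:20, 1:20, nullRef = ref)
  inter <- networkMetrics(D, 1:20, 21:40, nullRef = ref)
  expect_gt(intra$S_M, inter$S_M)
})

test_that("three-node networks count ordered inter-node pairs", {
  M <- matrix(1, 30, 30)
  D <- CoevolutionMatrix(M)
  nodes <- data.frame(node = 1:3, start = c(1L, 11L, 21L),
                      end = c(6L, 16L, 26L), peak = c(3L, 13L, 23L),
                      W = c(3, 2, 1))
  m <- threeNodeNetwork(D, nodes)
  expect_equal(m$n_matrix, 2L * 3L * 36L)   # 2 sum_{a<b} |a||b| = 216
  expect_equal(m$n_corr, 216L)              # no diagonal in inter blocks
  expect_error(threeNodeNetwork(D, nodes[1:2, ]), "3")

  # published 3-node spot value from the aggregate row
  ref3 <- metricsFromAggregates(11423.3, 76887, 34532, 103041)
  m3 <- metricsFromAggregates(102.3, 264, 148, 432, nullRef = ref3)
  expect_equal(round(m3$S_M, 2), 2.09)
})

test_that("autocorrelation finds periodic repeats and handles noise", {
  x <- sin(2 * pi * (1:84) / 7)
  G <- centralityAutocorrelation(x, maxLag = 20)
  expect_true(all(c(7L, 14L) %in% attr(G, "peaks")))
  expect_gt(G[7], 0.8)

  set.seed(2)
  ok <- 0
  for (r in 1:5) {
    w <- rnorm(300)
    Gw <- centralityAutocorrelation(w, maxLag = 10)
    ok <- ok + all(abs(Gw) < 3 / sqrt(300))
  }
  expect_gte(ok, 4)   # white noise stays inside the 3/sqrt(L) band

  expect_warning(Gc <- centralityAutocorrelation(rep(1, 30)), "constant")
  expect_true(all(Gc == 0))
})
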