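# Coevolution matrix estimation: weighted pair frequencies, (normalized)
# mutual information, average-product correction, sparse inverse
# covariance (graphical lasso), direct information, column-mean
# normalization, and the 3-sigma high-scoring threshold.

.encodeMSA <- function(aln) {
  m <- msaMatrix(aln)
  matrix(match(m, .ALPHABET), nrow = nrow(m))
}

# one-hot sparse indicator: N x (NSYM * L)
.oneHot <- function(code) {
  N <- nrow(code); L <- ncol(code)
  Matrix::sparseMatrix(
    i = rep(seq_len(N), L),
    j = as.vector((col(code) - 1L) * .NSYM + code),
    x = 1, dims = c(N, .NSYM * L))
}

#' Weighted joint and marginal symbol frequencies of column pairs
#'
#' Counts every symbol pair over all column pairs, optionally downweighting
#' redundant sequences: with \code{weighting = "identity_cluster"} each
#' sequence has weight 1 / (number of sequences, itself included, within
#' fractional identity >= \code{theta} of it), the usual redundancy
#' correction of covariance estimators.  A uniform pseudocount (default 1
#' per cell of each pair table, i.e. per symbol pair) is applied when the
#' tables are normalized; this PSICOV-style smoothing also damps the
#' finite-sample mutual-information noise of high-entropy column pairs.
#'
#' @param aln a \code{ProteinMSA}.
#' @param weighting \code{"identity_cluster"} (default) or \code{"none"}.
#' @param theta identity threshold of the clustering weighting.
#' @param pseudocount pseudocount added to every cell of every
#'   joint table (1 = one count per symbol pair).
#' @return object of class \code{PairFrequencies}: list with the weighted
#'   count matrix \code{counts} ((22 L) x (22 L)), \code{weights},
#'   effective depth \code{neff}, \code{L} and \code{pseudocount}.
#' @export
pairFrequencies <- function(aln, weighting = c("identity_cluster", "none"),
                            theta = 0.62, pseudocount = 1) {
  weighting <- match.arg(weighting)
  stopifnot(msaDepth(aln) >= 2L)
  code <- .encodeMSA(aln)
  N <- nrow(code); L <- ncol(code)
  X <- .oneHot(code)

  if (weighting == "identity_cluster") {
    idmat <- as.matrix(Matrix::tcrossprod(X)) / L   # fraction identity
    w <- 1 / rowSums(idmat >= theta)
  } else {
    w <- rep(1, N)
  }
  counts <- as.matrix(Matrix::crossprod(X, X * w))

  structure(list(counts = counts, weights = w, neff = sum(w),
                 L = L, pseudocount = pseudocount),
            class = "PairFrequencies")
}

#' @export
print.PairFrequencies <- function(x, ...) {
  cat("PairFrequencies: L =", x$L, ", effective depth =",
      format(x$neff, digits = 5), "\n")
  invisible(x)
}

#' Joint frequency table of one column pair
#'
#' @param pf a \code{PairFrequencies} object.
#' @param i,j column indices.
#' @param pseudocount override the stored pseudocount.
#' @return 22 x 22 matrix of joint frequencies summing to 1.
#' @export
jointTable <- function(pf, i, j, pseudocount = pf$pseudocount) {
  ri <- (i - 1L) * .NSYM + seq_len(.NSYM)
  rj <- (j - 1L) * .NSYM + seq_len(.NSYM)
  cnt <- pf$counts[ri, rj] + pseudocount
  dimnames(cnt) <- list(.ALPHABET, .ALPHABET)
  cnt / sum(cnt)
}

#' Mutual information matrix of all column pairs
#'
#' MI_ij = S_i + S_j - S_ij from the (pseudocounted, weighted) pair
#' frequencies; with \code{normalized = TRUE} the joint-entropy
#' normalization nMI_ij = MI_ij / S_ij is applied (0 where S_ij = 0).
#' The diagonal is set to the marginal entropy S_i (self-information),
#' which makes the matrix usable as a covariance-like input to the sparse
#' inverse step.
#'
#' @param pf a \code{PairFrequencies} object.
#' @param normalized apply the joint-entropy normalization (default TRUE).
#' @return L x L symmetric numeric matrix.
#' @export
miMatrix <- function(pf, normalized = TRUE) {
  L <- pf$L
  pc <- pf$pseudocount                    # per joint cell
  tot <- pf$neff + pc * .NSYM^2
  P <- (pf$counts + pc) / tot
  PlogP <- P * log2(P)
  PlogP[P == 0] <- 0

  G <- Matrix::sparseMatrix(i = seq_len(.NSYM * L),
                            j = rep(seq_len(L), each = .NSYM), x = 1)
  Sjoint <- -as.matrix(Matrix::crossprod(G, PlogP %*% G))

  # marginals consistent with the joints: row sums of any pair block
  margCounts <- vapply(seq_len(L), function(i) {
    ri <- (i - 1L) * .NSYM + seq_len(.NSYM)
    diag(pf$counts[ri, ri, drop = FALSE]) + pf$pseudocount * .NSYM
  }, numeric(.NSYM))
  pM <- margCounts / rep(colSums(margCounts), each = .NSYM)
  Si <- -colSums(ifelse(pM > 0, pM * log2(pM), 0))

  MI <- outer(Si, Si, `+`) - Sjoint
  if (normalized) {
    MI <- ifelse(Sjoint > 0, MI / Sjoint, 0)
  }
  diag(MI) <- Si
  (MI + t(MI)) / 2
}

#' Average-product correction
#'
#' Removes the background column-wise coupling bias:
#' corrected_ij = M_ij - mean_i(M) mean_j(M) / mean(M), with all means
#' taken over off-diagonal entries.  The diagonal is left untouched.
#'
#' @param M square symmetric numeric matrix.
#' @return corrected matrix of the same shape.
#' @export
apcCorrect <- function(M) {
  stopifnot(nrow(M) == ncol(M))
  L <- nrow(M)
  if (L < 2L) return(M)
  off <- M
  diag(off) <- NA_real_
  mi <- rowMeans(off, na.rm = TRUE)
  g <- mean(off[!is.na(off)])
  if (!is.finite(g) || g == 0) {
    warning("grand off-diagonal mean is zero; APC skipped")
    return(M)
  }
  corr <- M - outer(mi, mi) / g
  diag(corr) <- diag(M)
  corr
}

#' Sparse inverse covariance (graphical lasso)
#'
#' Estimates an L1-penalized precision matrix of a symmetric input.  The
#' input is first made positive definite by the smallest diagonal
#' shrinkage toward the identity, (1 - lambda) M + lambda I, that lifts
#' the minimum eigenvalue to \code{eigenFloor}.  At \code{rho = 0} the
#' estimate equals the plain inverse of the shrunk matrix.
#'
#' @param M symmetric numeric matrix.
#' @param rho L1 penalty weight (default 1e-3).
#' @param eigenFloor minimum eigenvalue enforced by shrinkage.
#' @param maxit,tol outer-loop control of the coordinate descent.
#' @return object of class \code{PrecisionMatrix}: list with \code{W}
#'   (the precision matrix), \code{sigma} (the fitted covariance),
#'   \code{rho} and \code{lambda} (the shrinkage used).
#' @export
sparseInverse <- function(M, rho = 1e-3, eigenFloor = 1e-3,
                          maxit = 200L, tol = 1e-9) {
  stopifnot(nrow(M) == ncol(M))
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  emin <- min(ev)
  lambda <- 0
  if (emin < eigenFloor) {
    lambda <- (eigenFloor - emin) / (1 - emin)
    lambda <- min(max(lambda, 0), 1)
    M <- (1 - lambda) * M + lambda * diag(nrow(M))
  }
  fit <- .glasso_cpp(M, rho, maxit = maxit, tol = tol)
  if (!fit$converged)
    stop("graphical lasso did not converge; increase rho or eigenFloor")
  W <- (fit$theta + t(fit$theta)) / 2
  if (any(diag(W) <= 0))
    stop("graphical lasso produced a nonpositive diagonal; ",
         "increase rho or eigenFloor")
  structure(list(W = W, sigma = fit$w, rho = rho, lambda = lambda),
            class = "PrecisionMatrix")
}

#' @export
print.PrecisionMatrix <- function(x, ...) {
  cat("PrecisionMatrix:", nrow(x$W), "x", nrow(x$W),
      sprintf("(rho = %g, shrinkage lambda = %.4g)\n", x$rho, x$lambda))
  invisible(x)
}

#' Direct information from a precision matrix
#'
#' D_ij = W_ij / (W_ii W_jj) for i != j; the diagonal is masked.  This is
#' the coupling score that suppresses indirect (transitive) correlations.
#'
#' @param P a \code{PrecisionMatrix} (or plain matrix with strictly
#'   positive diagonal).
#' @param provenance optional provenance list stored on the result.
#' @return a \code{\linkS4class{CoevolutionMatrix}} (pre-normalization).
#' @export
directInformation <- function(P, provenance = list()) {
  W <- if (inherits(P, "PrecisionMatrix")) P$W else P
  d <- diag(W)
  if (any(d <= 0)) stop("precision diagonal must be strictly positive")
  D <- W / outer(d, d)
  CoevolutionMatrix(D, provenance = provenance)
}

#' Column-mean normalization of a coupling matrix
#'
#' D'_ij = D_ij - (mean_i + mean_j) / 2, where mean_i is the mean of
#' column i over off-diagonal entries.  Symmetry is preserved, and the
#' operation centres the distribution of couplings per position.
#'
#' @param D a \code{CoevolutionMatrix}.
#' @return normalized \code{CoevolutionMatrix}.
#' @export
normalizeMatrix <- function(D) {
  M <- couplingMatrix(D)
  m <- colMeans(M, na.rm = TRUE)     # diagonal NA excluded automatically
  M2 <- M - (outer(m, rep(1, length(m))) + outer(rep(1, length(m)), m)) / 2
  CoevolutionMatrix(M2, provenance = c(D@provenance,
                                       list(normalized = TRUE)))
}

#' High-scoring edge threshold from a null library
#'
#' Significant ("high-scoring") couplings exceed the null distribution
#' mean by 3 sigma, with mean and sigma pooled over all off-diagonal
#' entries of the column-shuffled library (a per-position variant is
#' available via \code{perPosition}).
#'
#' @param D a \code{CoevolutionMatrix}.
#' @param null a \code{\linkS4class{NullLibrary}} built from an alignment
#'   of the same shape.
#' @param nSigma threshold multiplier (default 3).
#' @param perPosition use per-position null central values instead of the
#'   pooled ones (default FALSE; requires stored member matrices).
#' @return list with \code{threshold} and logical \code{mask} (L x L,
#'   TRUE where D exceeds the threshold; diagonal FALSE).
#' @export
highScoringThreshold <- function(D, null, nSigma = 3, perPosition = FALSE) {
  stopifnot(is(null, "NullLibrary"))
  M <- couplingMatrix(D)
  if (perPosition) {
    if (!length(null@matrices))
      stop("per-position thresholds need a library built with ",
           "keepMatrices = TRUE")
    arr <- simplify2array(lapply(null@matrices, couplingMatrix))
    thr <- apply(arr, c(1, 2), mean, na.rm = TRUE) +
      nSigma * apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  } else {
    thr <- null@entryMean + nSigma * null@entrySigma
  }
  mask <- !is.na(M) & (M > thr)
  diag(mask) <- FALSE
  list(threshold = thr, mask = mask)
}

#' Full coevolution-matrix pipeline on one alignment
#'
#' Runs pair frequencies -> normalized mutual information -> average
#' product correction -> diagonal shrinkage + graphical lasso -> direct
#' information -> column-mean normalization, the estimation chain applied
#' to every real and shuffled alignment in this package.
#'
#' @param aln a \code{ProteinMSA}.
#' @param weighting,theta,pseudocount see \code{\link{pairFrequencies}}.
#' @param normalizedMI use the joint-entropy normalization nMI =
#'   MI/S_ij instead of plain MI (default FALSE: on alignments with a
#'   steep conservation gradient the normalization inflates the variance
#'   of noise couplings between conserved columns and inverts the
#'   entropy-centrality covariation of the null background; see the
#'   methods vignette).
#' @param apc apply the average-product correction (default TRUE).
#' @param rho,eigenFloor see \code{\link{sparseInverse}}.
#' @param flipSign orient the score so that positively coevolving pairs
#'   get positive values (default TRUE).  The precision-matrix ratio
#'   W_ij/(W_ii W_jj) is a sign-flipped partial correlation: a pair of
#'   positively covarying columns produces a negative off-diagonal in
#'   the inverse, so the raw ratio is negated to make coevolved pairs
#'   score high, the orientation in which positive correlations measure
#'   coevolution and the 3-sigma rule selects the upper tail.
#' @param normalize apply the final column-mean normalization
#'   (default TRUE).
#' @return a \code{\linkS4class{CoevolutionMatrix}}.
#' @export
coevolutionMatrix <- function(aln, weighting = "identity_cluster",
                              theta = 0.62, pseudocount = 1,
                              normalizedMI = FALSE, apc = TRUE,
                              rho = 1e-3, eigenFloor = 1e-3,
                              flipSign = TRUE, normalize = TRUE) {
  pf <- pairFrequencies(aln, weighting = weighting, theta = theta,
                        pseudocount = pseudocount)
  M <- miMatrix(pf, normalized = normalizedMI)
  if (apc) M <- apcCorrect(M)
  P <- sparseInverse(M, rho = rho, eigenFloor = eigenFloor)
  D <- directInformation(P, provenance = list(
    weighting = weighting, theta = theta, pseudocount = pseudocount,
    normalizedMI = normalizedMI, apc = apc, rho = rho,
    eigenFloor = eigenFloor, flipSign = flipSign,
    N = msaDepth(aln), L = msaLength(aln)))
  if (flipSign) D <- CoevolutionMatrix(-couplingMatrix(D),
                                       provenance = D@provenance)
  if (normalize) D <- normalizeMatrix(D)
  D
}

#' Write a coupling matrix as dense TSV and as an edge list
#'
#' @param D a \code{CoevolutionMatrix}.
#' @param path output TSV for the dense matrix (1-based header
#'   row/column); \code{edgePath} optional edge-list TSV
#'   (pos_i, pos_j, D_ij for i < j).
#' @param edgePath optional edge-list output path.
#' @return \code{path}, invisibly.
#' @export
writeCoevolutionMatrix <- function(D, path, edgePath = NULL) {
  M <- couplingMatrix(D)
  L <- ncol(M)
  dimnames(M) <- list(seq_len(L), seq_len(L))
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(edgePath)) {
    iu <- which(upper.tri(M), arr.ind = TRUE)
    edges <- data.frame(pos_i = iu[, 1L], pos_j = iu[, 2L],
                        D = M[iu])
    utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
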