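# Column-shuffled randomized MSA library: the calibration null.  Shuffling
# each column independently preserves the per-column symbol multisets
# (hence the entropy profile) while destroying every inter-column
# correlation, so whatever structure survives in matrices computed from
# shuffled alignments is the residual background that all thresholds and
# normalizations must discount.

#' Shuffle the symbols of every alignment column independently
#'
#' @param aln a \code{ProteinMSA}.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return a \code{ProteinMSA} with identical per-column symbol counts.
#' @export
shuffleColumns <- function(aln, seed) {
  m <- msaMatrix(aln)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(nrow(m)), j]
  ProteinMSA(m)
}

#' Build the column-shuffled null library
#'
#' Generates K column-shuffled copies of the alignment (member m uses
#' \code{seed + m}), runs the full coevolution pipeline on each, and
#' summarizes: pooled off-diagonal entry mean and sigma, the per-position
#' centrality mean E_R and sigma, the member centrality profiles, and the
#' pooled full-matrix aggregates that serve as the randomized reference
#' row for strength/connectivity normalization.
#'
#' @param aln a \code{ProteinMSA}.
#' @param K library size (default 100; scaled-down values with wider
#'   tolerances are used in tests).
#' @param seed master seed.
#' @param keepMatrices retain the K member matrices (default FALSE;
#'   only summaries are consumed downstream).
#' @param ... estimator settings forwarded to
#'   \code{\link{coevolutionMatrix}}.
#' @return a \code{\linkS4class{NullLibrary}}.
#' @export
buildNullLibrary <- function(aln, K = 100L, seed = 1L,
                             keepMatrices = FALSE, ...) {
  K <- as.integer(K)
  stopifnot(K >= 2L)
  L <- msaLength(aln)
  settings <- list(...)

  ssum <- 0; ssq <- 0; n <- 0
  agg <- c(sum_pos = 0, n_pos = 0, n_corr = 0, n_matrix = 0)
  Emat <- matrix(NA_real_, K, L)
  mats <- if (keepMatrices) vector("list", K) else list()

  for (k in seq_len(K)) {
    memberSeed <- as.integer(seed) + k
    D <- tryCatch(
      .memberMatrix(aln, memberSeed, settings),
      error = function(e) {
        # one redraw with an offset seed, then hard failure
        tryCatch(.memberMatrix(aln, memberSeed + K + 1000L, settings),
                 error = function(e2)
                   stop("null library member ", k, " failed twice: ",
                        conditionMessage(e2)))
      })
    M <- couplingMatrix(D)
    off <- M[!is.na(M)]
    ssum <- ssum + sum(off)
    ssq <- ssq + sum(off^2)
    n <- n + length(off)
    agg <- agg + c(sum(off[off > 0]), sum(off > 0), length(off), L * L)
    Emat[k, ] <- eigenCentrality(D)$E
    if (keepMatrices) mats[[k]] <- D
  }

  mu <- ssum / n
  sigma <- sqrt(max(ssq / n - mu^2, 0) * n / (n - 1))
  new("NullLibrary", K = K, seed = as.integer(seed),
      entryMean = mu, entrySigma = sigma,
      ER = colMeans(Emat), sigmaE = apply(Emat, 2L, stats::sd),
      Emat = Emat,
      aggregates = as.list(agg),
      settings = settings, matrices = mats)
}

.memberMatrix <- function(aln, seed, settings) {
  shuffled <- shuffleColumns(aln, seed)
  do.call(coevolutionMatrix, c(list(aln = shuffled), settings))
}

#' Randomized reference row of a null library
#'
#' The pooled full-matrix aggregates of the library in the form consumed
#' by \code{\link{networkMetrics}}: the randomized row against which
#' strength S_M and connectivity C are normalized.
#'
#' @param null a \code{\linkS4class{NullLibrary}}.
#' @return a \code{NetworkMetrics} row (see
#'   \code{\link{metricsFromAggregates}}) with C = S_M = 1.
#' @export
nullReference <- function(null) {
  stopifnot(is(null, "NullLibrary"))
  a <- null@aggregates
  metricsFromAggregates(sum_pos = a$sum_pos, n_corr = a$n_corr,
                        n_pos = a$n_pos, n_matrix = a$n_matrix,
                        label = "randomized")
}

#' Serialize a null library summary to JSON
#' @param null a \code{\linkS4class{NullLibrary}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeNullLibrary <- function(null, path) {
  jsonlite::write_json(
    list(K = null@K, seed = null@seed,
         entry_mean = null@entryMean, entry_sigma = null@entrySigma,
         E_R = null@ER, sigma_E = null@sigmaE,
         aggregates = null@aggregates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
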