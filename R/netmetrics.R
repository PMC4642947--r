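# Network view of the coevolution matrix: eigenvector centrality,
# windowed node weights, null-corrected difference profiles, primary
# nodes, strength/connectivity metrics of (sub)networks, block
# extraction, autocorrelation, and 3-node networks.

#' Eigenvector centrality of a coupling matrix
#'
#' The principal eigenvector E of the non-negative matrix (negative
#' entries and the masked diagonal are clipped to zero for this
#' computation only; the unclipped matrix is retained for all sums and
#' thresholds elsewhere).  Computed by power iteration; E is oriented
#' non-negative and has unit L2 norm, and lambda is the leading
#' eigenvalue.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}} or plain symmetric
#'   matrix.
#' @param tol,maxit power-iteration control.
#' @return list of class \code{CentralityProfile}: \code{E} (length L,
#'   unit norm, non-negative) and \code{lambda}.
#' @export
eigenCentrality <- function(D, tol = 1e-12, maxit = 100000L) {
  M <- if (is(D, "CoevolutionMatrix")) couplingMatrix(D) else D
  stopifnot(nrow(M) == ncol(M))
  M[is.na(M) | M < 0] <- 0
  L <- ncol(M)
  if (all(M == 0)) {
    warning("all-zero matrix: returning a uniform centrality profile")
    return(structure(list(E = rep(1 / sqrt(L), L), lambda = 0),
                     class = "CentralityProfile"))
  }
  # diagonal shift makes the Perron eigenvalue strictly dominant (guards
  # against bipartite-like spectra where |lambda_min| = lambda_max)
  shift <- max(rowSums(M))
  v <- rep(1 / sqrt(L), L)
  for (it in seq_len(maxit)) {
    w <- as.vector(M %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v <- abs(v)           # Perron vector: non-negative orientation
  v <- v / sqrt(sum(v^2))
  lambda <- sum(v * as.vector(M %*% v))
  structure(list(E = v, lambda = lambda), class = "CentralityProfile")
}

#' @export
print.CentralityProfile <- function(x, ...) {
  cat("CentralityProfile: L =", length(x$E),
      sprintf(", lambda = %.6g\n", x$lambda))
  invisible(x)
}

#' Sliding-window node weights
#'
#' W_k = mean centrality over the n contiguous positions starting at k
#' (stride 1); windows running past the terminus are excluded.
#'
#' @param E a \code{CentralityProfile} or numeric vector.
#' @param n window length (default 6 residues).
#' @return numeric vector of length L - n + 1, named by window start.
#' @export
nodeWeights <- function(E, n = 6L) {
  x <- if (inherits(E, "CentralityProfile")) E$E else E
  n <- as.integer(n)
  L <- length(x)
  if (n < 1L || n > L) stop("window length n must be in [1, L]")
  cs <- cumsum(c(0, x))
  W <- (cs[(n + 1L):(L + 1L)] - cs[seq_len(L - n + 1L)]) / n
  names(W) <- seq_len(L - n + 1L)
  W
}

#' Difference centrality profile against the null library
#'
#' deltaW_i = E_i - (M_E / M_R) E_R,i, where M_E / M_R is the ratio of
#' the real to randomized-library centrality means.  The scaling makes
#' the difference profile zero-mean by construction.
#'
#' @param E a \code{CentralityProfile} (or numeric vector).
#' @param null a \code{\linkS4class{NullLibrary}} of matching length.
#' @return list of class \code{NodeWeightProfile}: \code{deltaW},
#'   \code{scale}, \code{E}, \code{ER}.
#' @export
differenceProfile <- function(E, null) {
  x <- if (inherits(E, "CentralityProfile")) E$E else E
  stopifnot(is(null, "NullLibrary"))
  ER <- null@ER
  if (length(x) != length(ER))
    stop("centrality and null profiles differ in length")
  if (mean(ER) == 0) stop("null centrality mean is zero")
  scale <- mean(x) / mean(ER)
  structure(list(deltaW = x - scale * ER, scale = scale,
                 E = x, ER = ER),
            class = "NodeWeightProfile")
}

#' @export
print.NodeWeightProfile <- function(x, ...) {
  cat("NodeWeightProfile: L =", length(x$deltaW),
      sprintf(", scale M_E/M_R = %.4g\n", x$scale))
  invisible(x)
}

# pooled null window-weight distribution for a given window length:
# each library member is corrected against the library mean profile the
# same way as the real profile, then windowed.
.nullWindowStats <- function(null, n) {
  ER <- null@ER
  vals <- unlist(lapply(seq_len(null@K), function(k) {
    e <- null@Emat[k, ]
    d <- e - (mean(e) / mean(ER)) * ER
    nodeWeights(d, n)
  }))
  c(mean = mean(vals), sd = stats::sd(vals))
}

#' Detect primary nodes in a difference profile
#'
#' Primary nodes are windows of n contiguous residues whose mean
#' difference weight exceeds the null window-weight distribution mean by
#' \code{nSigma} sigma (both calibrated from the shuffled library).
#' Overlapping qualifying windows are merged into runs; each run is
#' reported as one node with its peak-mode position (the residue of
#' maximal deltaW inside the run).
#'
#' @param prof a \code{NodeWeightProfile} from
#'   \code{\link{differenceProfile}}.
#' @param null the \code{\linkS4class{NullLibrary}}.
#' @param n window length (default 6).
#' @param nSigma threshold multiplier (default 2).
#' @param center use the \code{"null"} window-weight mean (default) or
#'   the \code{"real"} one as the distribution centre.
#' @return data.frame (node, start, end, peak, W) -- one row per merged
#'   node, W the maximal window weight of the run; zero rows if nothing
#'   qualifies.
#' @export
detectPrimaryNodes <- function(prof, null, n = 6L, nSigma = 2,
                               center = c("null", "real")) {
  center <- match.arg(center)
  stopifnot(inherits(prof, "NodeWeightProfile"))
  W <- nodeWeights(prof$deltaW, n)
  ns <- .nullWindowStats(null, n)
  mu <- if (center == "null") ns[["mean"]] else mean(W)
  thr <- mu + nSigma * ns[["sd"]]
  hits <- which(W > thr)
  if (!length(hits))
    return(data.frame(node = integer(), start = integer(),
                      end = integer(), peak = integer(), W = numeric()))
  # merge windows whose intervals [k, k+n-1] overlap
  starts <- hits
  ends <- hits + n - 1L
  breaks <- c(0L, which(starts[-1L] > ends[-length(ends)] + 0L), length(hits))
  out <- lapply(seq_len(length(breaks) - 1L), function(b) {
    idx <- (breaks[b] + 1L):breaks[b + 1L]
    s <- starts[idx[1L]]
    e <- ends[idx[length(idx)]]
    seg <- prof$deltaW[s:e]
    data.frame(start = s, end = e,
               peak = s + which.max(seg) - 1L,
               W = max(W[hits[idx]]))
  })
  res <- do.call(rbind, out)
  res <- cbind(node = seq_len(nrow(res)), res)
  attr(res, "threshold") <- thr
  res
}

#' Network metrics object from raw aggregates
#'
#' Builds the (sum of positive correlations, element counts) row used by
#' the strength and connectivity calculations, optionally normalizing
#' against a randomized reference row:
#' S_M = (sum_pos / n_pos) / (sum_pos_rand / n_pos_rand) and
#' C = (n_corr / n_matrix) / (n_corr_rand / n_matrix_rand).
#'
#' @param sum_pos sum of all positive correlation values.
#' @param n_corr number of elements carrying correlation values.
#' @param n_pos number of elements with positive values.
#' @param n_matrix total number of elements (dim1 * dim2).
#' @param nullRef optional randomized reference row (another
#'   \code{NetworkMetrics}); when given, C and S_M are filled in.
#' @param label network label.
#' @return object of class \code{NetworkMetrics} (a one-row list with
#'   fields sum_pos, n_corr, n_pos, n_matrix, density, strength_raw,
#'   C, S_M, label).
#' @export
metricsFromAggregates <- function(sum_pos, n_corr, n_pos, n_matrix,
                                  nullRef = NULL, label = "") {
  stopifnot(n_pos <= n_corr, n_corr <= n_matrix)
  density <- n_corr / n_matrix
  strength_raw <- if (n_pos > 0) sum_pos / n_pos else 0
  C <- S_M <- NA_real_
  if (!is.null(nullRef)) {
    stopifnot(inherits(nullRef, "NetworkMetrics"))
    C <- density / nullRef$density
    if (n_pos == 0) {
      warning("selection has no positive correlations; S_M = 0")
      S_M <- 0
    } else {
      S_M <- strength_raw / nullRef$strength_raw
    }
  } else {
    C <- 1; S_M <- 1   # a reference row is its own normalization
  }
  structure(list(label = label, sum_pos = sum_pos, n_corr = n_corr,
                 n_pos = n_pos, n_matrix = n_matrix, density = density,
                 strength_raw = strength_raw, C = C, S_M = S_M),
            class = "NetworkMetrics")
}

#' @export
print.NetworkMetrics <- function(x, ...) {
  cat(sprintf(
    "NetworkMetrics [%s]: sum_pos = %.4g, n_corr = %d, n_pos = %d, n_matrix = %d\n",
    x$label, x$sum_pos, as.integer(x$n_corr), as.integer(x$n_pos),
    as.integer(x$n_matrix)))
  cat(sprintf("  density = %.4g, strength = %.4g, C = %.4g, S_M = %.4g\n",
              x$density, x$strength_raw, x$C, x$S_M))
  invisible(x)
}

#' @export
as.data.frame.NetworkMetrics <- function(x, ...) {
  data.frame(label = x$label, sum_pos = x$sum_pos, n_corr = x$n_corr,
             n_pos = x$n_pos, n_matrix = x$n_matrix, density = x$density,
             strength_raw = x$strength_raw, C = x$C, S_M = x$S_M)
}

#' Strength and connectivity of a matrix selection
#'
#' Aggregates the selected block of the coupling matrix.  For a symmetric
#' selection (identical row and column sets) the diagonal is excluded and
#' both (i, j) and (j, i) are counted, the convention consistent with the
#' element count N_Matrix = dim1 x dim2; masked (NA) entries are excluded
#' from n_corr.  Normalization against \code{nullRef} yields S_M and C.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}}.
#' @param rows,cols position sets of the selection (defaults: all).
#' @param nullRef randomized reference row
#'   (\code{\link{nullReference}} of a library, or a
#'   \code{NetworkMetrics}).
#' @param label network label.
#' @return a \code{NetworkMetrics}.
#' @export
networkMetrics <- function(D, rows = NULL, cols = NULL, nullRef = NULL,
                           label = "") {
  M <- couplingMatrix(D)
  L <- ncol(M)
  if (is.null(rows)) rows <- seq_len(L)
  if (is.null(cols)) cols <- seq_len(L)
  if (any(rows < 1L | rows > L) || any(cols < 1L | cols > L))
    stop("selection positions out of matrix bounds")
  if (!length(rows) || !length(cols)) stop("selection is empty")
  block <- M[rows, cols, drop = FALSE]
  vals <- as.vector(block)      # diagonal entries are NA and drop below
  n_matrix <- length(rows) * length(cols)
  ok <- !is.na(vals)
  metricsFromAggregates(sum_pos = sum(vals[ok & vals > 0]),
                        n_corr = sum(ok),
                        n_pos = sum(ok & vals > 0),
                        n_matrix = n_matrix,
                        nullRef = nullRef, label = label)
}

#' Extract a sub-matrix block with its original position labels
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}}.
#' @param rows,cols position sets.
#' @return for a symmetric selection, a \code{CoevolutionMatrix} over the
#'   selected positions (labels preserved as dimnames); otherwise the
#'   plain numeric block.
#' @export
subMatrix <- function(D, rows, cols = rows) {
  M <- couplingMatrix(D)
  L <- ncol(M)
  if (any(rows < 1L | rows > L) || any(cols < 1L | cols > L))
    stop("selection positions out of matrix bounds")
  block <- M[rows, cols, drop = FALSE]
  dimnames(block) <- list(rows, cols)
  if (length(rows) == length(cols) && all(rows == cols)) {
    out <- CoevolutionMatrix(block, provenance = list(positions = rows))
    return(out)
  }
  block
}

#' Metrics of the network spanned by the top three primary nodes
#'
#' The selection consists of all ordered pairs between positions of
#' different node windows (both (i, j) and (j, i); intra-node pairs and
#' the diagonal excluded), so N_Matrix = 2 sum_{a<b} |a||b|.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}}.
#' @param nodes data.frame from \code{\link{detectPrimaryNodes}} (needs
#'   >= 3 rows) or a list of integer position vectors.
#' @param nullRef randomized reference row.
#' @param label network label.
#' @return a \code{NetworkMetrics}.
#' @export
threeNodeNetwork <- function(D, nodes, nullRef = NULL,
                             label = "3-node") {
  if (is.data.frame(nodes)) {
    if (nrow(nodes) < 3L)
      stop("need at least 3 primary nodes; available: ", nrow(nodes),
           if (nrow(nodes)) paste0(" (peaks ",
                                   paste(nodes$peak, collapse = ", "), ")")
           else "")
    nodes <- nodes[order(-nodes$W), ][seq_len(3L), ]
    sets <- lapply(seq_len(3L), function(i) nodes$start[i]:nodes$end[i])
  } else {
    if (length(nodes) < 3L) stop("need at least 3 node position sets")
    sets <- nodes[seq_len(3L)]
  }
  M <- couplingMatrix(D)
  vals <- numeric()
  n_matrix <- 0L
  for (a in 1:2) for (b in (a + 1):3) {
    blk <- M[sets[[a]], sets[[b]], drop = FALSE]
    vals <- c(vals, as.vector(blk), as.vector(t(blk)))
    n_matrix <- n_matrix + 2L * length(sets[[a]]) * length(sets[[b]])
  }
  ok <- !is.na(vals)
  metricsFromAggregates(sum_pos = sum(vals[ok & vals > 0]),
                        n_corr = sum(ok), n_pos = sum(ok & vals > 0),
                        n_matrix = n_matrix, nullRef = nullRef,
                        label = label)
}

#' Autocorrelation of a centrality profile over residue lags
#'
#' Mean-centred normalized autocorrelation G(lag) at integer residue
#' spacings, used to detect the alpha-helical ~3.5-residue repeat in the
#' coupling-derived centrality.  Peak lags (local maxima of G) are
#' reported as an attribute.
#'
#' @param x numeric profile (centrality or difference weights).
#' @param maxLag largest lag (default floor(length/3)).
#' @return numeric vector G of length maxLag with attribute
#'   \code{"peaks"}; all zeros (with a warning) for a constant profile.
#' @export
centralityAutocorrelation <- function(x, maxLag = floor(length(x) / 3)) {
  if (inherits(x, "CentralityProfile")) x <- x$E
  L <- length(x)
  if (L < 3L * 1L) stop("profile too short")
  maxLag <- min(maxLag, L - 2L)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    warning("constant profile: autocorrelation undefined, returning zeros")
    G <- rep(0, maxLag)
    names(G) <- seq_len(maxLag)
    attr(G, "peaks") <- integer()
    return(G)
  }
  G <- vapply(seq_len(maxLag), function(k)
    sum(xc[seq_len(L - k)] * xc[(k + 1L):L]) / denom, numeric(1))
  names(G) <- seq_len(maxLag)
  d <- diff(sign(diff(c(-Inf, G, -Inf))))
  attr(G, "peaks") <- which(d == -2)
  G
}

#' Per-position profile table
#'
#' Collates entropy, centrality, null centrality and difference weights
#' into one table (one row per alignment column), the per-position export
#' of a run.
#'
#' @param entropy per-column entropy (bits).
#' @param E \code{CentralityProfile}.
#' @param prof \code{NodeWeightProfile}.
#' @param n window length used for the windowed weight column.
#' @return data.frame (position, entropy, E, E_R, deltaW, W); W is NA for
#'   positions past the last full window start.
#' @export
profileTable <- function(entropy, E, prof, n = 6L) {
  x <- if (inherits(E, "CentralityProfile")) E$E else E
  L <- length(x)
  W <- rep(NA_real_, L)
  Wv <- nodeWeights(prof$deltaW, n)
  W[seq_along(Wv)] <- Wv
  data.frame(position = seq_len(L), entropy = entropy, E = x,
             E_R = prof$ER, deltaW = prof$deltaW, W = W)
}
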