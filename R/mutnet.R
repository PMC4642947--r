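# Mutation-defined sub-networks: binary mask matrices over CW/CCW mutated
# residue positions, masked-network metrics, and shuffled dummy-list
# permutation significance.

#' Read mutation lists from a two-column TSV
#'
#' Expects columns \code{position} and \code{label} (e.g. CW / CCW); one
#' MutationList per label.
#'
#' @param path TSV file.
#' @return named list of \code{MutationList} objects (lists with
#'   \code{label}, \code{positions}, \code{source}).
#' @export
readMutationList <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("position", "label") %in% names(df)))
    stop("mutation list needs columns 'position' and 'label'")
  out <- lapply(split(df$position, df$label), function(p)
    mutationList(sort(unique(as.integer(p))), label = NA_character_,
                 source = path))
  for (nm in names(out)) out[[nm]]$label <- nm
  out
}

#' Construct a mutation list
#' @param positions integer residue positions (reference numbering).
#' @param label list label, e.g. \code{"CW"} or \code{"CCW"}.
#' @param source free-text provenance note.
#' @return a \code{MutationList}.
#' @export
mutationList <- function(positions, label = "custom", source = "") {
  structure(list(label = label,
                 positions = sort(unique(as.integer(positions))),
                 source = source),
            class = "MutationList")
}

#' @export
print.MutationList <- function(x, ...) {
  cat("MutationList [", x$label, "]: ", length(x$positions),
      " positions\n", sep = "")
  invisible(x)
}

#' Binary mask matrix over a mutation list
#'
#' L x L symmetric binary matrix with 1 at every off-diagonal pair (i, j)
#' whose two positions both belong to the (mapped) mutation list --
#' "all possible interactions" between the mutated positions.  Positions
#' are first translated through \code{map} (reference residue ->
#' alignment/matrix column) when one is supplied; unmappable positions
#' are dropped and counted.
#'
#' @param list a \code{MutationList} (or plain integer vector).
#' @param L matrix dimension.
#' @param map optional data.frame with columns \code{alignment_column}
#'   and \code{reference_residue} (as from \code{\link{trimToReference}}).
#' @return logical L x L matrix with attributes \code{"positions"}
#'   (mapped matrix columns) and \code{"dropped"} (count).
#' @export
buildMask <- function(list, L, map = NULL) {
  pos <- if (inherits(list, "MutationList")) list$positions
         else sort(unique(as.integer(list)))
  if (!is.null(map)) {
    idx <- match(pos, map$reference_residue)
    dropped <- sum(is.na(idx))
    if (dropped)
      message("dropping ", dropped, " unmappable position(s): ",
              paste(pos[is.na(idx)], collapse = " "))
    pos <- map$alignment_column[idx[!is.na(idx)]]
  } else {
    dropped <- sum(pos < 1L | pos > L)
    if (dropped)
      message("dropping ", dropped, " out-of-range position(s)")
    pos <- pos[pos >= 1L & pos <= L]
  }
  if (length(pos) < 2L)
    stop("fewer than 2 mappable positions; cannot build a mask")
  B <- matrix(FALSE, L, L)
  B[pos, pos] <- TRUE
  diag(B) <- FALSE
  attr(B, "positions") <- pos
  attr(B, "dropped") <- dropped
  B
}

#' Metrics and centrality of a mask-defined sub-network
#'
#' The masked network is the elementwise product of the coupling matrix
#' with the binary mask: metrics aggregate over the masked pairs only
#' (equivalently, the symmetric sub-matrix over the mutation positions,
#' with N_Matrix = m x m as for any selection), and the centrality is the
#' eigenvector centrality of the full-size masked matrix.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}}.
#' @param mask logical mask from \code{\link{buildMask}}.
#' @param nullRef randomized reference row.
#' @param label network label.
#' @return list with \code{metrics} (a \code{NetworkMetrics}) and
#'   \code{centrality} (a \code{CentralityProfile} of the masked matrix).
#' @export
maskedNetwork <- function(D, mask, nullRef = NULL, label = "masked") {
  M <- couplingMatrix(D)
  stopifnot(all(dim(mask) == dim(M)))
  pos <- attr(mask, "positions")
  if (is.null(pos)) pos <- which(apply(mask | t(mask), 1L, any))
  metrics <- networkMetrics(D, rows = pos, cols = pos,
                            nullRef = nullRef, label = label)
  Mm <- M
  Mm[!mask] <- 0
  cent <- eigenCentrality(Mm)
  list(metrics = metrics, centrality = cent)
}

#' Dummy-list permutation significance of a masked network
#'
#' Generates \code{nDummies} random position lists of the same
#' cardinality as the real list (uniform sampling without replacement
#' from the analyzable positions by default; \code{mode = "contiguous"}
#' draws a contiguous block instead), computes each dummy network's
#' strength and connectivity, and reports the mean and sigma of the
#' dummy / real ratios.  Ratios below 1 mean the real list targets
#' stronger / better-connected network features than chance.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}}.
#' @param realList a \code{MutationList} or integer vector of matrix
#'   columns (already mapped).
#' @param nDummies number of dummy lists (default 1000).
#' @param seed integer seed.
#' @param nullRef randomized reference row (optional; ratios are
#'   invariant to it).
#' @param mode \code{"uniform"} or \code{"contiguous"} dummy draws.
#' @param candidates positions the dummies are drawn from (default: all
#'   matrix columns).
#' @return list of class \code{DummyPopulation}: real metrics, ratio
#'   means and sigmas for S_M and C, \code{n}, \code{seed}, and the raw
#'   ratio vectors.
#' @export
dummyPopulation <- function(D, realList, nDummies = 1000L, seed = 1L,
                            nullRef = NULL, mode = c("uniform",
                                                     "contiguous"),
                            candidates = NULL) {
  mode <- match.arg(mode)
  nDummies <- as.integer(nDummies)
  if (nDummies < 100L) stop("nDummies must be >= 100")
  M <- couplingMatrix(D)
  L <- ncol(M)
  pos <- if (inherits(realList, "MutationList")) realList$positions
         else as.integer(realList)
  pos <- pos[pos >= 1L & pos <= L]
  m <- length(pos)
  if (m < 2L) stop("real list has fewer than 2 usable positions")
  if (is.null(candidates)) candidates <- seq_len(L)
  if (m > length(candidates))
    stop("list cardinality exceeds the available positions")

  if (is.null(nullRef))
    nullRef <- networkMetrics(D, label = "whole-matrix")
  real <- networkMetrics(D, rows = pos, cols = pos, nullRef = nullRef,
                         label = "real")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ratioS <- ratioC <- numeric(nDummies)
  for (k in seq_len(nDummies)) {
    dpos <- if (mode == "uniform") {
      sample(candidates, m)
    } else {
      s <- sample.int(length(candidates) - m + 1L, 1L)
      candidates[s:(s + m - 1L)]
    }
    dm <- suppressWarnings(
      networkMetrics(D, rows = dpos, cols = dpos, nullRef = nullRef))
    ratioS[k] <- dm$S_M / real$S_M
    ratioC[k] <- dm$C / real$C
  }
  structure(list(real = real,
                 S_M_ratio_mean = mean(ratioS),
                 S_M_ratio_sd = stats::sd(ratioS),
                 C_ratio_mean = mean(ratioC),
                 C_ratio_sd = stats::sd(ratioC),
                 n = nDummies, seed = as.integer(seed),
                 ratios = list(S_M = ratioS, C = ratioC)),
            class = "DummyPopulation")
}

#' @export
print.DummyPopulation <- function(x, ...) {
  cat("DummyPopulation: n =", x$n, ", seed =", x$seed, "\n")
  cat(sprintf("  dummy/real S_M = %.3f +/- %.3f, C = %.3f +/- %.3f\n",
              x$S_M_ratio_mean, x$S_M_ratio_sd,
              x$C_ratio_mean, x$C_ratio_sd))
  invisible(x)
}

#' Serialize a dummy-population significance report to JSON
#' @param pop a \code{DummyPopulation}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSignificanceReport <- function(pop, path) {
  jsonlite::write_json(
    list(real_S_M = pop$real$S_M, real_C = pop$real$C,
         S_M_ratio_mean = pop$S_M_ratio_mean,
         S_M_ratio_sd = pop$S_M_ratio_sd,
         C_ratio_mean = pop$C_ratio_mean,
         C_ratio_sd = pop$C_ratio_sd,
         n_dummies = pop$n, seed = pop$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
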