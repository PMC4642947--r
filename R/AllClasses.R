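#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CoevoNet, .registration = TRUE
NULL

#' Amino-acid alphabet used throughout the package
#'
#' Twenty standard amino acids, an unknown symbol \code{"X"} (non-standard
#' residues B, Z, U, O and X itself are folded into it and counted like a
#' residue), and the gap symbol \code{"-"}.  Gaps are treated as a symbol in
#' all frequency and entropy computations.
#'
#' @return Character vector of length 22.
#' @export
coevoAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
    "X", "-")
}

.ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
               "X", "-")
.NSYM <- length(.ALPHABET)
.GAP <- "-"
.UNKNOWN <- "X"

#' ProteinMSA: a validated multiple sequence alignment
#'
#' Rows are sequences, columns are residue positions.  Stored as a character
#' matrix of single symbols over \code{\link{coevoAlphabet}()}, with unique
#' sequence identifiers as row names.
#'
#' @slot mat character matrix (N x L), symbols in \code{coevoAlphabet()},
#'   row names are the (unique) sequence identifiers.
#' @export
setClass("ProteinMSA", representation(mat = "matrix"))

setValidity("ProteinMSA", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be character")
  if (nrow(m) < 2L) return("an alignment needs at least 2 sequences")
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequence identifiers must be present and unique")
  bad <- setdiff(unique(as.vector(m)), .ALPHABET)
  if (length(bad))
    return(paste0("symbols outside the alphabet: ",
                  paste(bad, collapse = " ")))
  TRUE
})

#' @describeIn ProteinMSA number of sequences (depth N)
#' @param x a \code{ProteinMSA}
#' @export
msaDepth <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  nrow(x@mat)
}

#' @describeIn ProteinMSA number of alignment columns (length L)
#' @export
msaLength <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  ncol(x@mat)
}

#' @describeIn ProteinMSA sequence identifiers
#' @export
msaIds <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  rownames(x@mat)
}

setMethod("show", "ProteinMSA", function(object) {
  cat("ProteinMSA:", nrow(object@mat), "sequences x",
      ncol(object@mat), "columns\n")
  n <- min(3L, nrow(object@mat))
  for (i in seq_len(n)) {
    row <- paste(object@mat[i, seq_len(min(40L, ncol(object@mat)))],
                 collapse = "")
    cat(sprintf("  %-20s %s%s\n", rownames(object@mat)[i], row,
                if (ncol(object@mat) > 40L) "..." else ""))
  }
  if (nrow(object@mat) > n) cat("  ...\n")
})

#' Extract the aligned character matrix of a ProteinMSA
#' @param x a \code{ProteinMSA}
#' @return character matrix, rows = sequences.
#' @export
msaMatrix <- function(x) {
  stopifnot(is(x, "ProteinMSA"))
  x@mat
}

#' Construct a ProteinMSA from a character matrix or vector of strings
#'
#' Symbols are uppercased, both gap dialects (\code{"."} and \code{"-"})
#' are mapped to \code{"-"}, and non-standard residues to \code{"X"}.
#'
#' @param x character matrix of single symbols, or character vector of
#'   equal-length aligned strings.
#' @param ids sequence identifiers (defaults to names/rownames of \code{x}).
#' @return a validated \code{ProteinMSA}.
#' @export
ProteinMSA <- function(x, ids = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(ids)) ids <- names(x)
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      off <- which(lens != lens[1L])[1L]
      stop("alignment integrity: record '",
           if (!is.null(ids)) ids[off] else off,
           "' has length ", lens[off], ", expected ", lens[1L])
    }
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(x)))
  m <- toupper(x)
  m[m == "."] <- .GAP
  m[!(m %in% .ALPHABET)] <- .UNKNOWN
  dimnames(m) <- list(ids, NULL)
  new("ProteinMSA", mat = m)
}

#' CoevolutionMatrix: symmetric residue-coupling matrix
#'
#' Holds the (normalized) direct-information values D_ij between alignment
#' columns.  The diagonal is masked (\code{NA}): self-coupling is undefined
#' in the estimator and never participates in means, thresholds or counts.
#'
#' @slot D numeric L x L symmetric matrix, \code{NA} diagonal.
#' @slot provenance list of estimator settings and input fingerprint.
#' @export
setClass("CoevolutionMatrix",
         representation(D = "matrix", provenance = "list"),
         prototype(provenance = list()))

setValidity("CoevolutionMatrix", function(object) {
  D <- object@D
  if (nrow(D) != ncol(D)) return("matrix must be square")
  if (!all(is.na(diag(D)))) return("diagonal must be masked (NA)")
  off <- D[upper.tri(D) | lower.tri(D)]
  if (any(!is.finite(off[!is.na(off)])))
    return("off-diagonal entries must be finite or NA")
  if (!isTRUE(all.equal(D, t(D)))) return("matrix must be symmetric")
  TRUE
})

#' Construct a CoevolutionMatrix
#' @param D symmetric numeric matrix; its diagonal is masked.
#' @param provenance optional list of estimator settings.
#' @return a \code{CoevolutionMatrix}.
#' @export
CoevolutionMatrix <- function(D, provenance = list()) {
  diag(D) <- NA_real_
  new("CoevolutionMatrix", D = D, provenance = provenance)
}

#' @describeIn CoevolutionMatrix number of positions (L)
#' @param x a \code{CoevolutionMatrix}
#' @export
matrixSize <- function(x) {
  stopifnot(is(x, "CoevolutionMatrix"))
  ncol(x@D)
}

setMethod("show", "CoevolutionMatrix", function(object) {
  off <- object@D[upper.tri(object@D)]
  off <- off[!is.na(off)]
  cat("CoevolutionMatrix:", ncol(object@D), "x", ncol(object@D),
      "positions\n")
  if (length(off))
    cat(sprintf("  off-diagonal range [%.4g, %.4g], mean %.4g\n",
                min(off), max(off), mean(off)))
})

#' Extract the numeric coupling matrix
#' @param x a \code{CoevolutionMatrix}
#' @return numeric matrix with \code{NA} diagonal.
#' @export
couplingMatrix <- function(x) {
  stopifnot(is(x, "CoevolutionMatrix"))
  x@D
}

#' NullLibrary: column-shuffled randomized-MSA calibration library
#'
#' Summaries of coevolution matrices computed from K column-shuffled copies
#' of an alignment.  Shuffling preserves per-column symbol multisets (hence
#' entropy) while destroying inter-column correlations, so the library
#' measures the residual correlation background against which all
#' thresholds (2-sigma nodes, 3-sigma edges) and the strength/connectivity
#' normalizations are calibrated.
#'
#' @slot K library size.
#' @slot seed master seed; member m uses seed + m.
#' @slot entryMean,entrySigma pooled off-diagonal matrix statistics.
#' @slot ER per-position mean centrality over the library.
#' @slot sigmaE per-position centrality standard deviation.
#' @slot Emat K x L matrix of member centrality profiles.
#' @slot aggregates pooled full-matrix aggregates (sum_pos, n_pos, n_corr,
#'   n_matrix summed over members) used as the randomized reference row.
#' @slot settings estimator settings the members were computed with.
#' @slot matrices optionally the K member matrices (list), else empty.
#' @export
setClass("NullLibrary",
         representation(K = "integer", seed = "integer",
                        entryMean = "numeric", entrySigma = "numeric",
                        ER = "numeric", sigmaE = "numeric",
                        Emat = "matrix", aggregates = "list",
                        settings = "list", matrices = "list"),
         prototype(matrices = list(), settings = list()))

setValidity("NullLibrary", function(object) {
  if (object@K < 2L) return("K must be >= 2 for sigma to be defined")
  if (length(object@ER) != length(object@sigmaE))
    return("ER and sigmaE must have equal length")
  if (nrow(object@Emat) != object@K)
    return("Emat must have K rows")
  TRUE
})

setMethod("show", "NullLibrary", function(object) {
  cat("NullLibrary: K =", object@K, ", L =", length(object@ER),
      ", seed =", object@seed, "\n")
  cat(sprintf("  pooled entries: mean %.4g, sigma %.4g\n",
              object@entryMean, object@entrySigma))
})

#' StructureModel: Calpha-centred view of a protein structure
#'
#' @slot residues data.frame with columns chain, resno, aa (one-letter),
#'   x, y, z (Calpha coordinates, Angstrom).
#' @slot atoms data.frame of heavy atoms (chain, resno, elety, element,
#'   x, y, z) used for solvent accessibility; may equal the Calpha set for
#'   synthetic traces.
#' @slot source identifier of the originating file or generator.
#' @export
setClass("StructureModel",
         representation(residues = "data.frame", atoms = "data.frame",
                        source = "character"))

setValidity("StructureModel", function(object) {
  r <- object@residues
  need <- c("chain", "resno", "aa", "x", "y", "z")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = " ")))
  if (nrow(r) && any(!is.finite(as.matrix(r[, c("x", "y", "z")]))))
    return("Calpha coordinates must be finite")
  TRUE
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", nrow(object@residues), "residues,",
      nrow(object@atoms), "heavy atoms [", object@source, "]\n")
})

#' Residue table of a StructureModel
#' @param x a \code{StructureModel}
#' @return data.frame (chain, resno, aa, x, y, z).
#' @export
structureResidues <- function(x) {
  stopifnot(is(x, "StructureModel"))
  x@residues
}

#' Calpha coordinate matrix of a StructureModel
#' @param x a \code{StructureModel}
#' @return numeric matrix (n x 3).
#' @export
caCoords <- function(x) {
  stopifnot(is(x, "StructureModel"))
  as.matrix(x@residues[, c("x", "y", "z")])
}
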