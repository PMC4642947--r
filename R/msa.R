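# Alignment I/O, per-column entropy, concatenation and reference trimming.

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via Biostrings) or Stockholm alignments into a
#' \code{\linkS4class{ProteinMSA}}.  Symbols are uppercased; both gap
#' dialects \code{"."} and \code{"-"} are mapped to \code{"-"};
#' non-standard residues (B, Z, U, O) become the unknown symbol \code{"X"}.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @return a validated \code{ProteinMSA}.
#' @export
readAlignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("FASTA format error in '", path,
                                             "': ", conditionMessage(e)))
    if (length(set) == 0L) stop("format error: '", path, "' has no records")
    seqs <- as.character(set)
    names(seqs) <- names(set)
  } else {
    seqs <- .readStockholm(path)
  }
  ProteinMSA(seqs)
}

# Minimal Stockholm parser: '#' lines are annotation, '//' terminates,
# sequence lines may be split over blocks and are concatenated per id.
.readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("format error: '", path, "' is empty")
  seqs <- character()
  for (ln in lines) {
    if (grepl("^\\s*(#|$)", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L)
      stop("Stockholm format error: cannot parse line '", ln, "'")
    id <- parts[1L]
    seqs[id] <- paste0(if (id %in% names(seqs)) seqs[id] else "", parts[2L])
  }
  if (!length(seqs)) stop("format error: '", path, "' has no sequence lines")
  seqs
}

#' Write an alignment to FASTA
#' @param aln a \code{ProteinMSA}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "ProteinMSA"))
  m <- msaMatrix(aln)
  txt <- character(2L * nrow(m))
  txt[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  txt[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(txt, path)
  invisible(path)
}

#' Per-column Shannon entropy
#'
#' S_i = -sum_j p_ij log2 p_ij over the symbols present in column i, where
#' p_ij is the fraction of sequences carrying symbol j at position i.  The
#' gap is counted as a symbol, and the unknown symbol like a residue.
#'
#' @param aln a \code{ProteinMSA}.
#' @return numeric vector of length L, entropies in bits.
#' @export
shannonEntropy <- function(aln) {
  m <- msaMatrix(aln)
  apply(m, 2L, function(col) {
    p <- tabulate(match(col, .ALPHABET), nbins = .NSYM)
    p <- p[p > 0] / length(col)
    -sum(p * log2(p))
  })
}

#' Default identifier-pairing key: the organism token of a header
#'
#' Strips a trailing \code{"/start-end"} range and returns the part after
#' the last underscore of the accession (Uniprot-style \code{NAME_ORGANISM}
#' headers map to \code{ORGANISM}).  Headers with no underscore are used
#' verbatim.
#'
#' @param ids character vector of sequence identifiers.
#' @return character vector of keys.
#' @export
organismKey <- function(ids) {
  base <- sub("/.*$", "", ids)
  ifelse(grepl("_", base), sub("^.*_", "", base), base)
}

#' Concatenate alignments column-wise by matched identifiers
#'
#' Rows are joined per common key (by default the organism token of the
#' header, see \code{\link{organismKey}}); keys present in only some inputs
#' are dropped.  With \code{manyToOne = TRUE}, a key duplicated in one
#' alignment is paired with the (unique) matching row of each other
#' alignment, replicating it -- e.g. pairing one FliM orthologue with each
#' of several FliG orthologues of the same organism.  With
#' \code{manyToOne = FALSE} duplicates keep their first occurrence and the
#' rest are reported via \code{message()}.
#'
#' @param alns list of \code{ProteinMSA}.
#' @param keyFun function mapping identifiers to pairing keys.
#' @param manyToOne allow duplicated keys (see Details).
#' @return a \code{ProteinMSA} with L = sum of input lengths.
#' @export
concatenateAlignments <- function(alns, keyFun = organismKey,
                                  manyToOne = FALSE) {
  stopifnot(length(alns) >= 2L, all(vapply(alns, is, TRUE, "ProteinMSA")))
  keysets <- lapply(alns, function(a) keyFun(msaIds(a)))
  common <- Reduce(intersect, keysets)
  if (!length(common))
    stop("empty result: the alignments share no identifier keys")

  pick <- function(keys) {
    idx <- lapply(common, function(k) which(keys == k))
    if (!manyToOne) {
      dup <- vapply(idx, length, 1L) > 1L
      if (any(dup))
        message("dropping ", sum(vapply(idx, length, 1L)[dup] - 1L),
                " duplicate row(s) for key(s): ",
                paste(common[dup], collapse = " "))
      idx <- lapply(idx, `[`, 1L)
    }
    idx
  }
  idxs <- lapply(keysets, pick)

  rows <- list()
  ids <- character()
  for (ci in seq_along(common)) {
    counts <- vapply(idxs, function(x) length(x[[ci]]), 1L)
    if (manyToOne && any(counts > 1L)) {
      if (sum(counts > 1L) > 1L)
        stop("key '", common[ci],
             "' duplicated in more than one alignment; cannot pair")
      reps <- max(counts)
    } else reps <- 1L
    for (r in seq_len(reps)) {
      segs <- mapply(function(a, x) {
        i <- x[[ci]][if (length(x[[ci]]) > 1L) r else 1L]
        msaMatrix(a)[i, , drop = TRUE]
      }, alns, idxs, SIMPLIFY = FALSE)
      rows[[length(rows) + 1L]] <- unlist(segs, use.names = FALSE)
      ids <- c(ids, if (reps > 1L) paste0(common[ci], ".", r) else common[ci])
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  ProteinMSA(m)
}

#' Trim an alignment to the columns covered by a reference sequence
#'
#' Only columns where the reference row carries a residue (non-gap) are
#' retained, and a bidirectional column-to-residue map is returned --
#' mirroring the elimination of positions absent from, or unresolved in, a
#' structure's sequence.  If \code{refId} is not already a row of the
#' alignment, \code{refSeq} is threaded into the MSA by global pairwise
#' alignment (BLOSUM62) against its best-matching row; a best identity
#' below \code{minIdentity} raises a mapping-confidence error.
#'
#' @param aln a \code{ProteinMSA}.
#' @param refSeq ungapped reference sequence (required when \code{refId}
#'   is not a row of \code{aln}).
#' @param refId identifier of the reference row (existing or added).
#' @param minIdentity mapping-confidence floor (fraction identity of the
#'   reference to its best MSA match), default 0.3.
#' @param addReference add the threaded reference as a row of the trimmed
#'   alignment when it was not already present (default TRUE).
#' @return list with elements \code{alignment} (trimmed
#'   \code{ProteinMSA}), \code{map} (data.frame \code{alignment_column},
#'   \code{reference_residue}, both 1-based), and \code{refId}.
#' @export
trimToReference <- function(aln, refSeq = NULL, refId = "reference",
                            minIdentity = 0.3, addReference = TRUE) {
  stopifnot(is(aln, "ProteinMSA"))
  m <- msaMatrix(aln)

  if (refId %in% rownames(m)) {
    refRow <- m[refId, ]
    added <- FALSE
  } else {
    if (is.null(refSeq))
      stop("refSeq is required when refId is not a row of the alignment")
    refChars <- strsplit(toupper(refSeq), "")[[1L]]
    refRow <- .threadReference(m, refChars, minIdentity)
    added <- TRUE
  }

  keep <- which(refRow != .GAP)
  if (!length(keep)) stop("reference covers no alignment column")
  map <- data.frame(alignment_column = keep,
                    reference_residue = seq_along(keep))

  mm <- m[, keep, drop = FALSE]
  if (added && addReference) {
    mm <- rbind(mm, refRow[keep])
    rownames(mm)[nrow(mm)] <- refId
  }
  list(alignment = ProteinMSA(mm), map = map, refId = refId)
}

# Thread an ungapped reference into the alignment coordinate system via
# global pairwise alignment against the best-identity row.
.threadReference <- function(m, refChars, minIdentity) {
  ref <- paste(refChars, collapse = "")
  ungapped <- apply(m, 1L, function(r) paste(r[r != .GAP], collapse = ""))
  ungapped <- ungapped[nchar(ungapped) > 0L]
  if (!length(ungapped)) stop("alignment contains only gaps")

  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  best <- NULL
  bestId <- -1
  for (id in names(ungapped)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref), Biostrings::AAString(ungapped[[id]]),
      substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pid <- Biostrings::pid(pa, type = "PID1") / 100
    if (pid > bestId) {
      bestId <- pid
      best <- list(id = id, pa = pa)
    }
  }
  if (bestId < minIdentity)
    stop("mapping confidence: best identity of the reference to the ",
         "alignment is ", sprintf("%.2f", bestId), " (< ", minIdentity,
         "), closest row '", best$id, "'")

  # map reference residues -> residues of the best row -> alignment columns
  pat <- strsplit(as.character(Biostrings::pattern(best$pa)), "")[[1L]]
  sbj <- strsplit(as.character(Biostrings::subject(best$pa)), "")[[1L]]
  rowChars <- m[best$id, ]
  rowCols <- which(rowChars != .GAP)   # residue k of row -> column rowCols[k]

  refRow <- rep(.GAP, ncol(m))
  ri <- 0L; si <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ri <- ri + 1L
    if (sbj[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sbj[k] != "-")
      refRow[rowCols[si]] <- refChars[ri]
  }
  if (!any(refRow != .GAP))
    stop("mapping confidence: reference could not be threaded")
  refRow
}

#' Write a column-to-reference map as TSV
#' @param map the \code{map} element returned by
#'   \code{\link{trimToReference}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeColumnMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
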