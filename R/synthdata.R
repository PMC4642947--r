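# Synthetic inputs with the statistical structure the analysis assumes:
# alignments with a per-column conservation gradient, a gap process and
# planted covarying column pairs; an ideal-helix Calpha trace with known
# contact geometry; and mutation lists overlapping the planted signal.
# Ground truth is carried alongside so every stage is testable.

#' Specification of a synthetic alignment
#'
#' Defaults define the package's reference bundle: 300 sequences over 120
#' columns, a linear per-column entropy gradient from 0.5 to 3.5 bits, a
#' 5 percent per-column gap rate, and 8 planted covarying column pairs at
#' coupling 0.9 concentrated on two 6-residue segments (columns 30-35 and
#' 80-85), so the planted pairs double as planted network node segments.
#'
#' @param N sequence depth.
#' @param L alignment length.
#' @param entropyRange target per-column entropy gradient in bits
#'   (linear from first to second value).
#' @param gapRate per-column gap probability.
#' @param coupledPairs data.frame (i, j, c) of planted pairs with
#'   coupling c in [0, 1]; NULL for the reference layout.
#' @param domainBoundary column splitting the alignment into two
#'   "domains" (for inter/intra block tests).
#' @param seed integer seed.
#' @return list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(N = 300L, L = 120L,
                          entropyRange = c(0.5, 3.5),
                          gapRate = 0.05,
                          coupledPairs = NULL,
                          domainBoundary = 60L,
                          seed = 1L) {
  if (is.null(coupledPairs)) {
    segA <- 30:35
    segB <- 80:85
    coupledPairs <- data.frame(
      i = c(segA, 30L, 31L),
      j = c(segB, 81L, 80L),
      c = 0.9)
  }
  stopifnot(all(coupledPairs$i != coupledPairs$j),
            all(coupledPairs$c >= 0 & coupledPairs$c <= 1),
            all(c(coupledPairs$i, coupledPairs$j) >= 1),
            all(c(coupledPairs$i, coupledPairs$j) <= L))
  structure(list(N = as.integer(N), L = as.integer(L),
                 entropyRange = entropyRange, gapRate = gapRate,
                 coupledPairs = coupledPairs,
                 domainBoundary = as.integer(domainBoundary),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# solve for the consensus probability q giving a target entropy (bits)
# of the distribution (q on one residue, (1-q)/19 on the other 19)
.consensusProb <- function(targetBits) {
  if (targetBits > log2(20) - 1e-9)
    stop("unsatisfiable entropy target: ", targetBits, " > log2(20)")
  H <- function(q) {
    p <- c(q, rep((1 - q) / 19, 19))
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (targetBits <= 0) return(1)
  stats::uniroot(function(q) H(q) - targetBits,
                 lower = 1 / 20 + 1e-9, upper = 1 - 1e-12,
                 tol = 1e-10)$root
}

#' Generate a synthetic alignment with planted covarying pairs
#'
#' Columns are drawn independently from 20-residue distributions tuned to
#' the target entropy gradient.  For each planted pair (i, j, c), with
#' probability c the symbol at j is a fixed bijective image of the symbol
#' at i (a deterministic coupling diluted by c), else drawn from column
#' j's own distribution.  Gaps are inserted per column at the spec's gap
#' rate afterwards.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{alignment} (a \code{ProteinMSA}) and
#'   \code{truth} (ground-truth record: planted pairs, planted node
#'   segments, per-column consensus probabilities, seed).
#' @export
generateMSA <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  aa <- .ALPHABET[1:20]
  L <- spec$L; N <- spec$N
  targets <- seq(spec$entropyRange[1L], spec$entropyRange[2L],
                 length.out = L)
  consensus <- sample.int(20L, L, replace = TRUE)
  q <- vapply(targets, .consensusProb, numeric(1))

  m <- matrix("", N, L)
  for (l in seq_len(L)) {
    p <- rep((1 - q[l]) / 19, 20)
    p[consensus[l]] <- q[l]
    m[, l] <- aa[sample.int(20L, N, replace = TRUE, prob = p)]
  }

  # planted couplings: bijective symbol map per pair, diluted by c
  perm <- sample.int(20L)     # one fixed bijection for the bundle
  bij <- stats::setNames(aa[perm], aa)
  for (r in seq_len(nrow(spec$coupledPairs))) {
    i <- spec$coupledPairs$i[r]
    j <- spec$coupledPairs$j[r]
    cc <- spec$coupledPairs$c[r]
    link <- stats::runif(N) < cc
    m[link, j] <- bij[m[link, i]]
  }

  if (spec$gapRate > 0) {
    gap <- matrix(stats::runif(N * L) < spec$gapRate, N, L)
    m[gap] <- .GAP
  }
  rownames(m) <- sprintf("synth%04d_ORG%04d", seq_len(N), seq_len(N))

  segs <- .plantedSegments(spec)
  truth <- list(pairs = spec$coupledPairs,
                nodeSegments = segs,
                consensus = consensus, consensusProb = q,
                bijection = bij, seed = spec$seed,
                domainBoundary = spec$domainBoundary)
  list(alignment = ProteinMSA(m), truth = truth)
}

# contiguous runs among the planted coupled positions = planted node
# segments (the coupled columns are laid out as segments by default)
.plantedSegments <- function(spec) {
  pos <- sort(unique(c(spec$coupledPairs$i, spec$coupledPairs$j)))
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  br <- c(0L, which(diff(pos) > 1L), length(pos))
  do.call(rbind, lapply(seq_len(length(br) - 1L), function(b) {
    s <- pos[br[b] + 1L]; e <- pos[br[b + 1L]]
    data.frame(start = s, end = e)
  }))
}

#' Generate a toy Calpha trace with known contact geometry
#'
#' An ideal alpha-helical trace (rise 1.5 Angstrom per residue, 100
#' degree twist, 2.3 Angstrom helix radius) laid out as two parallel
#' helical segments: residues up to \code{foldPoint} on the first axis,
#' the rest on a second axis \code{axisSep} Angstrom away, axially offset
#' so the requested contact pairs sit below 12 Angstrom.  Far pairs are
#' verified to lie beyond 20 Angstrom; an infeasible constraint set is an
#' error.
#'
#' @param L residue count.
#' @param contacts data.frame (i, j) of pairs required below 12
#'   Angstrom; default: the reference bundle's planted pairs.
#' @param farPairs data.frame (i, j) of pairs required beyond 20
#'   Angstrom; default: the chain ends.
#' @param foldPoint residue index separating the two segments.
#' @param axisSep distance between the two helix axes (Angstrom).
#' @return list with \code{model} (a
#'   \code{\linkS4class{StructureModel}}) and \code{truth} (geometry
#'   record).
#' @export
generateStructure <- function(L = 120L,
                              contacts = data.frame(i = 30:35, j = 80:85),
                              farPairs = data.frame(i = 1L, j = L),
                              foldPoint = 60L, axisSep = 9) {
  L <- as.integer(L)
  stopifnot(foldPoint >= 1L, foldPoint < L)
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3

  # axial offset aligning the first contact pair across the two segments
  if (nrow(contacts)) {
    i0 <- contacts$i[1L]; j0 <- contacts$j[1L]
    if (i0 > foldPoint || j0 <= foldPoint)
      stop("infeasible constraints: contact pairs must straddle foldPoint")
    off <- j0 - i0
  } else off <- foldPoint
  helix <- function(i, x0, zi) {
    c(x0 + radius * cos(twist * i), radius * sin(twist * i), rise * zi)
  }
  xyz <- t(vapply(seq_len(L), function(i) {
    if (i <= foldPoint) helix(i, 0, i) else helix(i, axisSep, i - off)
  }, numeric(3)))

  dmat <- as.matrix(stats::dist(xyz))
  if (nrow(contacts)) {
    dc <- dmat[cbind(contacts$i, contacts$j)]
    if (any(dc >= 12))
      stop("infeasible constraints: contact pair(s) at ",
           paste(sprintf("%.1f", dc[dc >= 12]), collapse = " "),
           " Angstrom (need < 12)")
  }
  if (nrow(farPairs)) {
    df <- dmat[cbind(farPairs$i, farPairs$j)]
    if (any(df <= 20))
      stop("infeasible constraints: far pair(s) at ",
           paste(sprintf("%.1f", df[df <= 20]), collapse = " "),
           " Angstrom (need > 20)")
  }

  residues <- data.frame(chain = "A", resno = seq_len(L), aa = "A",
                         x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                         stringsAsFactors = FALSE)
  atoms <- data.frame(chain = "A", resno = seq_len(L), elety = "CA",
                      element = "C", x = xyz[, 1L], y = xyz[, 2L],
                      z = xyz[, 3L], stringsAsFactors = FALSE)
  model <- new("StructureModel", residues = residues, atoms = atoms,
               source = "synthetic-helix")
  list(model = model,
       truth = list(contacts = contacts, farPairs = farPairs,
                    foldPoint = foldPoint, axisSep = axisSep,
                    rise = rise, twistDeg = 100, radius = radius))
}

#' Write a StructureModel as a minimal PDB file
#' @param model a \code{\linkS4class{StructureModel}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
  at <- model@atoms
  aa3 <- names(.AA3TO1)[match(model@residues$aa[match(at$resno,
                                model@residues$resno)], .AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(at)), at$elety, aa3, at$chain, at$resno,
    at$x, at$y, at$z, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate mutation lists overlapping the planted signal
#'
#' One list drawing the stated fraction of its positions from the
#' planted coupled columns (emulating mutations that target network
#' features) and one of equal size; at \code{overlap = 0} the first list
#' is disjoint from the planted positions.  The companion list is always
#' uniform-random over non-planted columns.
#'
#' @param truth ground-truth record from \code{\link{generateMSA}}.
#' @param overlap fraction of the first list inside planted positions.
#' @param size list size (default 10).
#' @param L alignment length.
#' @param seed integer seed.
#' @return list with \code{targeted} and \code{random}
#'   \code{MutationList} objects of equal size.
#' @export
generateMutationLists <- function(truth, overlap = 1, size = 10L,
                                  L = 120L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  planted <- sort(unique(c(truth$pairs$i, truth$pairs$j)))
  others <- setdiff(seq_len(L), planted)
  nIn <- round(size * overlap)
  nIn <- min(nIn, length(planted))
  sel <- c(sample(planted, nIn),
           sample(others, size - nIn))
  rnd <- sample(others, size)
  list(targeted = mutationList(sel, label = "targeted",
                               source = "synthetic"),
       random = mutationList(rnd, label = "random",
                             source = "synthetic"))
}
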