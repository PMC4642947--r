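# Structure mapping: PDB reading (bio3d), alignment <-> structure residue
# maps with residue-type verification, Calpha distance matrices, contact
# vs long-range coupling statistics, Shrake-Rupley solvent accessibility,
# conserved surface patches, and Kabsch superposition RMSD.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "U", PYL = "O")

#' Read a PDB structure into a StructureModel
#'
#' First model only; alternate locations resolved to the highest
#' occupancy; waters and hetero atoms ignored; residues lacking a Calpha
#' are excluded (with a message).  Hydrogens are dropped from the
#' heavy-atom table used for solvent accessibility.
#'
#' @param path PDB file.
#' @param chain chain identifier (default: first protein chain).
#' @return a \code{\linkS4class{StructureModel}}.
#' @export
readStructure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!(chain %in% chains))
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = " "))
  at <- at[at$chain == chain, , drop = FALSE]

  # altloc: per atom name within a residue keep the highest occupancy
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix[which.max(at$o[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- toupper(substr(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(trimws(at$elety), 1L, 1L),
                                       at$elesy)), 1L, 2L))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]

  ca <- at[at$elety == "CA", , drop = FALSE]
  allRes <- unique(at$resno)
  noCA <- setdiff(allRes, ca$resno)
  if (length(noCA))
    message("excluding ", length(noCA),
            " residue(s) lacking a Calpha: ",
            paste(utils::head(noCA, 10L), collapse = " "))
  aa1 <- .AA3TO1[ca$resid]
  aa1[is.na(aa1)] <- "X"
  residues <- data.frame(chain = ca$chain, resno = ca$resno, aa = aa1,
                         x = ca$x, y = ca$y, z = ca$z,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      elety = trimws(at$elety), element = elem,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[atoms$resno %in% residues$resno, , drop = FALSE]
  new("StructureModel", residues = residues, atoms = atoms,
      source = basename(path))
}

#' Map alignment columns onto structure residues
#'
#' Threads the structure's sequence into the alignment (via
#' \code{\link{trimToReference}}) and returns a bijective map from
#' alignment columns to (chain, residue number).  Residue types at mapped
#' positions must agree between the threaded reference row and the
#' structure -- a mismatch is a hard error, the correctness check that
#' guarantees high-scoring couplings land on the right residues.
#'
#' @param aln a \code{ProteinMSA}.
#' @param model a \code{\linkS4class{StructureModel}}.
#' @param refId identifier of an alignment row known to be the
#'   structure's sequence.  When given, the map is built from that row
#'   and every mapped position's residue type is verified against the
#'   structure (mismatch = hard error).  When NULL (default) the
#'   structure sequence is threaded into the alignment by pairwise
#'   alignment first.
#' @param minIdentity mapping-confidence floor (see
#'   \code{\link{trimToReference}}).
#' @return list of class \code{ResidueMap}: data.frame \code{table}
#'   (alignment_column, reference_residue, chain, resno, aa),
#'   \code{coverage} (fraction of structure residues mapped), and the
#'   trimmed alignment.
#' @export
mapStructure <- function(aln, model, refId = NULL, minIdentity = 0.3) {
  res <- structureResidues(model)
  if (!is.null(refId)) {
    if (!(refId %in% msaIds(aln)))
      stop("refId '", refId, "' is not a row of the alignment")
    tr <- trimToReference(aln, refId = refId, minIdentity = minIdentity)
    refRow <- msaMatrix(tr$alignment)[refId, ]
  } else {
    refSeq <- paste(res$aa, collapse = "")
    tr <- trimToReference(aln, refSeq = refSeq, refId = "..structure..",
                          minIdentity = minIdentity, addReference = TRUE)
    refRow <- msaMatrix(tr$alignment)["..structure..", ]
  }
  tab <- tr$map
  if (max(tab$reference_residue) > nrow(res))
    stop("reference row has more residues (", max(tab$reference_residue),
         ") than the structure (", nrow(res), ")")
  tab$chain <- res$chain[tab$reference_residue]
  tab$resno <- res$resno[tab$reference_residue]
  tab$aa <- res$aa[tab$reference_residue]
  # residue-type check: trimmed column k corresponds to reference
  # residue k, so refRow[k] must equal the structure's residue k
  mism <- which(refRow != tab$aa & refRow != .UNKNOWN & tab$aa != "X")
  if (length(mism))
    stop("residue-type mismatch at alignment column ",
         tab$alignment_column[mism[1L]], ": alignment '",
         refRow[mism[1L]], "' vs structure '", tab$aa[mism[1L]],
         "' (", tab$chain[mism[1L]], tab$resno[mism[1L]], ")")
  structure(list(table = tab,
                 coverage = nrow(tab) / nrow(res),
                 alignment = tr$alignment),
            class = "ResidueMap")
}

#' @export
print.ResidueMap <- function(x, ...) {
  cat("ResidueMap:", nrow(x$table), "columns mapped, coverage",
      sprintf("%.2f\n", x$coverage))
  invisible(x)
}

#' Pairwise Calpha distance matrix
#'
#' @param model a \code{\linkS4class{StructureModel}}.
#' @param map optional \code{ResidueMap}: restrict to mapped residues, in
#'   map order (so the matrix is indexed like the trimmed alignment).
#' @return symmetric matrix of Euclidean distances in Angstrom, zero
#'   diagonal.
#' @export
distanceMatrix <- function(model, map = NULL) {
  xyz <- caCoords(model)
  if (!is.null(map)) {
    stopifnot(inherits(map, "ResidueMap"))
    xyz <- xyz[map$table$reference_residue, , drop = FALSE]
  }
  if (nrow(xyz) < 2L) stop("need at least 2 residues")
  as.matrix(stats::dist(xyz))
}

#' Contact / long-range coupling statistics
#'
#' Classifies every scored pair by Calpha distance -- contact [0, 12),
#' intermediate [12, 20], long-range (20, Inf) Angstrom, boundary values
#' on the non-contact side -- and reports per class the pair count, the
#' mean and sigma of the coupling values, and the fraction F of pairs
#' above the high-scoring threshold.  A two-way contact (< 12) vs
#' non-contact (>= 12) split is reported alongside.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}} (or numeric matrix)
#'   indexed like \code{distances}.
#' @param distances Calpha distance matrix (same indexing).
#' @param mask logical high-scoring mask from
#'   \code{\link{highScoringThreshold}} (same indexing), or NULL to skip
#'   F.
#' @param contactCut,longCut class boundaries in Angstrom.
#' @return list of class \code{ContactStats}: data.frame \code{classes}
#'   (class, count, mean, sd, F) and data.frame \code{twoWay}.
#' @export
contactStats <- function(D, distances, mask = NULL,
                         contactCut = 12, longCut = 20) {
  M <- if (is(D, "CoevolutionMatrix")) couplingMatrix(D) else D
  stopifnot(all(dim(M) == dim(distances)))
  iu <- upper.tri(M)
  ok <- iu & !is.na(M)
  v <- M[ok]
  d <- distances[ok]
  h <- if (!is.null(mask)) mask[ok] else rep(NA, length(v))

  cls <- cut(d, breaks = c(-Inf, contactCut, longCut, Inf),
             labels = c("contact", "intermediate", "long-range"),
             right = FALSE)
  # [12, 20] inclusive at 20: cut(right = FALSE) puts 20 in long-range;
  # move exact-boundary values back into the intermediate class
  cls[d == longCut] <- "intermediate"

  one <- function(sel, name) {
    data.frame(class = name, count = sum(sel),
               mean = if (any(sel)) mean(v[sel]) else NA_real_,
               sd = if (sum(sel) > 1L) stats::sd(v[sel]) else NA_real_,
               F = if (any(sel) && !all(is.na(h)))
                 mean(h[sel]) else NA_real_)
  }
  classes <- rbind(one(cls == "contact", "contact"),
                   one(cls == "intermediate", "intermediate"),
                   one(cls == "long-range", "long-range"))
  twoWay <- rbind(one(d < contactCut, "contact"),
                  one(d >= contactCut, "non-contact"))
  structure(list(classes = classes, twoWay = twoWay,
                 contactCut = contactCut, longCut = longCut,
                 nPairs = length(v)),
            class = "ContactStats")
}

#' @export
print.ContactStats <- function(x, ...) {
  cat("ContactStats over", x$nPairs, "pairs (cuts", x$contactCut, "/",
      x$longCut, "Angstrom):\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

# --- Shrake-Rupley solvent accessibility ------------------------------

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

# near-uniform points on the unit sphere (golden spiral)
.spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a water-sized probe (1.4 Angstrom) over the heavy atoms: each
#' atom's expanded sphere (van der Waals radius + probe) is sampled with
#' near-uniform points and the accessible fraction is the share of points
#' inside no neighbouring expanded sphere.  Areas are summed per residue.
#'
#' @param model a \code{\linkS4class{StructureModel}}.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints sphere sample points per atom (default 960;
#'   doubling the sampling then moves per-residue areas by ~1 percent).
#' @return data.frame (chain, resno, area) in Angstrom^2, one row per
#'   residue, with per-atom areas as attribute \code{"atomArea"}.
#' @export
solventAccessibility <- function(model, probe = 1.4, nPoints = 960L) {
  at <- model@atoms
  if (!nrow(at)) stop("structure has no heavy atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- .VDW[at$element]
  r[is.na(r)] <- 1.70
  R <- r + probe
  pts <- .spherePoints(nPoints)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour search: atoms closer than R_i + max(R) can occlude
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    p <- pts * R[i]
    p <- sweep(p, 2L, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dj <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
          (p[, 3L] - xyz[j, 3L])^2
        free <- free & (dj > R[j]^2)
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    area[i] <- 4 * pi * R[i]^2 * frac
  }
  res <- stats::aggregate(area,
                          by = list(chain = at$chain, resno = at$resno),
                          FUN = sum)
  names(res)[3L] <- "area"
  res <- res[order(match(res$resno, model@residues$resno)), ]
  rownames(res) <- NULL
  attr(res, "atomArea") <- area
  res
}

#' Conservation score from an entropy profile
#'
#' 1 - S_i / max(S): an entropy-based conservation proxy on [0, 1]
#' (1 = fully conserved).  Any externally computed per-column score
#' (e.g. an evolutionary-rate score) can be used in its place wherever a
#' conservation profile is accepted.
#'
#' @param S per-column Shannon entropy (bits).
#' @return numeric conservation scores.
#' @export
conservationScore <- function(S) {
  mx <- max(S)
  if (mx == 0) return(rep(1, length(S)))
  1 - S / mx
}

#' Conserved, solvent-accessible surface patches
#'
#' Maximal contiguous runs of more than 4 columns (i.e. length >= 5)
#' where both the conservation score and the solvent accessibility
#' strictly exceed their own profile means.
#'
#' @param conservation per-column conservation score.
#' @param accessibility per-column (per mapped residue) accessibility.
#' @return data.frame (start, end, length, mean_conservation,
#'   mean_accessibility); zero rows when nothing qualifies.
#' @export
surfacePatches <- function(conservation, accessibility) {
  stopifnot(length(conservation) == length(accessibility))
  qual <- conservation > mean(conservation) &
    accessibility > mean(accessibility)
  qual[is.na(qual)] <- FALSE
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > 4L
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), mean_conservation = numeric(),
                      mean_accessibility = numeric()))
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep],
             mean_conservation = vapply(which(keep), function(i)
               mean(conservation[starts[i]:ends[i]]), numeric(1)),
             mean_accessibility = vapply(which(keep), function(i)
               mean(accessibility[starts[i]:ends[i]]), numeric(1)))
}

#' Optimal rigid-body superposition RMSD (Kabsch)
#'
#' Least-squares superposition of two Calpha coordinate sets over a
#' common set of equivalent positions: both sets are centred, the optimal
#' rotation is obtained from the SVD of the cross-covariance (with the
#' usual determinant correction against reflections), and the RMSD over
#' the common positions is returned.
#'
#' @param a,b \code{\linkS4class{StructureModel}} objects or n x 3
#'   coordinate matrices.
#' @param common indices of equivalent positions: an integer vector
#'   (same indices in both) or a two-column matrix (index in a, index
#'   in b).  Default: all positions, paired in order.
#' @return RMSD in Angstrom, with the rotation matrix as attribute
#'   \code{"rotation"}.
#' @export
superposeRmsd <- function(a, b, common = NULL) {
  A <- if (is(a, "StructureModel")) caCoords(a) else as.matrix(a)
  B <- if (is(b, "StructureModel")) caCoords(b) else as.matrix(b)
  if (is.null(common)) {
    n <- min(nrow(A), nrow(B))
    ia <- ib <- seq_len(n)
  } else if (is.matrix(common)) {
    ia <- common[, 1L]; ib <- common[, 2L]
  } else {
    ia <- ib <- as.integer(common)
  }
  if (length(ia) < 3L) stop("need at least 3 common positions")
  P <- A[ia, , drop = FALSE]
  Q <- B[ib, , drop = FALSE]
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P %*% t(Rm)
  rmsd <- sqrt(mean(rowSums((Pr - Q)^2)))
  attr(rmsd, "rotation") <- Rm
  rmsd
}

#' Annotated high-scoring edge list
#'
#' One row per high-scoring pair (i < j): alignment columns, residue
#' identities and numbers, coupling value, Calpha distance and distance
#' class.
#'
#' @param D a \code{\linkS4class{CoevolutionMatrix}} indexed like the
#'   map/distances.
#' @param mask logical high-scoring mask.
#' @param map a \code{ResidueMap} (or NULL: columns only).
#' @param distances Calpha distance matrix (or NULL: no distances).
#' @param contactCut,longCut class boundaries in Angstrom.
#' @return data.frame (col_i, col_j, res_i, res_j, D, dist, class).
#' @export
edgeMap <- function(D, mask, map = NULL, distances = NULL,
                    contactCut = 12, longCut = 20) {
  M <- couplingMatrix(D)
  sel <- which(mask & upper.tri(M), arr.ind = TRUE)
  res <- data.frame(col_i = sel[, 1L], col_j = sel[, 2L])
  n <- nrow(res)
  if (!is.null(map)) {
    tab <- map$table
    res$res_i <- paste0(tab$aa[res$col_i], tab$resno[res$col_i])
    res$res_j <- paste0(tab$aa[res$col_j], tab$resno[res$col_j])
  } else {
    res$res_i <- rep(NA_character_, n)
    res$res_j <- rep(NA_character_, n)
  }
  res$D <- M[sel]
  if (!is.null(distances)) {
    res$dist <- distances[sel]
    res$class <- ifelse(res$dist < contactCut, "contact",
                        ifelse(res$dist > longCut, "long-range",
                               "intermediate"))
  } else {
    res$dist <- rep(NA_real_, n)
    res$class <- rep(NA_character_, n)
  }
  res[order(-res$D), , drop = FALSE]
}
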