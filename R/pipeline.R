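# End-to-end orchestration from a config file: inputs -> coevolution
# matrix -> null library -> centrality/nodes -> per-network metrics
# report -> edge maps and patches, with a provenance manifest.

#' Read and validate a run configuration
#'
#' YAML with fields: \code{msa} (path) or \code{synthetic: true};
#' optional \code{msa_format}, \code{structure} (PDB path),
#' \code{mutation_lists} (TSV path), \code{domains} (named list of
#' [start, end]), estimator settings (\code{weighting}, \code{theta},
#' \code{pseudocount}, \code{rho}), \code{null_K}, \code{seed},
#' \code{window} (node window n), \code{node_sigma}, \code{edge_sigma},
#' \code{contact_cut}, \code{long_cut}, \code{dummies}, \code{outdir}.
#' Missing fields take the package defaults (K = 100, n = 6, 2 sigma
#' nodes, 3 sigma edges, 1000 dummies, 12/20 Angstrom).
#'
#' @param path YAML file, or a list with the same fields.
#' @return validated config list (class \code{RunConfig}).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(msa_format = "fasta", weighting = "identity_cluster",
                   theta = 0.62, pseudocount = 1, rho = 1e-3,
                   null_K = 100L, seed = 1L, window = 6L,
                   node_sigma = 2, edge_sigma = 3,
                   contact_cut = 12, long_cut = 20, dummies = 1000L,
                   synthetic = FALSE, outdir = "coevonet-run")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  num <- c("theta", "pseudocount", "rho", "null_K", "seed", "window",
           "node_sigma", "edge_sigma", "contact_cut", "long_cut",
           "dummies")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("config field '", nm, "' must be a nonnegative number")
  if (cfg$node_sigma <= 0 || cfg$edge_sigma <= 0 ||
      cfg$contact_cut <= 0 || cfg$long_cut <= 0)
    stop("thresholds must be positive")
  if (!isTRUE(cfg$synthetic)) {
    if (is.null(cfg$msa)) stop("config needs 'msa' or 'synthetic: true'")
    if (!file.exists(cfg$msa)) stop("missing input file: ", cfg$msa)
  }
  for (f in c("structure", "mutation_lists"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("missing input file: ", cfg[[f]])
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis described by a config
#'
#' Stages: load (or synthesize) the alignment; estimate the coevolution
#' matrix; build the column-shuffled null library; centrality, difference
#' profile and primary nodes; strength/connectivity metrics for the
#' complete network, each configured domain, every inter-domain block,
#' mutation-mask networks (with dummy significance) and the 3-node
#' network; high-scoring edge map (with distances when a structure is
#' given) and conserved surface patches.  Everything is written under
#' \code{cfg$outdir} together with a provenance manifest; the run is
#' deterministic given the config.
#'
#' @param cfg a \code{RunConfig} (or path to one).
#' @return the output directory, invisibly; the metrics report is also
#'   returned as attribute \code{"report"}.
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "RunConfig")) cfg <- readRunConfig(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[", format(Sys.time(), "%H:%M:%S"), "] ",
                               ...)

  log("stage msa: loading alignment")
  if (isTRUE(cfg$synthetic)) {
    bundle <- generateMSA(syntheticSpec(seed = cfg$seed))
    aln <- bundle$alignment
    jsonlite::write_json(bundle$truth[c("pairs", "nodeSegments", "seed")],
                         file.path(cfg$outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    writeAlignment(aln, file.path(cfg$outdir, "alignment.fasta"))
  } else {
    aln <- readAlignment(cfg$msa, format = cfg$msa_format)
  }
  entropy <- shannonEntropy(aln)

  log("stage coevo: estimating coevolution matrix (L = ",
      msaLength(aln), ", N = ", msaDepth(aln), ")")
  est <- list(weighting = cfg$weighting, theta = cfg$theta,
              pseudocount = cfg$pseudocount, rho = cfg$rho)
  D <- do.call(coevolutionMatrix, c(list(aln = aln), est))
  writeCoevolutionMatrix(D, file.path(cfg$outdir, "coevolution.tsv"),
                         file.path(cfg$outdir, "edges.tsv"))

  log("stage null: building shuffled library (K = ", cfg$null_K, ")")
  null <- do.call(buildNullLibrary,
                  c(list(aln = aln, K = cfg$null_K, seed = cfg$seed), est))
  writeNullLibrary(null, file.path(cfg$outdir, "null_library.json"))
  nullRef <- nullReference(null)

  log("stage network: centrality, nodes, thresholds")
  cent <- eigenCentrality(D)
  prof <- differenceProfile(cent, null)
  nodes <- detectPrimaryNodes(prof, null, n = cfg$window,
                              nSigma = cfg$node_sigma)
  hs <- highScoringThreshold(D, null, nSigma = cfg$edge_sigma)
  utils::write.table(profileTable(entropy, cent, prof, cfg$window),
                     file.path(cfg$outdir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(nodes, file.path(cfg$outdir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log("stage metrics: network report")
  rows <- list(metricsFromAggregates(
    sum_pos = nullRef$sum_pos, n_corr = nullRef$n_corr,
    n_pos = nullRef$n_pos, n_matrix = nullRef$n_matrix,
    label = "randomized"))
  rows <- c(rows, list(networkMetrics(D, nullRef = nullRef,
                                      label = "complete")))
  doms <- cfg$domains
  if (!is.null(doms)) {
    sets <- lapply(doms, function(b) b[1L]:b[2L])
    for (nm in names(sets))
      rows <- c(rows, list(networkMetrics(D, sets[[nm]], sets[[nm]],
                                          nullRef, label = nm)))
    if (length(sets) >= 2L) {
      nms <- names(sets)
      for (a in seq_len(length(sets) - 1L))
        for (b in (a + 1L):length(sets))
          rows <- c(rows, list(networkMetrics(
            D, sets[[nms[a]]], sets[[nms[b]]], nullRef,
            label = paste0(nms[a], "-", nms[b], " inter"))))
    }
  }
  if (!is.null(cfg$mutation_lists)) {
    ml <- readMutationList(cfg$mutation_lists)
    for (nm in names(ml)) {
      B <- buildMask(ml[[nm]], msaLength(aln))
      mn <- maskedNetwork(D, B, nullRef, label = paste0(nm, " network"))
      rows <- c(rows, list(mn$metrics))
      pop <- dummyPopulation(D, attr(B, "positions"),
                             nDummies = cfg$dummies, seed = cfg$seed,
                             nullRef = nullRef)
      writeSignificanceReport(pop, file.path(
        cfg$outdir, paste0("significance_", nm, ".json")))
    }
  }
  if (nrow(nodes) >= 3L)
    rows <- c(rows, list(threeNodeNetwork(D, nodes, nullRef)))

  report <- reportTable(rows, file.path(cfg$outdir, "metrics.tsv"))

  if (!is.null(cfg$structure)) {
    log("stage structure: mapping couplings")
    model <- readStructure(cfg$structure, chain = cfg$chain)
    rmap <- mapStructure(aln, model)
    dmat <- distanceMatrix(model, rmap)
    cols <- rmap$table$alignment_column
    Dsub <- subMatrix(D, cols)
    hsSub <- highScoringThreshold(Dsub, null, nSigma = cfg$edge_sigma)
    cs <- contactStats(Dsub, dmat, hsSub$mask,
                       contactCut = cfg$contact_cut,
                       longCut = cfg$long_cut)
    utils::write.table(cs$classes,
                       file.path(cfg$outdir, "contact_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    em <- edgeMap(Dsub, hsSub$mask, rmap, dmat,
                  contactCut = cfg$contact_cut, longCut = cfg$long_cut)
    utils::write.table(em, file.path(cfg$outdir, "edge_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sasa <- solventAccessibility(model)
    cons <- conservationScore(entropy[cols])
    acc <- sasa$area[match(rmap$table$resno, sasa$resno)]
    patches <- surfacePatches(cons, acc)
    utils::write.table(patches, file.path(cfg$outdir, "patches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    config = unclass(cfg)[order(names(unclass(cfg)))],
    config_hash = rlang::hash(unclass(cfg)[order(names(unclass(cfg)))]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("CoevoNet")),
    n_sequences = msaDepth(aln), n_columns = msaLength(aln))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("run complete: ", cfg$outdir)
  out <- cfg$outdir
  attr(out, "report") <- report
  invisible(out)
}

#' Assemble and verify the metrics report table
#'
#' One row per network with the eight report columns (sum of positive
#' correlations, element counts, density, raw strength, C, S_M).  A
#' verification pass recomputes C and S_M of every row from its raw
#' columns against the randomized row and stops on disagreement beyond
#' 2 decimal places (round-trip check).
#'
#' @param rows list of \code{NetworkMetrics}; the first row labelled
#'   \code{"randomized"} is the reference.
#' @param path optional TSV output path.
#' @return data.frame in the printed column order.
#' @export
reportTable <- function(rows, path = NULL) {
  if (!length(rows)) {
    df <- data.frame(label = character(), sum_pos = numeric(),
                     n_corr = numeric(), n_pos = numeric(),
                     n_matrix = numeric(), density = numeric(),
                     strength_raw = numeric(), C = numeric(),
                     S_M = numeric())
  } else {
    df <- do.call(rbind, lapply(rows, as.data.frame))
    ref <- which(df$label == "randomized")
    if (length(ref)) {
      ref <- ref[1L]
      refRow <- metricsFromAggregates(df$sum_pos[ref], df$n_corr[ref],
                                      df$n_pos[ref], df$n_matrix[ref])
      for (r in seq_len(nrow(df))) {
        chk <- suppressWarnings(metricsFromAggregates(
          df$sum_pos[r], df$n_corr[r], df$n_pos[r], df$n_matrix[r],
          nullRef = if (r == ref) NULL else refRow))
        if (!is.na(df$C[r]) &&
            (abs(chk$C - df$C[r]) > 0.005 + 1e-9 ||
             abs(chk$S_M - df$S_M[r]) > 0.005 + 1e-9))
          stop("report verification failed for row '", df$label[r], "'")
      }
    }
  }
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
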