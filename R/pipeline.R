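# End-to-end orchestration: validated run configuration, staged execution
# (structures -> ensemble -> screening -> selectivity -> plif) over plain
# files, structured logging and a provenance manifest.

validationError <- function(fmt, ...) {
  stop(structure(class = c("kindock_validation_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

# full schema of known keys with documented defaults; unknown keys rejected
defaultRunConfig <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, structures = TRUE, ensemble = TRUE,
                  screening = TRUE, selectivity = TRUE, plif = TRUE),
    inputs = list(pdb_dir = NULL, distance_matrix = NULL, scores_a = NULL,
                  scores_b = NULL, lbi = NULL, position_map = NULL),
    simulate = list(
      ensemble = list(k = 5L, members_per_cluster = 15L, site_residues = 12L,
                      sigma_within = 0.3, sigma_between = 3.0),
      screen = list(n_actives = 694L, n_inactives = 857L, delta = 1.2,
                    sigma = 1.0, n_conformers = 4L, biased_fraction = 0.02,
                    beta = 1.0),
      complexes = list(n_active = 20L, n_inactive = 20L, n_decoys = 50L)),
    structures = list(site_cutoff_A = 5.0),
    ensemble = list(k = NULL, k_range = c(2L, 8L),
                    population_threshold = 0.25, representative_cap = 3L,
                    lbi_threshold_A = 2.0),
    screening = list(component = "total", alpha = 20, auc_min = 0.70,
                     cutoff_fractions = c(0.002, 0.005, 0.01, 0.02, 0.05,
                                          0.10)),
    selectivity = list(top_fraction = 0.05, rr_cutoff = 0,
                       separation_margin = 0.05, consensus = "mean",
                       comparisons = 2L),
    plif = list(hbond_dist_A = 3.5, hbond_angle_deg = 120,
                hydrophobic_dist_A = 4.5, aromatic_dist_A = 5.5,
                ionic_dist_A = 4.0, pose_rmsd_threshold_A = 2.0))
}

checkKnownKeys <- function(cfg, schema, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(schema))
      validationError("unknown config key '%s%s'", path, nm)
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]])) &&
        !is.null(cfg[[nm]])) {
      if (!is.list(cfg[[nm]]))
        validationError("config key '%s%s' must be a mapping", path, nm)
      checkKnownKeys(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys before any
#' computation, and fills every missing tunable with its documented default.
#'
#' @param path YAML file path, or `NULL` for the full default configuration.
#' @param overrides optional named list merged over the file (e.g. a seed
#'   override from the command line).
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  schema <- defaultRunConfig()
  checkKnownKeys(cfg, schema)
  if (!is.null(overrides)) {
    checkKnownKeys(overrides, schema)
    cfg <- mergeConfig(cfg, overrides)
  }
  out <- mergeConfig(schema, cfg)
  if (!is.numeric(out$seed)) validationError("seed must be numeric")
  out
}

stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

fileDigests <- function(paths) {
  if (is.null(paths) || !length(paths)) return(list())
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the full post-processing pipeline
#'
#' Executes the enabled stages in order (structures, ensemble, screening,
#' selectivity, plif), writing each stage's outputs under `outDir` and a
#' provenance manifest (`manifest.json`) recording the configuration
#' snapshot, input digests, package version, per-stage row counts and
#' timestamps.  The manifest is emitted on success and on failure (with the
#' failure point); all other CSV/JSON outputs are byte-reproducible for a
#' fixed configuration.  With the simulate stage enabled all inputs are
#' generated by the synthetic module with known ground truth; otherwise they
#' are read from the configured input paths.
#'
#' @param config validated configuration from [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @return A list: `status` (0 = ok), `artifacts` (named paths), `results`
#'   (in-memory stage results), `manifest` (manifest path).
#' @export
runPipeline <- function(config, outDir) {
  t0 <- Sys.time()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(); rowCounts <- list(); results <- list()
  inputPaths <- unlist(config$inputs[!vapply(config$inputs, is.null,
                                             logical(1))])
  failedStage <- NULL
  writeManifest <- function(status) {
    manifest <- list(
      tool = list(package = "kindock",
                  version = as.character(utils::packageVersion("kindock"))),
      status = status, failed_stage = failedStage,
      config = config,
      input_digests = fileDigests(inputPaths),
      row_counts = rowCounts,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  on.exit(writeManifest(if (is.null(failedStage)) "ok" else "failed"))
  seed <- as.integer(config$seed)
  runStage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    failedStage <<- name
    fun()
    failedStage <<- NULL
  }

  ## structures + ensemble ----------------------------------------------------
  D <- NULL; structuresList <- NULL
  runStage("structures", function() {
    dir.create(file.path(outDir, "structures"), showWarnings = FALSE)
    if (isTRUE(config$stages$simulate)) {
      es <- config$simulate$ensemble
      gen <- genConformerEnsemble(ensembleSpec(
        k = es$k, membersPerCluster = es$members_per_cluster,
        siteResidues = es$site_residues, sigmaWithin = es$sigma_within,
        sigmaBetween = es$sigma_between, seed = seed))
      structuresList <<- gen$structures
      results$planted_partition <<- gen$partition
    } else if (!is.null(config$inputs$pdb_dir)) {
      paths <- sort(list.files(config$inputs$pdb_dir, "\\.pdb$",
                               full.names = TRUE))
      if (!length(paths))
        validationError("no PDB files in '%s'", config$inputs$pdb_dir)
      structuresList <<- lapply(paths, readStructurePDB)
    } else {
      validationError("structures stage needs the simulate stage or inputs.pdb_dir")
    }
    al <- alignEnsemble(structuresList, cutoff = config$structures$site_cutoff_A)
    sites <- lapply(al$structures, function(s)
      extractBindingSite(s, config$structures$site_cutoff_A))
    D <<- pairwiseRmsdMatrix(al$structures, al$site)
    artifacts$distance_matrix <<- writeDistanceMatrixTSV(
      D, file.path(outDir, "structures", "distance_matrix.tsv"))
    artifacts$binding_sites <<- writeBindingSitesJSON(
      sites, file.path(outDir, "structures", "binding_sites.json"))
    rowCounts$structures <<- list(n_structures = length(structuresList),
                                  n_site_residues = length(al$site))
    stageLog("structures", "%d structures, %d consensus site residues",
             length(structuresList), length(al$site))
  })

  runStage("ensemble", function() {
    if (is.null(D)) {
      if (is.null(config$inputs$distance_matrix))
        validationError("ensemble stage needs the structures stage or inputs.distance_matrix")
      D <<- readDistanceMatrixTSV(config$inputs$distance_matrix)
    }
    dir.create(file.path(outDir, "ensemble"), showWarnings = FALSE)
    k <- config$ensemble$k
    if (is.null(k)) {
      ch <- chooseClusterCount(D, seq(config$ensemble$k_range[1],
                                      config$ensemble$k_range[2]))
      k <- ch$k
      stageLog("ensemble", "silhouette-selected k = %d", k)
    }
    model <- clusterConformers(D, k)
    reps <- selectRepresentatives(
      D, model, populationThreshold = config$ensemble$population_threshold,
      cap = config$ensemble$representative_cap)
    # docking-fidelity records: simulated re-dock deviations, or a table
    lbi <- if (!is.null(config$inputs$lbi)) {
      read.table(config$inputs$lbi, sep = ",", header = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      withSeed(seed + 1L, data.frame(
        structure_id = dmLabels(D),
        pose_deviation_A = runif(length(dmLabels(D)), 0.2, 2.5)))
    }
    reps <- applyLbiFilter(reps, lbi, D, model,
                           threshold = config$ensemble$lbi_threshold_A)
    mds <- mdsProject(D, dims = min(3, length(dmLabels(D)) - 1))
    artifacts$assignments <<- writeClusterAssignmentsCSV(
      model, file.path(outDir, "ensemble", "assignments.csv"))
    artifacts$representatives <<- writeRepresentativesJSON(
      reps, file.path(outDir, "ensemble", "representatives.json"))
    mdsPath <- file.path(outDir, "ensemble", "mds.csv")
    write.table(mds, mdsPath, sep = ",", quote = FALSE, row.names = FALSE)
    artifacts$mds <<- mdsPath
    results$cluster_model <<- model
    results$representatives <<- reps
    rowCounts$ensemble <<- list(k = k,
                                n_representatives = nrow(representatives(reps)))
    stageLog("ensemble", "k = %d, %d representatives", k,
             nrow(representatives(reps)))
  })

  ## screening ----------------------------------------------------------------
  screens <- NULL
  runStage("screening", function() {
    dir.create(file.path(outDir, "screening"), showWarnings = FALSE)
    if (isTRUE(config$stages$simulate)) {
      ss <- config$simulate$screen
      screens <<- genScreenTable(screenSpec(
        nActives = ss$n_actives, nInactives = ss$n_inactives,
        delta = ss$delta, sigma = ss$sigma, nConformers = ss$n_conformers,
        biasedFraction = ss$biased_fraction, beta = ss$beta,
        seed = seed + 2L))
    } else {
      if (is.null(config$inputs$scores_a))
        validationError("screening stage needs the simulate stage or inputs.scores_a")
      screens <<- list(kinaseA = readScreenTableCSV(config$inputs$scores_a),
                       kinaseB = if (!is.null(config$inputs$scores_b))
                         readScreenTableCSV(config$inputs$scores_b))
    }
    sc <- config$screening
    reports <- evaluateConformers(screens$kinaseA, component = sc$component,
                                  alpha = sc$alpha,
                                  cutoffFractions = sc$cutoff_fractions)
    selected <- selectConformers(reports, aucMin = sc$auc_min)
    agg <- writeMetricsReport(
      reports, jsonPath = file.path(outDir, "screening", "metrics.json"),
      tsvPath = file.path(outDir, "screening", "metrics.tsv"))
    artifacts$metrics <<- file.path(outDir, "screening", "metrics.json")
    # ROC points of the best-AUC conformer for external plotting
    best <- agg$perConformer$conformer_id[which.max(agg$perConformer$auc)]
    dd <- screenData(screens$kinaseA)
    dd <- dd[dd$conformer_id == best & dd$label != "unknown", ]
    rocPath <- file.path(outDir, "screening", "roc_points.csv")
    write.table(cbind(conformer_id = best,
                      rocPoints(dd[[sc$component]], dd$label)),
                rocPath, sep = ",", quote = FALSE, row.names = FALSE)
    artifacts$roc_points <<- rocPath
    selPath <- file.path(outDir, "screening", "selected_conformers.json")
    jsonlite::write_json(list(auc_min = sc$auc_min, selected = selected),
                         selPath, auto_unbox = TRUE, pretty = TRUE)
    artifacts$selected_conformers <<- selPath
    results$reports <<- reports
    results$selected_conformers <<- selected
    rowCounts$screening <<- list(
      n_rows = nrow(screenData(screens$kinaseA)),
      n_conformers = length(reports), n_selected = length(selected))
    stageLog("screening", "%d/%d conformers retained", length(selected),
             length(reports))
  })

  ## selectivity --------------------------------------------------------------
  runStage("selectivity", function() {
    if (is.null(screens) || is.null(screens$kinaseB))
      validationError("selectivity stage needs kinase A and B score tables")
    dir.create(file.path(outDir, "selectivity"), showWarnings = FALSE)
    sel <- config$selectivity
    conf <- results$selected_conformers
    if (is.null(conf) || !length(conf)) conf <- NULL
    rankA <- normalizeRanks(screens$kinaseA, conformers = conf,
                            component = config$screening$component,
                            consensus = sel$consensus)
    rankB <- normalizeRanks(screens$kinaseB, conformers = conf,
                            component = config$screening$component,
                            consensus = sel$consensus)
    tab <- selectivityTable(rankA, rankB)
    conc <- concordance(rankA, rankB)
    hits <- prioritizeHits(rankA, rankB, topFraction = sel$top_fraction,
                           rrCutoff = sel$rr_cutoff,
                           separationMargin = sel$separation_margin)
    # paired component tests on shared actives (vdW and electrostatics)
    tests <- list()
    dA <- screenData(screens$kinaseA); dB <- screenData(screens$kinaseB)
    if (all(c("vdw", "elec") %in% names(dA))) {
      act <- unique(dA$ligand_id[dA$label == "active"])
      for (comp in c("vdw", "elec")) {
        avgA <- tapply(dA[[comp]][dA$ligand_id %in% act],
                       dA$ligand_id[dA$ligand_id %in% act], mean)
        avgB <- tapply(dB[[comp]][dB$ligand_id %in% act],
                       dB$ligand_id[dB$ligand_id %in% act], mean)
        shared <- intersect(names(avgA), names(avgB))
        tests[[comp]] <- pairedComponentTest(avgA[shared], avgB[shared],
                                             m = sel$comparisons)
      }
    }
    artifacts$selectivity <<- writeSelectivityCSV(
      tab, file.path(outDir, "selectivity", "selectivity.csv"))
    artifacts$hits <<- writeHitListCSV(
      hits, file.path(outDir, "selectivity", "hits.csv"))
    artifacts$concordance <<- writeConcordanceJSON(
      conc, file.path(outDir, "selectivity", "concordance.json"))
    testsPath <- file.path(outDir, "selectivity", "component_tests.json")
    jsonlite::write_json(tests, testsPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    artifacts$component_tests <<- testsPath
    results$hits <<- hits
    results$concordance <<- conc
    results$component_tests <<- tests
    rowCounts$selectivity <<- list(n_shared = nrow(tab),
                                   n_hits = nrow(hitTable(hits)))
    stageLog("selectivity", "rho = %.3f, %d hits", conc$spearman_rho,
             nrow(hitTable(hits)))
  })

  ## plif ---------------------------------------------------------------------
  runStage("plif", function() {
    dir.create(file.path(outDir, "plif"), showWarnings = FALSE)
    pc <- config$plif
    criteria <- plifCriteria(hbondDist = pc$hbond_dist_A,
                             hbondAngleDeg = pc$hbond_angle_deg,
                             hydrophobicDist = pc$hydrophobic_dist_A,
                             aromaticDist = pc$aromatic_dist_A,
                             ionicDist = pc$ionic_dist_A)
    if (!isTRUE(config$stages$simulate))
      validationError("plif stage currently requires the simulate stage (pose inputs by path are read through detectInteractions directly)")
    cs <- config$simulate$complexes
    hingeBits <- data.frame(
      position = c("hinge.46", "hinge.48", "aD.55"),
      type = c("hbond.acceptor", "hbond.donor", "hydrophobic"),
      stringsAsFactors = FALSE)
    offBits <- data.frame(position = "linker.50", type = "hydrophobic",
                          stringsAsFactors = FALSE)
    fps <- list(); labs <- character()
    for (i in seq_len(cs$n_active + cs$n_inactive)) {
      isActive <- i <= cs$n_active
      cx <- genComplex(complexSpec(
        plantedBits = if (isActive) hingeBits else offBits,
        nDecoys = cs$n_decoys, seed = seed + 100L + i))
      fps[[i]] <- detectInteractions(cx$pose, cx$protein, cx$map, criteria,
                                     ligandId = sprintf("CPLX%03d", i))
      labs[i] <- if (isActive) "active" else "inactive"
    }
    enr <- bitEnrichment(fps, labs)
    hinge <- vapply(fps, hingeMotif, logical(1))
    artifacts$fingerprints <<- writeFingerprintTSV(
      fps, file.path(outDir, "plif", "fingerprints.tsv"), labs)
    enrPath <- file.path(outDir, "plif", "enrichment.csv")
    write.table(enr, enrPath, sep = ",", quote = FALSE, row.names = FALSE)
    artifacts$enrichment <<- enrPath
    hingePath <- file.path(outDir, "plif", "hinge.json")
    jsonlite::write_json(
      list(hinge_rate_active = mean(hinge[labs == "active"]),
           hinge_rate_inactive = mean(hinge[labs == "inactive"]),
           criteria = criteria),
      hingePath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts$hinge <<- hingePath
    results$bit_enrichment <<- enr
    results$hinge <<- hinge
    rowCounts$plif <<- list(n_fingerprints = length(fps),
                            n_bits = nrow(enr))
    stageLog("plif", "%d fingerprints, %d distinct bits", length(fps),
             nrow(enr))
  })

  list(status = 0L, artifacts = artifacts, results = results,
       manifest = file.path(outDir, "manifest.json"))
}
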