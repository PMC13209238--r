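# Synthetic fixtures with known ground truth: clustered conformer ensembles,
# dual-target score tables with planted activity/selectivity effects, and toy
# complexes with planted interaction geometry.  Every generator is a pure
# function of its spec (seed included); no global random state leaks.

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Spec for a synthetic clustered conformer ensemble
#'
#' `k` cluster centers are drawn as per-atom displacements of scale
#' `sigmaBetween` around a common binding-site template; each member adds
#' isotropic per-atom noise of scale `sigmaWithin`.  Defaults emulate a
#' deposited-kinase ensemble: 5 conformational families of 15 monomers each,
#' a 12-residue pocket, ~0.3 A within-family heavy-atom scatter and ~3 A
#' between-family displacements.
#'
#' @param k number of planted clusters.
#' @param membersPerCluster members per cluster (scalar or length-k vector).
#' @param siteResidues number of pocket residues (4 heavy atoms each).
#' @param sigmaWithin,sigmaBetween noise scales in angstroms (both > 0).
#' @param seed RNG seed.
#' @return A list of class `ensembleSpec`.
#' @export
ensembleSpec <- function(k = 5, membersPerCluster = 15, siteResidues = 12,
                         sigmaWithin = 0.3, sigmaBetween = 3.0, seed = 1) {
  stopifnot(isCount(k), isCount(siteResidues),
            all(membersPerCluster >= 1), sigmaWithin > 0, sigmaBetween > 0)
  structure(list(k = as.integer(k),
                 membersPerCluster = rep_len(as.integer(membersPerCluster), k),
                 siteResidues = as.integer(siteResidues),
                 sigmaWithin = sigmaWithin, sigmaBetween = sigmaBetween,
                 seed = as.integer(seed)),
            class = "ensembleSpec")
}

#' Generate a clustered conformer ensemble with known partition
#'
#' @param spec an [ensembleSpec()].
#' @return A list: `structures` (list of [StructureRecord-class]),
#'   `partition` (named integer, structure id -> planted cluster), `spec`.
#' @export
genConformerEnsemble <- function(spec) {
  stopifnot(inherits(spec, "ensembleSpec"))
  withSeed(spec$seed, {
    nRes <- spec$siteResidues
    # residue directions on a sphere; pocket residues at radius 6 A with the
    # reference ligand atoms at radius 2 A along the same directions (so each
    # residue sits 4 A from a ligand atom, inside the 5 A site cutoff)
    u <- matrix(rnorm(3 * nRes), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    resCenters <- 6 * u
    offsets <- rbind(N = c(0.7, 0, 0), CA = c(0, 0.7, 0),
                     C = c(-0.7, 0, 0), O = c(0, -0.7, 0))
    baseProt <- resCenters[rep(seq_len(nRes), each = 4), ] +
      offsets[rep(1:4, nRes), ]
    ligand <- data.frame(
      elety = paste0("C", seq_len(nRes)), elesy = "C", chain = "A",
      resno = 900L, icode = "", resid = "LIG",
      x = 2 * u[, 1], y = 2 * u[, 2], z = 2 * u[, 3],
      stringsAsFactors = FALSE)
    protTemplate <- data.frame(
      elety = rep(rownames(offsets), nRes),
      elesy = rep(c("N", "C", "C", "O"), nRes), chain = "A",
      resno = rep(seq_len(nRes), each = 4), icode = "",
      resid = "ALA", x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
    structures <- list()
    partition <- integer()
    for (c in seq_len(spec$k)) {
      center <- baseProt +
        matrix(rnorm(length(baseProt), sd = spec$sigmaBetween),
               nrow = nrow(baseProt))
      for (m in seq_len(spec$membersPerCluster[c])) {
        coords <- center +
          matrix(rnorm(length(baseProt), sd = spec$sigmaWithin),
                 nrow = nrow(baseProt))
        prot <- protTemplate
        prot$x <- coords[, 1]; prot$y <- coords[, 2]; prot$z <- coords[, 3]
        id <- sprintf("synth_c%02d_m%02d", c, m)
        structures[[id]] <- StructureRecord(id, prot, ligand, "LIG")
        partition[id] <- c
      }
    }
    list(structures = structures, partition = partition, spec = spec)
  })
}

#' Spec for a synthetic dual-target screen
#'
#' Total scores follow the docking convention (lower = better): inactives
#' ~ Normal(0, sigma), actives ~ Normal(-delta, sigma); a tagged fraction of
#' the actives receives an additional -beta shift against kinase A only (the
#' planted isoform bias).  Each (kinase, conformer) replicate adds
#' independent Normal(0, sigma/2) jitter; component columns are generated as
#' vdw = 0.6 * total and elec = 0.2 * total, each plus Normal(0, sigma/4)
#' noise (a fixed testing convention, not a physical decomposition).
#' Defaults mirror a benchmark of 694 actives / 857 inactives screened
#' against 4 retained conformers, with an activity effect delta = 1.2 sigma
#' (population AUC about 0.80) and a small biased subset (2% of actives,
#' beta = 1 sigma).
#'
#' @param nActives,nInactives class sizes.
#' @param delta active score shift (score units; lower = better).
#' @param sigma score noise scale.
#' @param nConformers conformer replicates per kinase.
#' @param biasedFraction fraction of actives tagged as kinase-A biased.
#' @param beta extra kinase-A shift of the tagged subset (>= 0).
#' @param seed RNG seed.
#' @return A list of class `screenSpec`.
#' @export
screenSpec <- function(nActives = 694, nInactives = 857, delta = 1.2,
                       sigma = 1.0, nConformers = 4, biasedFraction = 0.02,
                       beta = 1.0, seed = 1) {
  stopifnot(isCount(nActives), isCount(nInactives), isCount(nConformers),
            delta >= 0, sigma > 0, beta >= 0,
            biasedFraction >= 0, biasedFraction <= 1)
  structure(list(nActives = as.integer(nActives),
                 nInactives = as.integer(nInactives),
                 delta = delta, sigma = sigma,
                 nConformers = as.integer(nConformers),
                 biasedFraction = biasedFraction, beta = beta,
                 seed = as.integer(seed)),
            class = "screenSpec")
}

#' Generate a dual-target screen table pair with planted effects
#'
#' @param spec a [screenSpec()].
#' @return A list: `kinaseA`, `kinaseB` ([ScreenTable-class] objects),
#'   `truth` (data.frame: `ligand_id`, `label`, `tagged`, `pchembl`,
#'   `standard_value_nM`), `spec`.
#' @export
genScreenTable <- function(spec) {
  stopifnot(inherits(spec, "screenSpec"))
  withSeed(spec$seed, {
    nA <- spec$nActives; nI <- spec$nInactives
    n <- nA + nI
    ids <- sprintf("LIG%05d", seq_len(n))
    active <- c(rep(TRUE, nA), rep(FALSE, nI))
    nTag <- floor(spec$biasedFraction * nA)
    tagged <- c(seq_len(n) <= nTag)   # first actives tagged
    base <- rnorm(n, mean = ifelse(active, -spec$delta, 0), sd = spec$sigma)
    pchembl <- ifelse(active, runif(n, 7.2, 9.0), runif(n, 4.0, 5.3))
    truth <- data.frame(ligand_id = ids,
                        label = ifelse(active, "active", "inactive"),
                        tagged = tagged, pchembl = pchembl,
                        standard_value_nM = 10^(9 - pchembl),
                        stringsAsFactors = FALSE)
    makeTable <- function(kinase, bias) {
      rows <- lapply(seq_len(spec$nConformers), function(cf) {
        total <- base + bias + rnorm(n, sd = spec$sigma / 2)
        data.frame(ligand_id = ids, conformer_id = sprintf("conf%02d", cf),
                   kinase_id = kinase, total = total,
                   vdw = 0.6 * total + rnorm(n, sd = spec$sigma / 4),
                   elec = 0.2 * total + rnorm(n, sd = spec$sigma / 4),
                   label = truth$label, stringsAsFactors = FALSE)
      })
      ScreenTable(do.call(rbind, rows))
    }
    kinaseA <- makeTable("kinaseA", ifelse(tagged, -spec$beta, 0))
    kinaseB <- makeTable("kinaseB", 0)
    list(kinaseA = kinaseA, kinaseB = kinaseB, truth = truth, spec = spec)
  })
}

#' Spec for a toy protein-ligand complex with planted interactions
#'
#' Each planted bit occupies its own spatial pod (pods 20 A apart, so planted
#' geometries never interfere); decoy ligand atoms are placed at least 6 A
#' from every protein atom, violating all criteria with a wide margin.
#' Planted geometries satisfy the default criteria with >= 0.3 A slack:
#' hydrogen bonds at 2.9 A, hydrophobic contacts at 4.0 A, ring centroids at
#' 4.5 A, ionic contacts at 3.6 A.
#'
#' @param plantedBits data.frame with columns `position` (canonical label)
#'   and `type` (interaction type); at most one bit per position.
#' @param nDecoys number of decoy ligand atoms.
#' @param seed RNG seed.
#' @return A list of class `complexSpec`.
#' @export
complexSpec <- function(plantedBits = data.frame(
                          position = c("hinge.46", "hinge.48", "aD.55"),
                          type = c("hbond.acceptor", "hbond.donor",
                                   "hydrophobic"),
                          stringsAsFactors = FALSE),
                        nDecoys = 50, seed = 1) {
  stopifnot(is.data.frame(plantedBits),
            all(c("position", "type") %in% names(plantedBits)))
  bad <- setdiff(plantedBits$position, klifsPositions())
  if (length(bad))
    stopf("infeasible geometry request: unknown position(s) %s",
          paste(bad, collapse = ", "))
  bad <- setdiff(plantedBits$type, interactionTypes)
  if (length(bad))
    stopf("infeasible geometry request: unknown interaction type(s) %s",
          paste(bad, collapse = ", "))
  if (anyDuplicated(plantedBits$position))
    stopf("infeasible geometry request: at most one planted bit per position")
  stopifnot(nDecoys >= 0)
  structure(list(plantedBits = plantedBits, nDecoys = as.integer(nDecoys),
                 seed = as.integer(seed)),
            class = "complexSpec")
}

hexagonRing <- function(center, radius = 1.39) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

#' Generate a toy complex realizing a planted interaction bit set
#'
#' Emits a protein record, a ligand pose and a position map such that
#' [detectInteractions()] under the default criteria returns exactly the
#' planted bits.
#'
#' @param spec a [complexSpec()].
#' @return A list: `protein` ([StructureRecord-class]), `pose` (ligand atom
#'   table), `map` (position map data.frame), `planted` (character vector of
#'   planted `"position|type"` bits), `spec`.
#' @export
genComplex <- function(spec) {
  stopifnot(inherits(spec, "complexSpec"))
  pb <- spec$plantedBits
  sid <- "synth_complex"
  protRows <- list(); poseRows <- list(); mapRows <- list()
  atomRow <- function(elety, elesy, resno, resid, xyz) {
    data.frame(elety = elety, elesy = elesy, chain = "A", resno = resno,
               icode = "", resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
               stringsAsFactors = FALSE)
  }
  ligRow <- function(elety, elesy, xyz, charge = 0, ring = NA_integer_) {
    data.frame(elety = elety, elesy = elesy, chain = "A", resno = 901L,
               icode = "", resid = "LIG", x = xyz[1], y = xyz[2], z = xyz[3],
               charge = charge, ring = ring, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pb))) {
    p0 <- c(20 * i, 0, 0)
    type <- pb$type[i]
    if (type == "hbond.donor") {
      protRows[[length(protRows) + 1]] <-
        rbind(atomRow("N", "N", i, "GLY", p0),
              atomRow("CA", "C", i, "GLY", p0 + c(0, 0, 1.5)))
      poseRows[[length(poseRows) + 1]] <-
        ligRow(sprintf("O%d", i), "O", p0 + c(2.9, 0, 0))
    } else if (type == "hbond.acceptor") {
      protRows[[length(protRows) + 1]] <-
        rbind(atomRow("O", "O", i, "GLY", p0),
              atomRow("CA", "C", i, "GLY", p0 + c(0, 0, 1.5)))
      poseRows[[length(poseRows) + 1]] <-
        ligRow(sprintf("N%d", i), "N", p0 + c(2.9, 0, 0))
    } else if (type == "hydrophobic") {
      protRows[[length(protRows) + 1]] <-
        rbind(atomRow("CD1", "C", i, "LEU", p0),
              atomRow("CA", "C", i, "LEU", p0 + c(0, 0, 6)))
      poseRows[[length(poseRows) + 1]] <-
        ligRow(sprintf("C%d", i), "C", p0 + c(4.0, 0, 0))
    } else if (type == "aromatic") {
      ring <- hexagonRing(p0)
      protRows[[length(protRows) + 1]] <- do.call(rbind, c(
        lapply(seq_len(6), function(a)
          atomRow(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")[a], "C", i, "PHE",
                  ring[a, ])),
        list(atomRow("CA", "C", i, "PHE", p0 + c(0, 0, 8)))))
      ligRing <- hexagonRing(p0 + c(0, 0, 4.5))
      poseRows[[length(poseRows) + 1]] <- do.call(rbind, lapply(
        seq_len(6), function(a)
          ligRow(sprintf("C%d%d", i, a), "C", ligRing[a, ], ring = i)))
    } else if (type == "ionic") {
      protRows[[length(protRows) + 1]] <-
        rbind(atomRow("OD1", "O", i, "ASP", p0),
              atomRow("CA", "C", i, "ASP", p0 + c(0, 0, 6)))
      poseRows[[length(poseRows) + 1]] <-
        ligRow(sprintf("N%d", i), "N", p0 + c(3.6, 0, 0), charge = 1)
    }
    mapRows[[length(mapRows) + 1]] <-
      data.frame(structure_id = sid, chain = "A", resno = i, icode = "",
                 klifs_label = pb$position[i], stringsAsFactors = FALSE)
  }
  # anchor residue far from everything so the protein is never empty and
  # carries no contacts
  protRows[[length(protRows) + 1]] <-
    atomRow("CA", "C", 800L, "GLY", c(0, 120, 0))
  pose <- if (length(poseRows)) do.call(rbind, poseRows) else emptyAtomTable()
  withSeed(spec$seed, {
    if (spec$nDecoys > 0) {
      decoys <- do.call(rbind, lapply(seq_len(spec$nDecoys), function(d)
        ligRow(sprintf("D%d", d), "C",
               c(-10 - runif(1, 0, 90), runif(1, -20, 20),
                 runif(1, -20, 20)))))
      pose <- rbind(pose, decoys)
    }
    protein <- StructureRecord(sid, do.call(rbind, protRows))
    map <- if (length(mapRows)) do.call(rbind, mapRows) else
      data.frame(structure_id = character(), chain = character(),
                 resno = integer(), icode = character(),
                 klifs_label = character(), stringsAsFactors = FALSE)
    planted <- if (nrow(pb)) sort(paste(pb$position, pb$type, sep = "|"))
      else character()
    # emission-time feasibility check: decoys must violate every criterion
    if (spec$nDecoys > 0) {
      pm <- as.matrix(proteinAtoms(protein)[, c("x", "y", "z")])
      dm <- distMat(as.matrix(pose[grepl("^D", pose$elety),
                                   c("x", "y", "z")]), pm)
      if (min(dm) < 5.5 + 0.3)
        stopf("infeasible geometry request: decoy atom within criteria margin")
    }
    list(protein = protein, pose = pose, map = map, planted = planted,
         spec = spec)
  })
}

#' Write synthetic screen tables and truth sidecar
#'
#' Scores as CSV in the wide component format; ground truth as a YAML
#' sidecar.  Every file header states the score convention.
#'
#' @param screens list returned by [genScreenTable()].
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
writeScreenFixture <- function(screens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("kinaseA", "kinaseB")) {
    p <- file.path(dir, paste0("scores_", nm, ".csv"))
    con <- file(p, "w")
    writeLines("# docking score table; lower = better for all components", con)
    write.table(screenData(screens[[nm]]), con, sep = ",", quote = FALSE,
                row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(spec = unclass(screens$spec),
                        n_tagged = sum(screens$truth$tagged),
                        labels = setNames(as.list(screens$truth$label),
                                          screens$truth$ligand_id)), tp)
  invisible(c(paths, tp))
}
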