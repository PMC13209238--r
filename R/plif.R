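# Geometric protein-ligand interaction fingerprints on canonical kinase
# binding-site positions, hinge-motif detection, active/inactive bit
# enrichment, and cross-conformer pose consistency.

## canonical 85-position vocabulary ------------------------------------------

klifsRegions <- list(
  "I" = 1:3, "g.l" = 4:9, "II" = 10:13, "III" = 14:19, "aC" = 20:30,
  "b.l" = 31:37, "IV" = 38:41, "V" = 42:44, "GK" = 45, "hinge" = 46:48,
  "linker" = 49:52, "aD" = 53:59, "aE" = 60:64, "VI" = 65:67, "c.l" = 68:75,
  "VII" = 76:78, "VIII" = 79, "xDFG" = 80:82, "a.l" = 83:85)

#' Canonical kinase binding-site position labels
#'
#' The 85-position vocabulary for the ATP-site residues shared by all protein
#' kinases, labelled `<region>.<position>` (e.g. `hinge.46`, `GK.45`,
#' `aD.55`), with region spans I.1-3, g.l.4-9, II.10-13, III.14-19, aC.20-30,
#' b.l.31-37, IV.38-41, V.42-44, GK.45, hinge.46-48, linker.49-52, aD.53-59,
#' aE.60-64, VI.65-67, c.l.68-75, VII.76-78, VIII.79, xDFG.80-82, a.l.83-85.
#'
#' @return Character vector of the 85 labels, ordered by position.
#' @export
klifsPositions <- function() {
  out <- unlist(lapply(names(klifsRegions), function(r)
    paste(r, klifsRegions[[r]], sep = ".")), use.names = FALSE)
  out[order(as.integer(sub("^.*\\.", "", out)))]
}

interactionTypes <- c("hbond.donor", "hbond.acceptor", "hydrophobic",
                      "aromatic", "ionic")

#' Geometric interaction criteria
#'
#' Default thresholds for the geometric fingerprint: hydrogen-bond
#' donor-acceptor heavy-atom distance <= 3.5 A (with a D-H...A angle >= 120
#' degrees required only when an explicit hydrogen is present), hydrophobic
#' C...C contact <= 4.5 A between apolar carbons, aromatic ring-centroid
#' distance <= 5.5 A, and opposite-charge heavy-atom distance <= 4.0 A.
#'
#' @param hbondDist,hbondAngleDeg,hydrophobicDist,aromaticDist,ionicDist
#'   threshold overrides (distances in angstroms, angle in degrees).
#' @return Named list of criteria.
#' @export
plifCriteria <- function(hbondDist = 3.5, hbondAngleDeg = 120,
                         hydrophobicDist = 4.5, aromaticDist = 5.5,
                         ionicDist = 4.0) {
  list(hbondDist = hbondDist, hbondAngleDeg = hbondAngleDeg,
       hydrophobicDist = hydrophobicDist, aromaticDist = aromaticDist,
       ionicDist = ionicDist)
}

## built-in protein atom typing ----------------------------------------------
# small residue-name/atom-name tables; no general perception engine

proteinTyping <- local({
  donors <- list(
    backbone = "N",
    SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
    ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"))
  acceptors <- list(
    backbone = c("O", "OXT"),
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
    SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
  positive <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  negative <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  rings <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  list(donors = donors, acceptors = acceptors, positive = positive,
       negative = negative, rings = rings)
})

matchTyping <- function(atoms, table) {
  hit <- atoms$elety %in% table$backbone
  side <- mapply(function(resid, elety) {
    !is.null(table[[resid]]) && elety %in% table[[resid]]
  }, atoms$resid, atoms$elety, USE.NAMES = FALSE)
  hit | side
}

# ligand typing: element plus supplied formal charge; charged atoms are typed
# ionic only (not reused as hydrogen-bond partners); ring atoms carry a ring id
ligandTyping <- function(pose) {
  el <- toupper(pose$elesy)
  charge <- pose$charge
  inRing <- !is.na(pose$ring)
  list(polar = el %in% c("N", "O") & charge == 0,
       apolarC = el == "C" & !inRing & charge == 0,
       positive = charge > 0, negative = charge < 0,
       hydrogen = el == "H")
}

distMat <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# D-H...A angle in degrees given donor D, hydrogen H, acceptor A rows
dhAngle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# hbond check between donor atoms (with optional explicit hydrogens hXyz from
# the donor's own molecule) and acceptor atoms; angle enforced only when a
# hydrogen sits within bonding distance of the donor.  Returns the full
# donor x acceptor logical matrix.
hbondPairs <- function(donXyz, accXyz, hXyz, criteria) {
  ok <- matrix(FALSE, nrow(donXyz), nrow(accXyz))
  if (!nrow(donXyz) || !nrow(accXyz)) return(ok)
  dm <- distMat(donXyz, accXyz)
  within <- dm <= criteria$hbondDist
  if (!any(within)) return(ok)
  hasH <- nrow(hXyz) > 0
  for (i in seq_len(nrow(donXyz))) {
    for (j in seq_len(ncol(dm))) {
      if (!within[i, j]) next
      if (hasH) {
        hd <- distMat(donXyz[i, , drop = FALSE], hXyz)
        bonded <- which(hd <= 1.25)
        if (length(bonded)) {
          ang <- vapply(bonded, function(k)
            dhAngle(donXyz[i, ], hXyz[k, ], accXyz[j, ]), numeric(1))
          if (max(ang) < criteria$hbondAngleDeg) next
        }
      }
      ok[i, j] <- TRUE
    }
  }
  ok
}

xyzOf <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

ringCentroids <- function(atoms, rings) {
  # protein: rings defined per residue by atom-name table
  keys <- residueKey(atoms$chain, atoms$resno, atoms$icode)
  out <- list()
  for (key in unique(keys)) {
    res <- atoms[keys == key, , drop = FALSE]
    def <- rings[[res$resid[1]]]
    if (is.null(def)) next
    ringAtoms <- res[res$elety %in% def, , drop = FALSE]
    if (nrow(ringAtoms) >= length(def) - 1 && nrow(ringAtoms) >= 5)
      out[[key]] <- colMeans(xyzOf(ringAtoms))
  }
  out
}

ligandRingCentroids <- function(pose) {
  ids <- unique(pose$ring[!is.na(pose$ring)])
  lapply(setNames(ids, ids), function(rid)
    colMeans(xyzOf(pose[!is.na(pose$ring) & pose$ring == rid, , drop = FALSE])))
}

#' Detect geometric protein-ligand interactions for one pose
#'
#' Sets the bit (position p, interaction type t) whenever at least one
#' ligand/protein atom pair satisfies the geometric criterion for t at the
#' residue mapped to p.  Interaction types (protein-side role):
#' `hbond.donor` (protein donor to a ligand N/O), `hbond.acceptor` (protein
#' acceptor from a ligand N/O), `hydrophobic` (apolar C...C), `aromatic`
#' (ring-centroid contact) and `ionic` (opposite formal charges).  Contacts at
#' residues absent from the position map are recorded under the sentinel label
#' `"unmapped"` with a warning, never dropped.
#'
#' @param pose ligand atom table (columns as in [emptyAtomTable()]; `charge`
#'   holds formal charges, `ring` an integer aromatic-ring id or NA).  Must be
#'   in the same frame as `protein`.
#' @param protein a [StructureRecord-class] (its protein atoms are used).
#' @param map position map data.frame with columns `structure_id`, `chain`,
#'   `resno`, `icode`, `klifs_label`.
#' @param criteria geometric thresholds from [plifCriteria()].
#' @param ligandId,conformerId identifiers stored in the fingerprint.
#' @return A [Fingerprint-class].
#' @export
detectInteractions <- function(pose, protein, map, criteria = plifCriteria(),
                               ligandId = "ligand", conformerId = "conformer") {
  pose <- normalizeAtomTable(pose)
  prot <- proteinAtoms(protein)
  sid <- structureId(protein)
  map <- map[map$structure_id == sid, , drop = FALSE]
  mapKeys <- residueKey(map$chain, map$resno, map$icode)
  labelOf <- function(keys) {
    idx <- match(keys, mapKeys)
    out <- map$klifs_label[idx]
    out[is.na(idx)] <- "unmapped"
    out
  }
  lt <- ligandTyping(pose)
  protHeavy <- prot[isHeavy(prot), , drop = FALSE]
  poseHeavy <- pose[!lt$hydrogen, , drop = FALSE]
  ltH <- ligandTyping(poseHeavy)
  hXyzLig <- xyzOf(pose[lt$hydrogen, , drop = FALSE])
  hXyzProt <- xyzOf(prot[!isHeavy(prot), , drop = FALSE])
  bits <- character()
  addBits <- function(resKeys, type) {
    labs <- unique(labelOf(resKeys))
    if ("unmapped" %in% labs)
      warnf("contact at unmapped residue(s) %s recorded under 'unmapped'",
            paste(unique(resKeys[labelOf(resKeys) == "unmapped"]),
                  collapse = ", "))
    paste(labs, type, sep = "|")
  }
  protKeys <- residueKey(protHeavy$chain, protHeavy$resno, protHeavy$icode)

  # hydrogen bonds: protein donor -> ligand polar acceptor
  don <- matchTyping(protHeavy, proteinTyping$donors)
  if (any(don) && any(ltH$polar)) {
    ok <- hbondPairs(xyzOf(protHeavy[don, , drop = FALSE]),
                     xyzOf(poseHeavy[ltH$polar, , drop = FALSE]),
                     hXyzProt, criteria)
    hit <- apply(ok, 1, any)
    if (any(hit))
      bits <- c(bits, addBits(protKeys[don][hit], "hbond.donor"))
  }
  # hydrogen bonds: ligand polar donor -> protein acceptor
  acc <- matchTyping(protHeavy, proteinTyping$acceptors)
  if (any(acc) && any(ltH$polar)) {
    ok <- hbondPairs(xyzOf(poseHeavy[ltH$polar, , drop = FALSE]),
                     xyzOf(protHeavy[acc, , drop = FALSE]),
                     hXyzLig, criteria)
    hit <- apply(ok, 2, any)   # protein acceptors reached by any ligand donor
    if (any(hit))
      bits <- c(bits, addBits(protKeys[acc][hit], "hbond.acceptor"))
  }
  # hydrophobic: apolar side-chain carbons vs apolar ligand carbons
  apolarProt <- toupper(protHeavy$elesy) == "C" &
    !(protHeavy$elety %in% c("C", "CA")) &
    !mapply(function(resid, elety) {
      def <- proteinTyping$rings[[resid]]
      !is.null(def) && elety %in% def
    }, protHeavy$resid, protHeavy$elety, USE.NAMES = FALSE)
  if (any(apolarProt) && any(ltH$apolarC)) {
    dm <- distMat(xyzOf(protHeavy[apolarProt, , drop = FALSE]),
                  xyzOf(poseHeavy[ltH$apolarC, , drop = FALSE]))
    hit <- apply(dm <= criteria$hydrophobicDist, 1, any)
    if (any(hit))
      bits <- c(bits, addBits(protKeys[apolarProt][hit], "hydrophobic"))
  }
  # aromatic: ring-centroid distance
  protRings <- ringCentroids(protHeavy, proteinTyping$rings)
  ligRings <- ligandRingCentroids(poseHeavy)
  if (length(protRings) && length(ligRings)) {
    pm <- do.call(rbind, protRings)
    lm <- do.call(rbind, ligRings)
    dm <- distMat(pm, lm)
    hit <- apply(dm <= criteria$aromaticDist, 1, any)
    if (any(hit))
      bits <- c(bits, addBits(names(protRings)[hit], "aromatic"))
  }
  # ionic: opposite formal charges within cutoff
  pos <- matchTyping(protHeavy, proteinTyping$positive)
  neg <- matchTyping(protHeavy, proteinTyping$negative)
  for (pair in list(list(p = pos, l = ltH$negative),
                    list(p = neg, l = ltH$positive))) {
    if (any(pair$p) && any(pair$l)) {
      dm <- distMat(xyzOf(protHeavy[pair$p, , drop = FALSE]),
                    xyzOf(poseHeavy[pair$l, , drop = FALSE]))
      hit <- apply(dm <= criteria$ionicDist, 1, any)
      if (any(hit))
        bits <- c(bits, addBits(protKeys[pair$p][hit], "ionic"))
    }
  }
  new("Fingerprint", ligandId = as.character(ligandId),
      conformerId = as.character(conformerId), bits = sort(unique(bits)))
}

#' Canonical hinge-binding motif
#'
#' TRUE when a hydrogen-bond-type bit (either protein-side role) is present
#' at both hinge.46 and hinge.48 — the two backbone hydrogen bonds anchoring
#' ATP-competitive inhibitors in the kinase hinge.
#'
#' @param fp a [Fingerprint-class].
#' @return Logical scalar.
#' @export
hingeMotif <- function(fp) {
  bits <- fingerprintBits(fp)
  has <- function(pos) any(grepl(paste0("^", pos, "\\|hbond\\."), bits))
  has("hinge.46") && has("hinge.48")
}

#' Interaction-bit enrichment between actives and inactives
#'
#' Per bit: frequency among active and inactive fingerprints, their
#' difference, a Fisher exact p-value on the 2x2 presence table and a
#' Benjamini-Hochberg adjusted q-value; rows sorted by decreasing
#' |difference|.
#'
#' @param fps list of [Fingerprint-class] objects (one per ligand).
#' @param labels activity labels aligned with `fps` ("active"/"inactive" or
#'   logical).
#' @return data.frame: `bit`, `n_active`, `n_inactive`, `freq_active`,
#'   `freq_inactive`, `difference`, `p`, `q`.
#' @export
bitEnrichment <- function(fps, labels) {
  act <- asActiveLogical(labels)
  if (length(act) != length(fps)) stopf("labels must align with fingerprints")
  checkTwoClasses(act)
  allBits <- sort(unique(unlist(lapply(fps, fingerprintBits))))
  if (!length(allBits)) stopf("no interaction bits present")
  inc <- vapply(fps, function(f) allBits %in% fingerprintBits(f),
                logical(length(allBits)))
  inc <- matrix(inc, nrow = length(allBits))
  na <- sum(act); ni <- sum(!act)
  ca <- rowSums(inc[, act, drop = FALSE])
  ci <- rowSums(inc[, !act, drop = FALSE])
  p <- vapply(seq_along(allBits), function(i)
    fisher.test(matrix(c(ca[i], na - ca[i], ci[i], ni - ci[i]), 2))$p.value,
    numeric(1))
  out <- data.frame(bit = allBits, n_active = ca, n_inactive = ci,
                    freq_active = ca / na, freq_inactive = ci / ni,
                    difference = ca / na - ci / ni, p = p,
                    q = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$difference), out$bit, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Cross-conformer docking pose consistency
#'
#' Mean over all pose pairs of the heavy-atom RMSD without re-fitting (poses
#' already share the common docking frame); a ligand is called stable when
#' the mean is below `threshold`.
#'
#' @param poses list of >= 2 ligand atom tables (or plain n x 3 coordinate
#'   matrices) with identical atom ordering.
#' @param threshold stability threshold in angstroms (default 2.0).
#' @return A list: `mean_rmsd`, `stable`, `n_pairs`.
#' @export
poseConsistency <- function(poses, threshold = 2.0) {
  if (length(poses) < 2) stopf("need at least 2 poses")
  mats <- lapply(poses, function(p) {
    if (is.matrix(p)) return(p)
    p <- normalizeAtomTable(p)
    xyzOf(p[isHeavy(p), , drop = FALSE])
  })
  counts <- vapply(mats, nrow, integer(1))
  if (length(unique(counts)) != 1)
    stopf("atom-count mismatch across poses: %s",
          paste(counts, collapse = ", "))
  pairs <- utils::combn(length(mats), 2)
  rmsds <- apply(pairs, 2, function(ij) coordRmsd(mats[[ij[1]]], mats[[ij[2]]]))
  list(mean_rmsd = mean(rmsds), stable = mean(rmsds) < threshold,
       n_pairs = ncol(pairs))
}

#' Read a position map from CSV
#'
#' CSV columns `structure_id, chain, resnum, icode, klifs_label` mapping
#' residues onto the canonical 85-position vocabulary.  Labels outside the
#' vocabulary or duplicated within a structure are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with columns `structure_id`, `chain`, `resno`, `icode`,
#'   `klifs_label`.
#' @export
readPositionMapCSV <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character")
  names(d)[names(d) == "resnum"] <- "resno"
  d$resno <- as.integer(d$resno)
  d$icode[is.na(d$icode)] <- ""
  validatePositionMap(d)
  d
}

validatePositionMap <- function(map) {
  bad <- setdiff(map$klifs_label, klifsPositions())
  if (length(bad))
    stopf("position label(s) outside the 85-position vocabulary: %s",
          paste(unique(bad), collapse = ", "))
  for (sid in unique(map$structure_id)) {
    sub <- map[map$structure_id == sid, ]
    if (anyDuplicated(sub$klifs_label) ||
        anyDuplicated(residueKey(sub$chain, sub$resno, sub$icode)))
      stopf("position map must be injective per structure ('%s')", sid)
  }
  invisible(map)
}

#' Write a fingerprint matrix as TSV
#'
#' Ligands x bits 0/1 matrix; rows ordered by activity (inactives first, then
#' actives) when labels are given, mirroring activity-sorted fingerprint
#' heatmaps.
#'
#' @param fps list of [Fingerprint-class] objects.
#' @param path output file path.
#' @param labels optional activity labels for row ordering.
#' @return `path`, invisibly.
#' @export
writeFingerprintTSV <- function(fps, path, labels = NULL) {
  allBits <- sort(unique(unlist(lapply(fps, fingerprintBits))))
  ids <- vapply(fps, function(f) f@ligandId, character(1))
  m <- t(vapply(fps, function(f) as.integer(allBits %in% fingerprintBits(f)),
                integer(length(allBits))))
  if (length(allBits) == 1) m <- matrix(m, ncol = 1)
  colnames(m) <- allBits
  ord <- if (!is.null(labels))
    order(asActiveLogical(labels), ids, method = "radix")
  else orderLex(ids)
  df <- data.frame(ligand_id = ids[ord],
                   label = if (!is.null(labels)) labels[ord] else NA,
                   m[ord, , drop = FALSE], check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
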