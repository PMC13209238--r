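# Structure handling: PDB input, binding-site definition, rigid-body
# superposition and binding-site RMSD matrices.  Heavy atoms only enter every
# distance computation; hydrogens are carried along but ignored.

# crystallographic components irrelevant for ligand binding, stripped on read
solventHetCodes <- c("HOH", "WAT", "DOD", "SO4", "PO4", "GOL", "EDO", "ACT",
                     "DMS", "PEG", "PG4", "MPD", "TRS", "EPE", "MES", "FMT",
                     "ACE", "NH4", "NO3", "CIT", "BME", "IPA", "IMD",
                     "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "BR", "IOD",
                     "CS", "NI", "CD", "CO", "CU", "LI")

elementFromName <- function(elety) {
  # PDB element inference when the element column is absent: strip digits,
  # recognise two-letter halogens/metals by the standard column convention
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA")
  out <- substr(nm, 1, 1)
  out[nm %in% two] <- nm[nm %in% two]
  # hydrogens named like 1HB2 -> HB2 after digit strip; names starting H
  out[substr(nm, 1, 1) == "H"] <- "H"
  out
}

#' Read a protein chain and its co-crystallized ligand from a PDB file
#'
#' Parses standard ATOM/HETATM records through bio3d, strips waters, buffer
#' molecules and ions, resolves alternate locations (highest occupancy, ties
#' to altloc "A") and splits the remaining atoms into protein and reference
#' ligand.  The ligand is either the configured HET code or, by default, the
#' largest organic HETATM group in the chain.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to isolate; default: first chain in the file.
#' @param ligandCode optional HET code of the reference ligand; when `NULL`
#'   the largest organic hetero group (most heavy atoms) is used.
#' @param structureId identifier for the resulting record; default
#'   `"<file stem>_<chain>"`.
#' @return A [StructureRecord-class].
#' @export
readStructurePDB <- function(path, chain = NULL, ligandCode = NULL,
                             structureId = NULL) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stopf("chain '%s' not found in %s", chain, path)
  # alternate locations: keep highest occupancy, tie -> altloc "A"
  if (!is.null(at$alt)) {
    alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
    keep <- unsplit(lapply(split(seq_along(key), key), function(idx) {
      if (length(idx) == 1L) return(TRUE)
      o <- occ[idx]
      best <- idx[o == max(o)]
      if (length(best) > 1L) {
        a <- alt[best]
        best <- if ("A" %in% a) best[a == "A"][1] else best[order(a)][1]
      }
      idx %in% best
    }), key)
    at <- at[keep, , drop = FALSE]
  }
  elesy <- if (!is.null(at$elesy) && any(nzchar(at$elesy) & !is.na(at$elesy)))
    ifelse(is.na(at$elesy) | at$elesy == "", elementFromName(at$elety),
           toupper(at$elesy))
  else elementFromName(at$elety)
  tab <- data.frame(elety = at$elety, elesy = elesy, chain = at$chain,
                    resno = at$resno,
                    icode = ifelse(is.na(at$insert) | at$insert == " ", "",
                                   at$insert),
                    resid = at$resid, x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  het <- at$type == "HETATM"
  strip <- het & (tab$resid %in% solventHetCodes)
  tab <- tab[!strip, , drop = FALSE]
  het <- het[!strip]
  prot <- tab[!het, , drop = FALSE]
  lig <- tab[het, , drop = FALSE]
  ligId <- ""
  if (nrow(lig)) {
    grp <- paste(lig$resid, lig$chain, lig$resno, sep = "\r")
    if (!is.null(ligandCode)) {
      sel <- lig$resid == ligandCode
      if (!any(sel)) stopf("ligand code '%s' not found in chain %s",
                           ligandCode, chain)
      lig <- lig[sel, , drop = FALSE]
    } else {
      heavyCount <- tapply(isHeavy(lig), grp, sum)
      best <- names(heavyCount)[order(-heavyCount, names(heavyCount))][1]
      lig <- lig[grp == best, , drop = FALSE]
    }
    ligId <- lig$resid[1]
  }
  if (is.null(structureId))
    structureId <- paste0(tools::file_path_sans_ext(basename(path)), "_", chain)
  StructureRecord(structureId, prot, lig, ligId)
}

#' Write a StructureRecord to a PDB file
#'
#' Protein atoms are emitted as ATOM records, ligand atoms as HETATM.
#'
#' @param structure a [StructureRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  p <- proteinAtoms(structure)
  l <- ligandAtoms(structure)
  all <- rbind(p, l)
  bio3d::write.pdb(file = path,
                   type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
                   xyz = as.vector(t(as.matrix(all[, c("x", "y", "z")]))),
                   resno = all$resno, resid = all$resid, chain = all$chain,
                   insert = ifelse(all$icode == "", "", all$icode),
                   elety = all$elety, elesy = all$elesy)
  invisible(path)
}

#' Define the binding site around the co-crystallized ligand
#'
#' Returns exactly the residues having at least one heavy atom at distance
#' `cutoff` or less from any heavy atom of the reference ligand.
#'
#' @param structure a [StructureRecord-class] with a non-empty ligand.
#' @param cutoff distance cutoff in angstroms (default 5.0).
#' @return A [BindingSite-class].
#' @export
extractBindingSite <- function(structure, cutoff = 5.0) {
  lig <- ligandAtoms(structure)
  lig <- lig[isHeavy(lig), , drop = FALSE]
  if (!nrow(lig)) stopf("no reference ligand: structure '%s' has no ligand heavy atoms",
                        structureId(structure))
  prot <- proteinAtoms(structure)
  prot <- prot[isHeavy(prot), , drop = FALSE]
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig[, c("x", "y", "z")])
  # min distance of each protein heavy atom to any ligand heavy atom
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  keys <- residueKey(prot$chain, prot$resno, prot$icode)
  members <- sort(unique(keys[mind <= cutoff]))
  new("BindingSite", structureId = structureId(structure),
      residues = members, cutoff = cutoff)
}

# Kabsch least-squares rigid superposition of paired coordinate sets.
# Returns rotation R (det +1) and translation t mapping mobile -> reference
# as  x %*% t(R) + t  on row-vector coordinates.
kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cr - as.vector(R %*% cm)
  list(R = R, t = t)
}

applyTransform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$R), 2, tr$t, "+")
}

pairSiteAtoms <- function(reference, mobile, site = NULL) {
  atomsOf <- function(s) {
    a <- proteinAtoms(s)
    a <- a[isHeavy(a), , drop = FALSE]
    if (!is.null(site))
      a <- a[residueKey(a$chain, a$resno, a$icode) %in% site, , drop = FALSE]
    a
  }
  ra <- atomsOf(reference); ma <- atomsOf(mobile)
  rk <- paste(residueKey(ra$chain, ra$resno, ra$icode), ra$elety)
  mk <- paste(residueKey(ma$chain, ma$resno, ma$icode), ma$elety)
  common <- intersect(rk, mk)
  list(ref = as.matrix(ra[match(common, rk), c("x", "y", "z")]),
       mob = as.matrix(ma[match(common, mk), c("x", "y", "z")]),
       n = length(common))
}

#' Rigid-body superposition of one structure onto another
#'
#' Least-squares (Kabsch) fit over a paired atom selection; the fitted rigid
#' transform (rotation with determinant +1, plus translation) is applied to
#' all atoms of the mobile structure, protein and ligand alike.
#'
#' @param reference,mobile [StructureRecord-class] objects.
#' @param pairs optional list with numeric matrices `ref` and `mob`
#'   (n x 3 paired coordinates).  When `NULL`, atoms are paired by
#'   (residue key, atom name) over heavy atoms, restricted to `site`.
#' @param site optional character vector of residue keys restricting the fit.
#' @return A list: `structure` (transformed mobile), `rmsd` (fit RMSD in
#'   angstroms), `transform` (list with `R`, `t`), `nAtoms` (pairs fitted).
#' @export
superpose <- function(reference, mobile, pairs = NULL, site = NULL) {
  if (is.null(pairs)) {
    p <- pairSiteAtoms(reference, mobile, site)
    refXyz <- p$ref; mobXyz <- p$mob
  } else {
    refXyz <- as.matrix(pairs$ref); mobXyz <- as.matrix(pairs$mob)
  }
  n <- nrow(refXyz)
  if (is.null(n) || n < 3 || nrow(mobXyz) != n)
    stopf("degenerate superposition: need >= 3 paired atoms, got %d",
          if (is.null(n)) 0L else n)
  # collinearity check: centered mobile points must span a plane
  sv <- svd(sweep(mobXyz, 2, colMeans(mobXyz)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stopf("degenerate superposition: paired atoms are collinear")
  tr <- kabsch(mobXyz, refXyz)
  fitted <- applyTransform(mobXyz, tr)
  rmsd <- coordRmsd(fitted, refXyz)
  prot <- proteinAtoms(mobile); lig <- ligandAtoms(mobile)
  prot[, c("x", "y", "z")] <- applyTransform(
    as.matrix(prot[, c("x", "y", "z")]), tr)
  if (nrow(lig))
    lig[, c("x", "y", "z")] <- applyTransform(
      as.matrix(lig[, c("x", "y", "z")]), tr)
  out <- StructureRecord(structureId(mobile), prot, lig, mobile@ligandId)
  list(structure = out, rmsd = rmsd, transform = tr, nAtoms = n)
}

#' Consensus binding site over an ensemble
#'
#' Union of the per-structure binding-site residue sets at the given cutoff.
#' Structures without a ligand are skipped (they cannot define a site).
#'
#' @param structures list of [StructureRecord-class] objects.
#' @param cutoff site cutoff in angstroms.
#' @return Sorted character vector of residue keys.
#' @export
consensusSite <- function(structures, cutoff = 5.0) {
  sets <- lapply(structures, function(s) {
    lig <- ligandAtoms(s)
    if (!nrow(lig) || !any(isHeavy(lig))) return(character())
    siteResidues(extractBindingSite(s, cutoff))
  })
  out <- sort(unique(unlist(sets)))
  if (!length(out)) stopf("no structure in the ensemble defines a binding site")
  out
}

#' Superpose an ensemble onto a common reference
#'
#' The reference is the structure with the most resolved heavy atoms within
#' the consensus site; every other structure is Kabsch-fitted onto it over the
#' shared site atoms.  All downstream pairwise RMSDs are then computed in this
#' single frame without per-pair re-fitting.
#'
#' @param structures list of [StructureRecord-class] objects.
#' @param cutoff site cutoff in angstroms.
#' @return A list: `structures` (aligned, same order), `site` (consensus
#'   residue keys), `referenceId`, `fitRmsd` (named numeric).
#' @export
alignEnsemble <- function(structures, cutoff = 5.0) {
  ids <- vapply(structures, structureId, character(1))
  if (anyDuplicated(ids)) stopf("duplicate structure ids in ensemble")
  site <- consensusSite(structures, cutoff)
  nSite <- vapply(structures, function(s) {
    a <- proteinAtoms(s)
    a <- a[isHeavy(a), , drop = FALSE]
    sum(residueKey(a$chain, a$resno, a$icode) %in% site)
  }, integer(1))
  refIdx <- which(nSite == max(nSite))
  refIdx <- refIdx[orderLex(ids[refIdx])[1]]  # tie -> lexicographic id
  ref <- structures[[refIdx]]
  fit <- setNames(numeric(length(structures)), ids)
  aligned <- structures
  for (i in seq_along(structures)) {
    if (i == refIdx) next
    sp <- superpose(ref, structures[[i]], site = site)
    aligned[[i]] <- sp$structure
    fit[i] <- sp$rmsd
  }
  list(structures = aligned, site = site, referenceId = ids[refIdx],
       fitRmsd = fit)
}

#' Pairwise binding-site RMSD matrix
#'
#' Entry (i, j) is the RMSD over the consensus-site heavy atoms resolved in
#' both structures, computed in the common frame without re-fitting.
#' Structures must already be superposed (see [alignEnsemble()]).
#'
#' @param structures list of aligned [StructureRecord-class] objects.
#' @param site character vector of consensus residue keys.
#' @return A [DistanceMatrix-class].
#' @export
pairwiseRmsdMatrix <- function(structures, site) {
  ids <- vapply(structures, structureId, character(1))
  atoms <- lapply(structures, function(s) {
    a <- proteinAtoms(s)
    a <- a[isHeavy(a), , drop = FALSE]
    a <- a[residueKey(a$chain, a$resno, a$icode) %in% site, , drop = FALSE]
    key <- paste(residueKey(a$chain, a$resno, a$icode), a$elety)
    list(key = key, xyz = as.matrix(a[, c("x", "y", "z")]))
  })
  n <- length(structures)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      common <- intersect(atoms[[i]]$key, atoms[[j]]$key)
      if (!length(common))
        stopf("no common site heavy atoms between '%s' and '%s'",
              ids[i], ids[j])
      xi <- atoms[[i]]$xyz[match(common, atoms[[i]]$key), , drop = FALSE]
      xj <- atoms[[j]]$xyz[match(common, atoms[[j]]$key), , drop = FALSE]
      m[i, j] <- m[j, i] <- coordRmsd(xi, xj)
    }
  }
  DistanceMatrix(m)
}

#' Write / read a distance matrix as TSV
#'
#' Tab-separated matrix with structure ids as header row and first column.
#'
#' @param D a [DistanceMatrix-class].
#' @param path file path.
#' @return `path` (write) or a [DistanceMatrix-class] (read).
#' @export
writeDistanceMatrixTSV <- function(D, path) {
  v <- dmValues(D)
  df <- data.frame(structure_id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrixTSV
#' @export
readDistanceMatrixTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df[[1]], colnames(df)[-1])
  DistanceMatrix(m)
}

#' Export binding-site definitions as JSON
#'
#' @param sites list of [BindingSite-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBindingSitesJSON <- function(sites, path) {
  out <- lapply(sites, function(s)
    list(structure_id = structureId(s), cutoff_A = s@cutoff,
         residues = siteResidues(s)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
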