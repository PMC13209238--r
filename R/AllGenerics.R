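#' Accessors for kindock classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `structureId()`, `proteinAtoms()`, `ligandAtoms()`, `siteResidues()`,
#' `dmValues()`, `dmLabels()`, `assignments()`, `nClusters()`,
#' `representatives()`, `screenData()`, `rankValues()`, `hitTable()`,
#' `fingerprintBits()`.
#'
#' @param object a kindock S4 object.
#' @return The underlying slot value (vector, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("proteinAtoms", function(object) standardGeneric("proteinAtoms"))
#' @rdname accessors
#' @export
setGeneric("ligandAtoms", function(object) standardGeneric("ligandAtoms"))
#' @rdname accessors
#' @export
setGeneric("siteResidues", function(object) standardGeneric("siteResidues"))
#' @rdname accessors
#' @export
setGeneric("dmValues", function(object) standardGeneric("dmValues"))
#' @rdname accessors
#' @export
setGeneric("dmLabels", function(object) standardGeneric("dmLabels"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(object) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("screenData", function(object) standardGeneric("screenData"))
#' @rdname accessors
#' @export
setGeneric("rankValues", function(object) standardGeneric("rankValues"))
#' @rdname accessors
#' @export
setGeneric("hitTable", function(object) standardGeneric("hitTable"))
#' @rdname accessors
#' @export
setGeneric("fingerprintBits", function(object) standardGeneric("fingerprintBits"))

#' @rdname accessors
setMethod("structureId", "StructureRecord", function(object) object@structureId)
#' @rdname accessors
setMethod("proteinAtoms", "StructureRecord", function(object) object@protein)
#' @rdname accessors
setMethod("ligandAtoms", "StructureRecord", function(object) object@ligand)
#' @rdname accessors
setMethod("structureId", "BindingSite", function(object) object@structureId)
#' @rdname accessors
setMethod("siteResidues", "BindingSite", function(object) object@residues)
#' @rdname accessors
setMethod("dmValues", "DistanceMatrix", function(object) object@values)
#' @rdname accessors
setMethod("dmLabels", "DistanceMatrix", function(object) rownames(object@values))
#' @rdname accessors
setMethod("assignments", "ClusterModel", function(object) object@assignments)
#' @rdname accessors
setMethod("nClusters", "ClusterModel", function(object) object@k)
#' @rdname accessors
setMethod("representatives", "RepresentativeSet", function(object) object@reps)
#' @rdname accessors
setMethod("screenData", "ScreenTable", function(object) object@data)
#' @rdname accessors
setMethod("rankValues", "RankTable", function(object) object@ranks)
#' @rdname accessors
setMethod("hitTable", "HitList", function(object) object@hits)
#' @rdname accessors
setMethod("fingerprintBits", "Fingerprint", function(object) object@bits)

## show methods ---------------------------------------------------------------

setMethod("show", "StructureRecord", function(object) {
  cat(sprintf("StructureRecord '%s': %d protein atoms, %d ligand atoms (%s)\n",
              object@structureId, nrow(object@protein), nrow(object@ligand),
              if (nzchar(object@ligandId)) object@ligandId else "no ligand"))
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf("BindingSite for '%s': %d residues within %.1f A of the ligand\n",
              object@structureId, length(object@residues), object@cutoff))
})

setMethod("show", "DistanceMatrix", function(object) {
  v <- object@values
  cat(sprintf("DistanceMatrix: %d structures, RMSD range [%.3f, %.3f] A\n",
              nrow(v), if (nrow(v) > 1) min(v[upper.tri(v)]) else 0,
              if (nrow(v) > 1) max(v) else 0))
})

setMethod("show", "ClusterModel", function(object) {
  sizes <- table(object@assignments)
  cat(sprintf("ClusterModel: %d structures in %d clusters (sizes %s)\n",
              length(object@labels), object@k,
              paste(as.integer(sizes), collapse = ", ")))
})

setMethod("show", "RepresentativeSet", function(object) {
  cat(sprintf("RepresentativeSet: %d representatives over %d clusters\n",
              nrow(object@reps), length(unique(object@reps$cluster))))
  print(object@reps, row.names = FALSE)
})

setMethod("show", "ScreenTable", function(object) {
  d <- object@data
  cat(sprintf(
    "ScreenTable: %d rows | %d ligands x %d conformers x %d kinase(s)\n",
    nrow(d), length(unique(d$ligand_id)), length(unique(d$conformer_id)),
    length(unique(d$kinase_id))))
  comps <- setdiff(names(d)[vapply(d, is.numeric, logical(1))], NULL)
  cat("  components:", paste(comps, collapse = ", "), "(lower = better)\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s / %s]: AUC %.3f, eROCE %.3f, EF1%% %.2f (%d/%d actives)\n",
              object@conformerId, object@component, object@auc, object@eroce,
              if ("0.01" %in% names(object@ef)) object@ef[["0.01"]] else NA,
              object@nActives, object@nLigands))
})

setMethod("show", "RankTable", function(object) {
  cat(sprintf("RankTable [%s]: %d ligands, consensus '%s' over %d conformer(s)\n",
              object@kinaseId, length(object@ranks), object@consensus,
              length(object@conformers)))
})

setMethod("show", "HitList", function(object) {
  p <- object@provenance
  cat(sprintf("HitList: %d hits (top %.1f%%, rr <= %g, |rr| >= %g)\n",
              nrow(object@hits), 100 * p$top_fraction, p$rr_cutoff,
              p$separation_margin))
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint [%s/%s]: %d bits\n", object@ligandId,
              object@conformerId, length(object@bits)))
  if (length(object@bits)) cat(" ", paste(object@bits, collapse = " "), "\n")
})
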