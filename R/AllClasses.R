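# Central S4 data types. Atom tables are plain data.frames with columns
#   elety (atom name), elesy (element symbol), chain, resno, icode, resid,
#   x, y, z  and, for ligand atoms, optionally charge (formal) and ring
#   (integer ring id). Heaviness is derived from the element (element != "H").

atomTableColumns <- c("elety", "elesy", "chain", "resno", "icode", "resid",
                      "x", "y", "z")

#' Create an empty atom table
#'
#' Returns a zero-row data.frame with the atom-table columns used throughout
#' the package (`elety`, `elesy`, `chain`, `resno`, `icode`, `resid`,
#' `x`, `y`, `z`, `charge`, `ring`).
#'
#' @return A zero-row data.frame.
#' @export
emptyAtomTable <- function() {
  data.frame(elety = character(), elesy = character(), chain = character(),
             resno = integer(), icode = character(), resid = character(),
             x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), ring = integer(),
             stringsAsFactors = FALSE)
}

normalizeAtomTable <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(emptyAtomTable())
  miss <- setdiff(atomTableColumns, names(df))
  if (length(miss))
    stopf("atom table missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(df$charge)) df$charge <- 0
  if (is.null(df$ring)) df$ring <- NA_integer_
  df$icode[is.na(df$icode) | df$icode == " "] <- ""
  df$charge[is.na(df$charge)] <- 0
  rownames(df) <- NULL
  df[, c(atomTableColumns, "charge", "ring")]
}

isHeavy <- function(atoms) toupper(atoms$elesy) != "H"

validAtomTable <- function(df, what) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) && !all(is.finite(xyz)))
    return(sprintf("%s coordinates must be finite", what))
  TRUE
}

## ---------------------------------------------------------------- structures

#' StructureRecord: one protein chain plus its co-crystallized ligand
#'
#' Holds the heavy-atom coordinates of one protein monomer (typically a kinase
#' catalytic domain isolated from a crystal structure) together with the atoms
#' of its reference ligand.  The ligand may be empty when the structure is used
#' only as a docking target, never for binding-site definition.
#'
#' @slot structureId single string identifying the monomer (e.g. PDB id + chain).
#' @slot protein atom table of protein atoms.
#' @slot ligand atom table of the co-crystallized ligand (possibly empty).
#' @slot ligandId HET code or name of the ligand ("" when absent).
#' @export
setClass("StructureRecord",
  representation(structureId = "character", protein = "data.frame",
                 ligand = "data.frame", ligandId = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@structureId) != 1L || !nzchar(object@structureId))
      msgs <- c(msgs, "structureId must be a single non-empty string")
    if (nrow(object@protein) < 1L)
      msgs <- c(msgs, "at least one protein atom is required")
    v <- validAtomTable(object@protein, "protein")
    if (!isTRUE(v)) msgs <- c(msgs, v)
    v <- validAtomTable(object@ligand, "ligand")
    if (!isTRUE(v)) msgs <- c(msgs, v)
    if (length(msgs)) msgs else TRUE
  })

#' Construct a StructureRecord
#'
#' @param structureId structure identifier.
#' @param protein protein atom table (see [emptyAtomTable()] for columns).
#' @param ligand ligand atom table; may be empty.
#' @param ligandId ligand identifier.
#' @return A [StructureRecord-class] object.
#' @export
StructureRecord <- function(structureId, protein, ligand = emptyAtomTable(),
                            ligandId = "") {
  new("StructureRecord", structureId = as.character(structureId),
      protein = normalizeAtomTable(protein),
      ligand = normalizeAtomTable(ligand),
      ligandId = as.character(ligandId))
}

#' BindingSite: residues lining a ligand pocket
#'
#' The set of residues having at least one heavy atom within `cutoff`
#' angstroms of any heavy atom of the co-crystallized ligand.
#'
#' @slot structureId structure the site was derived from.
#' @slot residues character vector of residue keys ("chain:resno:icode").
#' @slot cutoff distance cutoff in angstroms.
#' @export
setClass("BindingSite",
  representation(structureId = "character", residues = "character",
                 cutoff = "numeric"),
  validity = function(object) {
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
        object@cutoff <= 0)
      return("cutoff must be a single positive number")
    if (anyDuplicated(object@residues))
      return("residues must be unique")
    TRUE
  })

#' DistanceMatrix: pairwise binding-site RMSD in angstroms
#'
#' Symmetric matrix of heavy-atom RMSD values with a zero diagonal, labelled
#' by structure id.
#'
#' @slot values symmetric numeric matrix with dimnames.
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
      return("matrix must carry identical row and column labels")
    if (anyDuplicated(rownames(v))) return("labels must be unique")
    if (!all(is.finite(v))) return("entries must be finite")
    if (any(v < 0)) return("entries must be non-negative")
    if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
    if (max(abs(diag(v))) > 1e-8) return("diagonal must be zero")
    TRUE
  })

#' Construct a DistanceMatrix
#'
#' @param values square symmetric numeric matrix; dimnames are the structure
#'   ids (set from `labels` if given).
#' @param labels optional character vector of structure ids.
#' @return A [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  # symmetrize away numerical fuzz before validity
  values <- (values + t(values)) / 2
  diag(values) <- 0
  new("DistanceMatrix", values = values)
}

## ------------------------------------------------------------------ ensemble

#' ClusterModel: complete-linkage partition of an ensemble
#'
#' @slot labels ordered structure ids (matrix order).
#' @slot assignments named integer vector, structure id -> cluster index.
#' @slot k number of clusters.
#' @slot tree the agglomeration tree (an `hclust` object stored as a list).
#' @export
setClass("ClusterModel",
  representation(labels = "character", assignments = "integer",
                 k = "integer", tree = "list"),
  validity = function(object) {
    if (!setequal(names(object@assignments), object@labels))
      return("assignments must cover exactly the labels")
    if (length(unique(object@assignments)) != object@k)
      return("assignments must use exactly k clusters")
    h <- object@tree$height
    if (length(h) > 1 && any(diff(h) < -1e-8))
      return("merge heights must be non-decreasing")
    TRUE
  })

#' RepresentativeSet: annotated cluster representatives
#'
#' @slot reps data.frame with columns `cluster`, `structure_id`, `rank`
#'   (selection order within the cluster, 1 = primary), `annotation`
#'   (one of "medoid", "maxmin", "lbi-replacement") and `flagged`
#'   (TRUE when a failing representative had no passing replacement).
#' @slot params snapshot of the selection parameters.
#' @export
setClass("RepresentativeSet",
  representation(reps = "data.frame", params = "list"),
  validity = function(object) {
    r <- object@reps
    need <- c("cluster", "structure_id", "rank", "annotation", "flagged")
    if (!all(need %in% names(r)))
      return(sprintf("reps must have columns %s", paste(need, collapse = ", ")))
    if (!all(r$annotation %in% c("medoid", "maxmin", "lbi-replacement")))
      return("unknown annotation value")
    counts <- table(r$cluster)
    if (length(counts) && (min(counts) < 1 || max(counts) > 3))
      return("each cluster must have 1-3 representatives")
    first <- r$annotation[r$rank == 1]
    if (!all(first %in% c("medoid", "lbi-replacement")))
      return("primary representative must be medoid or lbi-replacement")
    TRUE
  })

## ----------------------------------------------------------------- screening

#' ScreenTable: best-pose docking scores joined with activity labels
#'
#' Long-format docking results with one best-pose row per
#' (ligand, conformer, kinase) and score components as columns.  All score
#' components follow the docking convention: lower = better.
#'
#' @slot data data.frame with columns `ligand_id`, `conformer_id`,
#'   `kinase_id`, `total` (always present), further numeric component columns
#'   (e.g. `vdw`, `elec`) and optionally `label`
#'   ("active"/"inactive"/"unknown").
#' @export
setClass("ScreenTable",
  representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("ligand_id", "conformer_id", "kinase_id", "total")
    miss <- setdiff(need, names(d))
    if (length(miss))
      return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (!is.numeric(d$total)) return("'total' must be numeric")
    key <- paste(d$ligand_id, d$conformer_id, d$kinase_id, sep = "\r")
    if (anyDuplicated(key))
      return("one best-pose row per (ligand, conformer, kinase) required")
    if ("label" %in% names(d) &&
        !all(d$label %in% c("active", "inactive", "unknown")))
      return("label must be active/inactive/unknown")
    TRUE
  })

#' Construct a ScreenTable
#'
#' @param data data.frame of best-pose rows (see [ScreenTable-class]).
#' @return A [ScreenTable-class] object.
#' @export
ScreenTable <- function(data) {
  data <- as.data.frame(data)
  rownames(data) <- NULL
  new("ScreenTable", data = data)
}

#' MetricsReport: screening performance of one conformer/component
#'
#' @slot conformerId conformer the metrics refer to.
#' @slot component score component used for ranking (e.g. "total", "vdw").
#' @slot auc area under the ROC curve.
#' @slot eroce exponential ROC enrichment.
#' @slot ef named numeric vector of enrichment factors, names = fractions.
#' @slot cutoffs data.frame of confusion-matrix metrics per top-ranked
#'   fraction: `fraction`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @slot nActives,nLigands class sizes underlying the metrics.
#' @export
setClass("MetricsReport",
  representation(conformerId = "character", component = "character",
                 auc = "numeric", eroce = "numeric", ef = "numeric",
                 cutoffs = "data.frame", nActives = "integer",
                 nLigands = "integer"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    if (object@eroce <= 0 || object@eroce > 1 + 1e-12)
      return("eroce must lie in (0, 1]")
    cc <- object@cutoffs
    if (nrow(cc)) {
      if (any(cc$tp + cc$fn != object@nActives))
        return("tp + fn must equal the number of actives at every cutoff")
      if (any(cc$tp + cc$fp != ceiling(cc$fraction * object@nLigands)))
        return("top-set size must equal ceiling(fraction * N)")
    }
    if (length(object@ef) &&
        any(object@ef > 1 / as.numeric(names(object@ef)) + 1e-9))
      return("EF(f) cannot exceed 1/f")
    TRUE
  })

## ---------------------------------------------------------------- selectivity

#' RankTable: normalized docking ranks for one kinase
#'
#' Normalized rank = rank position / ligand count with midranks for ties;
#' lower = better.  When several conformers are consolidated the value is the
#' consensus (mean or best) of the per-conformer normalized ranks, still in
#' (0, 1].
#'
#' @slot kinaseId kinase the ranks refer to.
#' @slot conformers conformer ids that entered the consensus.
#' @slot consensus consensus rule used ("mean" or "best").
#' @slot ranks named numeric vector, ligand id -> normalized rank in (0, 1].
#' @export
setClass("RankTable",
  representation(kinaseId = "character", conformers = "character",
                 consensus = "character", ranks = "numeric"),
  validity = function(object) {
    r <- object@ranks
    if (is.null(names(r))) return("ranks must be named by ligand id")
    if (length(r) && (min(r) <= 0 || max(r) > 1 + 1e-12))
      return("normalized ranks must lie in (0, 1]")
    TRUE
  })

#' HitList: prioritized selective candidates with filter provenance
#'
#' @slot hits data.frame with columns `ligand_id`, `r_a`, `r_b`, `rr` and any
#'   joined drug-likeness flag columns, ordered by `rr` ascending then
#'   kinase-A rank.
#' @slot provenance list recording the filters applied (top fraction, rr
#'   cutoff, separation margin, consensus rule, library size, retained counts).
#' @export
setClass("HitList",
  representation(hits = "data.frame", provenance = "list"),
  validity = function(object) {
    need <- c("ligand_id", "r_a", "r_b", "rr")
    if (!all(need %in% names(object@hits)))
      return(sprintf("hits must have columns %s", paste(need, collapse = ", ")))
    TRUE
  })

## ---------------------------------------------------------------------- plif

#' Fingerprint: geometric protein-ligand interaction bits for one pose
#'
#' A bit is the pair (canonical position label, interaction type); types are
#' `hbond.donor` / `hbond.acceptor` (the protein-side role), `hydrophobic`,
#' `aromatic` and `ionic`.  Bits are stored as sorted strings
#' `"<position>|<type>"`.
#'
#' @slot ligandId,conformerId identity of the pose.
#' @slot bits sorted character vector of present bits.
#' @export
setClass("Fingerprint",
  representation(ligandId = "character", conformerId = "character",
                 bits = "character"),
  validity = function(object) {
    if (anyDuplicated(object@bits)) return("bits must be unique")
    bad <- !grepl("^[^|]+\\|(hbond\\.donor|hbond\\.acceptor|hydrophobic|aromatic|ionic)$",
                  object@bits)
    if (any(bad))
      return(sprintf("malformed bit(s): %s",
                     paste(object@bits[bad], collapse = ", ")))
    TRUE
  })
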