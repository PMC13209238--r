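# Screening-performance evaluation.  Scores follow the docking convention
# (lower = better) throughout.  Ties use the midrank convention everywhere.

#' Classify ligand activity from assay values
#'
#' A ligand is active at pChEMBL > 7 or standard value <= 100 nM, inactive at
#' pChEMBL <= 5.5 or standard value >= 10 uM (10,000 nM), otherwise unknown.
#' When the two values disagree, the curated pChEMBL classification wins and
#' the conflict is reported via a warning.
#'
#' @param pchembl numeric vector of pChEMBL values (NA when absent).
#' @param standardValueNM numeric vector of standard values in nM (NA when
#'   absent).
#' @param activePchembl,inactivePchembl pChEMBL thresholds (default > 7
#'   active, <= 5.5 inactive).
#' @param activeNM,inactiveNM standard-value thresholds in nM (default
#'   <= 100 active, >= 10000 inactive).
#' @return Character vector of labels: "active", "inactive" or "unknown".
#' @export
classifyActivity <- function(pchembl, standardValueNM = NA_real_,
                             activePchembl = 7, inactivePchembl = 5.5,
                             activeNM = 100, inactiveNM = 1e4) {
  n <- max(length(pchembl), length(standardValueNM))
  pchembl <- rep_len(as.numeric(pchembl), n)
  standardValueNM <- rep_len(as.numeric(standardValueNM), n)
  if (any(is.na(pchembl) & is.na(standardValueNM)))
    stopf("at least one of pChEMBL / standard value must be present for every ligand")
  labP <- ifelse(is.na(pchembl), NA,
                 ifelse(pchembl > activePchembl, "active",
                        ifelse(pchembl <= inactivePchembl, "inactive",
                               "unknown")))
  labV <- ifelse(is.na(standardValueNM), NA,
                 ifelse(standardValueNM <= activeNM, "active",
                        ifelse(standardValueNM >= inactiveNM, "inactive",
                               "unknown")))
  conflict <- !is.na(labP) & !is.na(labV) & labP != "unknown" &
    labV != "unknown" & labP != labV
  if (any(conflict))
    warnf("%d ligand(s) with conflicting pChEMBL / standard-value classes; pChEMBL retained",
          sum(conflict))
  out <- ifelse(!is.na(labP) & labP != "unknown", labP,
                ifelse(!is.na(labV) & labV != "unknown", labV, "unknown"))
  # pChEMBL between thresholds but decisive standard value: value decides,
  # unless it conflicts (handled above: labP != unknown wins there)
  out[is.na(labP) & !is.na(labV)] <- labV[is.na(labP) & !is.na(labV)]
  out
}

#' ROC AUC for a docking ranking
#'
#' Probability that a randomly chosen active outranks (scores lower than) a
#' randomly chosen inactive, with ties counting one half — the rank-sum
#' formulation with midranks.
#'
#' @param scores numeric scores, lower = better.
#' @param labels "active"/"inactive" (or logical, TRUE = active).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  act <- asActiveLogical(labels)
  checkTwoClasses(act)
  na <- sum(act); ni <- sum(!act)
  r <- rank(-scores)            # higher rank = better (lower score)
  (sum(r[act]) - na * (na + 1) / 2) / (na * ni)
}

#' Exponential ROC enrichment (eROCE)
#'
#' Early-recognition metric weighting each active by `exp(-alpha * FPR)`,
#' where FPR is the fraction of inactives ranked strictly ahead of that
#' active (ties contribute one half):
#' `eROCE = mean over actives of exp(-alpha * FPR_i)`, in (0, 1].
#'
#' @param scores numeric scores, lower = better.
#' @param labels "active"/"inactive" or logical.
#' @param alpha positive early-recognition weight (default 20, comparable
#'   early emphasis to BEDROC at alpha = 20).
#' @return eROCE value in (0, 1].
#' @export
eroce <- function(scores, labels, alpha = 20) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0)
    stopf("alpha must be a single positive number")
  act <- asActiveLogical(labels)
  checkTwoClasses(act)
  sAct <- scores[act]; sIna <- scores[!act]
  ni <- length(sIna)
  so <- sort(sIna)
  # inactives strictly better (smaller) than each active, plus half the ties
  strict <- findInterval(sAct, so, left.open = TRUE)  # counts so < s
  ties <- findInterval(sAct, so) - strict             # counts so == s
  fpr <- (strict + 0.5 * ties) / ni
  mean(exp(-alpha * fpr))
}

# deterministic top-set membership: best `size` rows by (score, ligand order)
topSet <- function(scores, size) {
  order(scores, seq_along(scores))[seq_len(size)]
}

#' Enrichment factor at a top-ranked fraction
#'
#' `EF(f) = (actives in top set / top-set size) / (total actives / N)` with the
#' top set holding `ceiling(f * N)` ligands (boundary ties resolved by input
#' order, making the value deterministic).
#'
#' @param scores numeric scores, lower = better.
#' @param labels "active"/"inactive" or logical.
#' @param fraction top fraction in (0, 1].
#' @return Enrichment factor (>= 0, bounded by 1/fraction).
#' @export
enrichmentFactor <- function(scores, labels, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1]")
  act <- asActiveLogical(labels)
  checkTwoClasses(act)
  n <- length(scores)
  size <- ceiling(fraction * n)
  hits <- sum(act[topSet(scores, size)])
  (hits / size) / (sum(act) / n)
}

#' Confusion-matrix metrics at top-ranked cutoffs
#'
#' For each fraction f, "predicted positive" is membership in the top
#' `ceiling(f * N)` of the ranking; precision, recall and F1 are derived
#' exactly from the confusion counts (F1 defined as 0 when undefined).
#'
#' @param scores numeric scores, lower = better.
#' @param labels "active"/"inactive" or logical.
#' @param fractions cutoff fractions (default 0.2%, 0.5%, 1%, 2%, 5%, 10%).
#' @return data.frame with columns `fraction`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
cutoffMetrics <- function(scores, labels,
                          fractions = c(0.002, 0.005, 0.01, 0.02, 0.05, 0.10)) {
  act <- asActiveLogical(labels)
  checkTwoClasses(act)
  n <- length(scores); na <- sum(act)
  rows <- lapply(fractions, function(f) {
    size <- ceiling(f * n)
    tp <- sum(act[topSet(scores, size)])
    fp <- size - tp
    fn <- na - tp
    tn <- n - size - fn
    precision <- if (size > 0) tp / size else 0
    recall <- tp / na
    f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(fraction = f, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Per-conformer screening metrics from a ScreenTable
#'
#' Computes AUC, eROCE, enrichment factors and cutoff metrics for one
#' conformer and one score component.  Rows with label "unknown" are excluded.
#'
#' @param screen a [ScreenTable-class] with a `label` column.
#' @param conformer conformer id to evaluate.
#' @param component score-component column (default "total").
#' @param kinase optional kinase id filter (required when the table holds
#'   several kinases).
#' @param alpha eROCE weight.
#' @param efFractions fractions for enrichment factors (default 1% and 10%).
#' @param cutoffFractions fractions for confusion-matrix metrics.
#' @return A [MetricsReport-class].
#' @export
conformerMetrics <- function(screen, conformer, component = "total",
                             kinase = NULL, alpha = 20,
                             efFractions = c(0.01, 0.10),
                             cutoffFractions = c(0.002, 0.005, 0.01, 0.02,
                                                 0.05, 0.10)) {
  d <- screenData(screen)
  if (!component %in% names(d)) stopf("unknown score component '%s'", component)
  if (!"label" %in% names(d)) stopf("ScreenTable has no activity labels")
  if (!is.null(kinase)) d <- d[d$kinase_id == kinase, , drop = FALSE]
  if (length(unique(d$kinase_id)) > 1)
    stopf("ScreenTable holds several kinases; pass `kinase`")
  d <- d[d$conformer_id == conformer & d$label != "unknown", , drop = FALSE]
  if (!nrow(d)) stopf("no labelled rows for conformer '%s'", conformer)
  s <- d[[component]]; lab <- d$label
  ef <- vapply(efFractions, function(f) enrichmentFactor(s, lab, f), numeric(1))
  names(ef) <- as.character(efFractions)
  new("MetricsReport", conformerId = as.character(conformer),
      component = component, auc = rocAuc(s, lab),
      eroce = eroce(s, lab, alpha), ef = ef,
      cutoffs = cutoffMetrics(s, lab, cutoffFractions),
      nActives = sum(lab == "active"), nLigands = nrow(d))
}

#' Evaluate every conformer in a ScreenTable
#'
#' @inheritParams conformerMetrics
#' @return Named list of [MetricsReport-class], one per conformer.
#' @export
evaluateConformers <- function(screen, component = "total", kinase = NULL,
                               alpha = 20,
                               cutoffFractions = c(0.002, 0.005, 0.01, 0.02,
                                                   0.05, 0.10)) {
  d <- screenData(screen)
  if (!is.null(kinase)) d <- d[d$kinase_id == kinase, , drop = FALSE]
  ids <- sort(unique(d$conformer_id))
  reports <- lapply(ids, function(cid)
    conformerMetrics(screen, cid, component, kinase, alpha,
                     cutoffFractions = cutoffFractions))
  names(reports) <- ids
  reports
}

#' Aggregate conformer metrics across the ensemble
#'
#' Sums confusion counts across conformers per cutoff and recomputes
#' precision/recall/F1 from the pooled counts; also returns the per-conformer
#' metric table.
#'
#' @param reports list of [MetricsReport-class] sharing one cutoff grid.
#' @return A list: `summary` (pooled cutoff metrics data.frame),
#'   `perConformer` (data.frame of auc/eroce/ef per conformer).
#' @export
aggregateConformers <- function(reports) {
  if (!length(reports)) stopf("need at least one report")
  grids <- lapply(reports, function(r) r@cutoffs$fraction)
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stopf("reports use different cutoff grids")
  pooled <- Reduce(function(a, b) {
    a[, c("tp", "fp", "fn", "tn")] <- a[, c("tp", "fp", "fn", "tn")] +
      b[, c("tp", "fp", "fn", "tn")]
    a
  }, lapply(reports, function(r) r@cutoffs[, c("fraction", "tp", "fp", "fn",
                                               "tn")]))
  pooled$precision <- ifelse(pooled$tp + pooled$fp > 0,
                             pooled$tp / (pooled$tp + pooled$fp), 0)
  pooled$recall <- ifelse(pooled$tp + pooled$fn > 0,
                          pooled$tp / (pooled$tp + pooled$fn), 0)
  pooled$f1 <- ifelse(pooled$tp > 0,
                      2 * pooled$precision * pooled$recall /
                        (pooled$precision + pooled$recall), 0)
  per <- do.call(rbind, lapply(reports, function(r) {
    data.frame(conformer_id = r@conformerId, component = r@component,
               auc = r@auc, eroce = r@eroce,
               ef1 = if ("0.01" %in% names(r@ef)) r@ef[["0.01"]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(summary = pooled, perConformer = per)
}

#' Prioritize conformers by discrimination and early enrichment
#'
#' Retains conformers with AUC at or above `aucMin` and strong early
#' enrichment, operationalized as eROCE and EF1\% both at or above the
#' ensemble median.
#'
#' @param reports list of [MetricsReport-class].
#' @param aucMin minimum AUC (default 0.70).
#' @return Character vector of retained conformer ids (possibly empty).
#' @export
selectConformers <- function(reports, aucMin = 0.70) {
  if (!length(reports)) stopf("need at least one report")
  auc <- vapply(reports, function(r) r@auc, numeric(1))
  er <- vapply(reports, function(r) r@eroce, numeric(1))
  ef1 <- vapply(reports, function(r) {
    if (!"0.01" %in% names(r@ef)) stopf("reports must include EF at 1%%")
    r@ef[["0.01"]]
  }, numeric(1))
  keep <- auc >= aucMin & er >= median(er) & ef1 >= median(ef1)
  ids <- vapply(reports, function(r) r@conformerId, character(1))
  ids[keep]
}

#' ROC curve points for external plotting
#'
#' True/false positive rates along the ranking (score thresholds swept from
#' best to worst, ties grouped).
#'
#' @param scores numeric scores, lower = better.
#' @param labels "active"/"inactive" or logical.
#' @return data.frame with columns `fpr`, `tpr`, starting at (0, 0).
#' @export
rocPoints <- function(scores, labels) {
  act <- asActiveLogical(labels)
  checkTwoClasses(act)
  thr <- sort(unique(scores))
  na <- sum(act); ni <- sum(!act)
  tpr <- vapply(thr, function(t) sum(act & scores <= t) / na, numeric(1))
  fpr <- vapply(thr, function(t) sum(!act & scores <= t) / ni, numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Read a docking score table from CSV
#'
#' Accepts the long format (`ligand_id, conformer_id, kinase_id, component,
#' value`) or the wide format with one numeric column per component; a
#' `label` column, when present, is carried through.
#'
#' @param path CSV file path.
#' @return A [ScreenTable-class].
#' @export
readScreenTableCSV <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (all(c("component", "value") %in% names(d))) {
    wide <- stats::reshape(d, idvar = c("ligand_id", "conformer_id",
                                        "kinase_id"),
                           timevar = "component", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    d <- wide
  }
  ScreenTable(d)
}

#' Write screening metrics to JSON and TSV
#'
#' @param reports list of [MetricsReport-class].
#' @param jsonPath,tsvPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the aggregate list from [aggregateConformers()].
#' @export
writeMetricsReport <- function(reports, jsonPath = NULL, tsvPath = NULL) {
  agg <- aggregateConformers(reports)
  if (!is.null(jsonPath)) {
    payload <- list(
      per_conformer = agg$perConformer,
      pooled_cutoffs = agg$summary,
      cutoff_tables = lapply(reports, function(r) r@cutoffs),
      parameters = list(score_convention = "lower = better"))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsvPath))
    write.table(agg$perConformer, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(agg)
}
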