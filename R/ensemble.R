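# Conformational ensemble reduction: complete-linkage clustering of the
# binding-site RMSD matrix, medoid + max-min representative selection, MDS
# projection for visualization, and the docking-fidelity replacement rule.

#' Complete-linkage clustering of a binding-site RMSD matrix
#'
#' Hierarchical agglomerative clustering with complete linkage, cut to `k`
#' groups.  At every merge the inter-cluster distance equals the maximum
#' pairwise distance between members, so merge heights are non-decreasing.
#'
#' @param D a [DistanceMatrix-class].
#' @param k number of clusters, `1 <= k <= n`.
#' @return A [ClusterModel-class].
#' @export
clusterConformers <- function(D, k) {
  stopifnot(is(D, "DistanceMatrix"))
  n <- length(dmLabels(D))
  if (!isCount(k) || k > n) stopf("k must be an integer in [1, %d]", n)
  hc <- hclust(as.dist(dmValues(D)), method = "complete")
  assign <- cutree(hc, k = k)
  new("ClusterModel", labels = dmLabels(D),
      assignments = setNames(as.integer(assign), names(assign)),
      k = as.integer(k), tree = unclass(hc))
}

# mean silhouette width of a k-cut (k >= 2)
meanSilhouette <- function(D, k) {
  model <- clusterConformers(D, k)
  sil <- cluster::silhouette(assignments(model), dmatrix = dmValues(D))
  mean(sil[, "sil_width"])
}

#' Choose the cluster count by maximum mean silhouette
#'
#' Evaluates the complete-linkage cut at each `k` in `kRange` and returns the
#' `k` with the largest mean silhouette width (ties to the smallest `k`).
#'
#' @param D a [DistanceMatrix-class].
#' @param kRange candidate cluster counts (default 2 to 8).
#' @return A list: `k` (chosen count), `silhouette` (named numeric of mean
#'   widths per candidate).
#' @export
chooseClusterCount <- function(D, kRange = 2:8) {
  n <- length(dmLabels(D))
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stopf("no admissible k in range for %d structures", n)
  widths <- vapply(kRange, function(k) meanSilhouette(D, k), numeric(1))
  names(widths) <- kRange
  list(k = kRange[which.max(widths)], silhouette = widths)
}

clusterMembers <- function(model) {
  split(names(assignments(model)), assignments(model))
}

# medoid of a member set: minimum sum of within-cluster distances,
# ties broken by lexicographic structure id
medoidOf <- function(members, V) {
  sums <- rowSums(V[members, members, drop = FALSE])
  cand <- members[sums == min(sums)]
  cand[orderLex(cand)[1]]
}

#' Select cluster representatives (medoid plus max-min diversity picks)
#'
#' The primary representative of each cluster is the medoid.  Clusters holding
#' at least `populationThreshold` of all structures receive one extra pick, and
#' clusters whose mean within-cluster RMSD exceeds the across-cluster median
#' receive another, up to `cap` (and never more than the cluster size).  Each
#' extra pick maximizes its minimum RMSD to the already-selected
#' representatives of that cluster.
#'
#' @param D a [DistanceMatrix-class].
#' @param model a [ClusterModel-class] consistent with `D`.
#' @param populationThreshold fraction of all structures above which a cluster
#'   earns an extra representative (default 0.25).
#' @param cap maximum representatives per cluster (default 3).
#' @return A [RepresentativeSet-class].
#' @export
selectRepresentatives <- function(D, model, populationThreshold = 0.25,
                                  cap = 3) {
  stopifnot(is(D, "DistanceMatrix"), is(model, "ClusterModel"))
  if (!setequal(dmLabels(D), model@labels))
    stopf("cluster model labels do not match the distance matrix")
  V <- dmValues(D)
  members <- clusterMembers(model)
  if (any(lengths(members) == 0)) stopf("empty cluster")
  nTotal <- length(model@labels)
  meanWithin <- vapply(members, function(m) {
    if (length(m) < 2) return(0)
    sub <- V[m, m, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  dispersionRef <- median(meanWithin)
  rows <- list()
  for (cl in names(members)) {
    m <- members[[cl]]
    nReps <- 1L + (length(m) / nTotal >= populationThreshold) +
      (meanWithin[[cl]] > dispersionRef)
    nReps <- min(nReps, cap, length(m))
    sel <- medoidOf(m, V)
    ann <- "medoid"
    while (length(sel) < nReps) {
      rest <- setdiff(m, sel)
      minDist <- apply(V[rest, sel, drop = FALSE], 1, min)
      cand <- rest[minDist == max(minDist)]
      sel <- c(sel, cand[orderLex(cand)[1]])
      ann <- c(ann, "maxmin")
    }
    rows[[cl]] <- data.frame(cluster = as.integer(cl), structure_id = sel,
                             rank = seq_along(sel), annotation = ann,
                             flagged = FALSE, stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  new("RepresentativeSet", reps = reps,
      params = list(population_threshold = populationThreshold,
                    dispersion_reference = dispersionRef, cap = cap))
}

#' Classical multidimensional scaling of the RMSD matrix
#'
#' Torgerson MDS: eigendecomposition of the double-centered squared-distance
#' matrix, returning the top-`dims` coordinates ordered by eigenvalue.  If
#' fewer than `dims` positive eigenvalues exist, missing coordinates are
#' zero-padded with a warning.
#'
#' @param D a [DistanceMatrix-class].
#' @param dims embedding dimension (default 3); must be `<= n - 1`.
#' @return A data.frame: `structure_id` followed by columns `mds1..mds<dims>`.
#' @export
mdsProject <- function(D, dims = 3) {
  stopifnot(is(D, "DistanceMatrix"))
  n <- length(dmLabels(D))
  if (!isCount(dims) || dims > n - 1)
    stopf("dims must be an integer in [1, %d]", n - 1)
  fit <- cmdscale(as.dist(dmValues(D)), k = dims, eig = TRUE)
  pts <- fit$points
  # drop numerically-zero eigendirections before padding
  if (ncol(pts)) {
    eig <- fit$eig[seq_len(ncol(pts))]
    keep <- eig > max(fit$eig) * 1e-8
    pts <- pts[, keep, drop = FALSE]
  }
  if (ncol(pts) < dims) {
    warnf("only %d positive eigenvalue(s); padding %d coordinate(s) with zeros",
          ncol(pts), dims - ncol(pts))
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  out <- data.frame(structure_id = dmLabels(D), pts, stringsAsFactors = FALSE)
  names(out) <- c("structure_id", paste0("mds", seq_len(dims)))
  rownames(out) <- NULL
  out
}

#' Apply the docking-fidelity (LBI) replacement rule to representatives
#'
#' A representative passes when its re-docked crystallographic ligand deviates
#' from the crystal pose by at most `threshold` angstroms.  A failing
#' representative is replaced by the nearest same-cluster structure (by RMSD)
#' that passes and is not already selected; when no member passes, the original
#' is kept and flagged with a warning.
#'
#' @param reps a [RepresentativeSet-class].
#' @param lbi data.frame with columns `structure_id` and `pose_deviation_A`.
#' @param D the [DistanceMatrix-class] the clustering was computed from.
#' @param model the [ClusterModel-class].
#' @param threshold pass threshold in angstroms (default 2.0).
#' @return An updated [RepresentativeSet-class].
#' @export
applyLbiFilter <- function(reps, lbi, D, model, threshold = 2.0) {
  stopifnot(is(reps, "RepresentativeSet"))
  r <- representatives(reps)
  miss <- setdiff(r$structure_id, lbi$structure_id)
  if (length(miss))
    stopf("missing LBI record for structure(s): %s", paste(miss, collapse = ", "))
  dev <- setNames(lbi$pose_deviation_A, lbi$structure_id)
  if (any(dev < 0)) stopf("pose deviations must be non-negative")
  passes <- function(id) !is.na(dev[id]) && dev[id] <= threshold
  V <- dmValues(D)
  members <- clusterMembers(model)
  for (i in seq_len(nrow(r))) {
    id <- r$structure_id[i]
    if (passes(id)) next
    pool <- setdiff(members[[as.character(r$cluster[i])]], r$structure_id)
    pool <- pool[pool %in% names(dev)[dev <= threshold]]
    if (!length(pool)) {
      r$flagged[i] <- TRUE
      warnf("cluster %d: no member passes the docking-fidelity threshold; keeping '%s' (deviation %.2f A)",
            r$cluster[i], id, dev[id])
      next
    }
    dd <- V[id, pool]
    cand <- pool[dd == min(dd)]
    repl <- cand[orderLex(cand)[1]]
    r$structure_id[i] <- repl
    r$annotation[i] <- "lbi-replacement"
  }
  params <- reps@params
  params$lbi_threshold_A <- threshold
  new("RepresentativeSet", reps = r, params = params)
}

#' Write cluster assignments / representatives / MDS coordinates
#'
#' Plain-file exports used by the pipeline stage: assignments as CSV,
#' representatives as JSON (with annotations and selection parameters) and
#' MDS coordinates as CSV.
#'
#' @param model a [ClusterModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClusterAssignmentsCSV <- function(model, path) {
  df <- data.frame(structure_id = names(assignments(model)),
                   cluster = as.integer(assignments(model)))
  df <- df[orderLex(df$structure_id), ]
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterAssignmentsCSV
#' @param reps a [RepresentativeSet-class].
#' @export
writeRepresentativesJSON <- function(reps, path) {
  jsonlite::write_json(list(parameters = reps@params,
                            representatives = representatives(reps)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
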