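# Relative-rank selectivity between two kinase isoforms: normalized ranks,
# the RR difference, cross-kinase rank concordance, paired component tests
# and hit prioritization on an external library.

#' Normalized docking ranks for one kinase
#'
#' Ranks ligands by a score component within each selected conformer (rank 1 =
#' best score, midranks for ties), normalizes by the ligand count, and
#' consolidates across conformers: `"mean"` (default) averages the
#' per-conformer normalized ranks, `"best"` takes their minimum.
#'
#' @param screen a [ScreenTable-class].
#' @param kinase kinase id to slice (default: the single kinase present).
#' @param conformers conformer ids to use (default: all present); must be
#'   non-empty.
#' @param component score component column (default "total").
#' @param consensus consensus rule, "mean" or "best".
#' @return A [RankTable-class].
#' @export
normalizeRanks <- function(screen, kinase = NULL, conformers = NULL,
                           component = "total", consensus = c("mean", "best")) {
  consensus <- match.arg(consensus)
  d <- screenData(screen)
  if (is.null(kinase)) {
    kin <- unique(d$kinase_id)
    if (length(kin) > 1) stopf("ScreenTable holds several kinases; pass `kinase`")
    kinase <- kin
  }
  d <- d[d$kinase_id == kinase, , drop = FALSE]
  if (is.null(conformers)) conformers <- sort(unique(d$conformer_id))
  if (!length(conformers)) stopf("empty conformer selection")
  miss <- setdiff(conformers, d$conformer_id)
  if (length(miss)) stopf("conformer(s) not in table: %s",
                          paste(miss, collapse = ", "))
  if (!component %in% names(d)) stopf("unknown score component '%s'", component)
  perConf <- lapply(conformers, function(cid) {
    dd <- d[d$conformer_id == cid, , drop = FALSE]
    if (!nrow(dd)) stopf("no rows for conformer '%s'", cid)
    setNames(rank(dd[[component]]) / nrow(dd), dd$ligand_id)
  })
  ligands <- Reduce(intersect, lapply(perConf, names))
  if (!length(ligands)) stopf("no ligand scored by every selected conformer")
  mat <- vapply(perConf, function(r) r[ligands], numeric(length(ligands)))
  mat <- matrix(mat, nrow = length(ligands))
  vals <- if (consensus == "mean") rowMeans(mat) else apply(mat, 1, min)
  new("RankTable", kinaseId = as.character(kinase),
      conformers = as.character(conformers), consensus = consensus,
      ranks = setNames(vals, ligands))
}

#' Relative-rank (RR) selectivity score
#'
#' `rr = R_A - R_B`, the difference of a ligand's normalized ranks against
#' kinase A and kinase B.  Negative values indicate preferential kinase-A
#' ranking; values near zero indicate comparable predicted affinity.
#'
#' @param rA,rB normalized ranks in (0, 1] (vectors recycle).
#' @return Numeric rr values in (-1, 1).
#' @export
relativeRank <- function(rA, rB) {
  if (any(!is.finite(rA)) || any(!is.finite(rB)) ||
      any(rA <= 0 | rA > 1) || any(rB <= 0 | rB > 1))
    stopf("normalized ranks must lie in (0, 1]")
  rA - rB
}

#' Per-ligand selectivity table for two kinases
#'
#' Joins two [RankTable-class] objects on their shared ligands and computes
#' the RR score for each.
#'
#' @param rankA,rankB [RankTable-class] objects for kinase A and kinase B.
#' @return data.frame with columns `ligand_id`, `r_a`, `r_b`, `rr`, ordered
#'   by ligand id.
#' @export
selectivityTable <- function(rankA, rankB) {
  shared <- intersect(names(rankValues(rankA)), names(rankValues(rankB)))
  if (!length(shared)) stopf("no shared ligands between the two rank tables")
  shared <- shared[orderLex(shared)]
  ra <- rankValues(rankA)[shared]
  rb <- rankValues(rankB)[shared]
  data.frame(ligand_id = shared, r_a = unname(ra), r_b = unname(rb),
             rr = unname(relativeRank(ra, rb)), stringsAsFactors = FALSE)
}

skewness <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Cross-kinase rank concordance
#'
#' Tie-corrected Spearman rho and Kendall tau-b with large-sample p-values on
#' the ligands shared by both rank tables, plus a summary of the per-ligand
#' percentile differences (Delta = R_B - R_A).
#'
#' @param rankA,rankB [RankTable-class] objects.
#' @return A list: `n`, `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`, `delta` (list with `mean`, `sd`, `skew`).
#' @export
concordance <- function(rankA, rankB) {
  tab <- selectivityTable(rankA, rankB)
  if (nrow(tab) < 3) stopf("need at least 3 shared ligands, got %d", nrow(tab))
  sp <- suppressWarnings(cor.test(tab$r_a, tab$r_b, method = "spearman",
                                  exact = FALSE))
  kd <- suppressWarnings(cor.test(tab$r_a, tab$r_b, method = "kendall",
                                  exact = FALSE))
  delta <- tab$r_b - tab$r_a
  list(n = nrow(tab),
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       kendall_tau = unname(kd$estimate), kendall_p = kd$p.value,
       delta = list(mean = mean(delta), sd = sd(delta),
                    skew = skewness(delta)))
}

#' Paired Wilcoxon signed-rank test on score components
#'
#' Two-sided Wilcoxon signed-rank test on paired component values (zero
#' differences dropped, Wilcoxon's convention), exact null distribution for
#' n <= 25 pairs and the normal approximation with continuity correction
#' otherwise, with a Bonferroni-adjusted significance level `0.05 / m`.
#'
#' @param a,b paired numeric vectors (e.g. a component's values against
#'   kinase A and kinase B for the same ligands).
#' @param m number of comparisons in the family (default 2: vdW and
#'   electrostatics), giving adjusted alpha 0.05/m.
#' @param alternative test sidedness passed to [stats::wilcox.test()].
#' @return A list: `statistic` (V), `p`, `n` (non-zero pairs),
#'   `adjusted_alpha`, `significant`.
#' @export
pairedComponentTest <- function(a, b, m = 2, alternative = "two.sided") {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  diffs <- a - b
  diffs <- diffs[diffs != 0]
  if (!length(diffs)) stopf("degenerate pairs: all differences are zero")
  if (length(diffs) < 5)
    stopf("need at least 5 non-zero paired differences, got %d", length(diffs))
  exact <- length(diffs) <= 25
  wt <- suppressWarnings(wilcox.test(diffs, alternative = alternative,
                                     exact = exact, correct = TRUE))
  adj <- 0.05 / m
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(diffs),
       adjusted_alpha = adj, significant = wt$p.value < adj)
}

#' Prioritize kinase-A-selective hits from a dual-target screen
#'
#' Retains the top `topFraction` of the library by kinase-A consensus rank
#' (`ceiling(topFraction * N)` ligands, boundary ties to the better rank then
#' lexicographic ligand id), drops ligands with `rr > rrCutoff`, drops ligands
#' with `|rr| < separationMargin` (marginal rank separation), and orders the
#' survivors by rr ascending then kinase-A rank.  Both kinases must have been
#' screened on the same library.
#'
#' @param rankA,rankB [RankTable-class] objects for the two kinases over the
#'   same ligand library.
#' @param topFraction fraction of the library retained from the kinase-A
#'   ranking (default 0.05).
#' @param rrCutoff maximum rr retained (default 0: drop any kinase-B-leaning
#'   ligand).
#' @param separationMargin minimum |rr| retained (default 0.05).
#' @param flags optional data.frame of drug-likeness flags keyed by
#'   `ligand_id` (joined onto the hits, not used for filtering).
#' @return A [HitList-class].
#' @export
prioritizeHits <- function(rankA, rankB, topFraction = 0.05, rrCutoff = 0,
                           separationMargin = 0.05, flags = NULL) {
  ra <- rankValues(rankA); rb <- rankValues(rankB)
  if (!setequal(names(ra), names(rb)))
    stopf("library mismatch: the two kinases were not screened on the same ligand set")
  if (topFraction <= 0 || topFraction > 1) stopf("topFraction must lie in (0, 1]")
  tab <- selectivityTable(rankA, rankB)
  n <- nrow(tab)
  size <- ceiling(topFraction * n)
  ord <- order(tab$r_a, tab$ligand_id, method = "radix")
  top <- tab[ord[seq_len(size)], , drop = FALSE]
  kept <- top[top$rr <= rrCutoff & abs(top$rr) >= separationMargin, ,
              drop = FALSE]
  kept <- kept[order(kept$rr, kept$r_a, method = "radix"), , drop = FALSE]
  rownames(kept) <- NULL
  if (!is.null(flags)) {
    idx <- match(kept$ligand_id, flags$ligand_id)
    kept <- cbind(kept, flags[idx, setdiff(names(flags), "ligand_id"),
                              drop = FALSE])
    rownames(kept) <- NULL
  }
  new("HitList", hits = kept,
      provenance = list(top_fraction = topFraction, rr_cutoff = rrCutoff,
                        separation_margin = separationMargin,
                        consensus = rankA@consensus,
                        library_size = n, top_retained = size,
                        hits_retained = nrow(kept)))
}

#' Drug-likeness rule flags from supplied descriptors
#'
#' Evaluates the Lipinski (at most one violation of MW <= 500, logP <= 5,
#' HBD <= 5, HBA <= 10), Veber (RotB <= 10 and TPSA <= 140) and Ghose
#' (160 <= MW <= 480, -0.4 <= logP <= 5.6, 40 <= MR <= 130, 20 <= atoms <= 70)
#' rules on an input descriptor table.  Descriptors are inputs, never computed
#' from structure; a missing descriptor renders the affected flag
#' indeterminate (NA), not failing.
#'
#' @param descriptors data.frame with columns `ligand_id`, `MW`, `logP`,
#'   `HBD`, `HBA`, `RotB`, `TPSA`, `MR`, `heavy_atoms` (missing columns are
#'   treated as all-NA).
#' @return data.frame: `ligand_id`, `lipinski_violations`, `lipinski`,
#'   `veber`, `ghose` (logical flags, NA = indeterminate).
#' @export
drugLikenessFlags <- function(descriptors) {
  getcol <- function(nm) if (nm %in% names(descriptors))
    as.numeric(descriptors[[nm]]) else rep(NA_real_, nrow(descriptors))
  MW <- getcol("MW"); logP <- getcol("logP"); HBD <- getcol("HBD")
  HBA <- getcol("HBA"); RotB <- getcol("RotB"); TPSA <- getcol("TPSA")
  MR <- getcol("MR"); atoms <- getcol("heavy_atoms")
  viol <- (MW > 500) + (logP > 5) + (HBD > 5) + (HBA > 10)
  lipinski <- viol <= 1
  veber <- RotB <= 10 & TPSA <= 140
  ghose <- MW >= 160 & MW <= 480 & logP >= -0.4 & logP <= 5.6 &
    MR >= 40 & MR <= 130 & atoms >= 20 & atoms <= 70
  data.frame(ligand_id = descriptors$ligand_id,
             lipinski_violations = viol, lipinski = lipinski,
             veber = veber, ghose = ghose, stringsAsFactors = FALSE)
}

#' Write selectivity outputs
#'
#' Selectivity table and hit list as CSV (the latter with filter-provenance
#' columns), concordance report as JSON.
#'
#' @param tab selectivity data.frame from [selectivityTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSelectivityCSV <- function(tab, path) {
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelectivityCSV
#' @param hits a [HitList-class].
#' @export
writeHitListCSV <- function(hits, path) {
  h <- hitTable(hits)
  p <- hits@provenance
  if (nrow(h)) {
    h$top_fraction <- p$top_fraction
    h$rr_cutoff <- p$rr_cutoff
    h$separation_margin <- p$separation_margin
    h$consensus <- p$consensus
  }
  write.table(h, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelectivityCSV
#' @param report concordance list from [concordance()].
#' @export
writeConcordanceJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
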