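#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats hclust cutree cmdscale dist rank wilcox.test cor.test
#'   fisher.test p.adjust rnorm runif setNames median sd cor
#' @importFrom utils write.table read.table head
NULL

# residue identity key: chain, number, insertion code (1-based PDB numbering
# preserved verbatim)
residueKey <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = ":")
}

# deterministic ordering used for every tie-break on structure/ligand ids
orderLex <- function(ids) order(ids, method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 1

# Euclidean RMSD between two coordinate matrices (rows paired), no fitting
coordRmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

asActiveLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("active", "inactive")
    if (!all(ok)) stopf("labels must be 'active'/'inactive' (or logical); got %s",
                        paste(unique(labels[!ok]), collapse = ", "))
    return(labels == "active")
  }
  stopf("unsupported label type '%s'", class(labels)[1])
}

checkTwoClasses <- function(active) {
  if (!any(active) || all(active))
    stopf("need at least one active and one inactive ligand")
  invisible(TRUE)
}
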