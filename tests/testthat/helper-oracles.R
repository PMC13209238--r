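# Independent oracles used to cross-check the package implementations.
# Each is written naively (brute force / enumeration) and never shares code
# with the functions it checks.

# naive O(n^3) complete-linkage agglomeration: repeatedly merge the two
# clusters whose maximum inter-member distance is smallest
naiveCompleteLinkage <- function(V, k) {
  n <- nrow(V)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- max(V[clusters[[i]], clusters[[j]]])
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (i in seq_along(clusters)) assign[clusters[[i]]] <- i
  assign
}

# partitions equal up to cluster relabelling
samePartition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# exhaustive active/inactive pair counting AUC (ties count one half)
pairCountAuc <- function(scores, active) {
  sa <- scores[active]; si <- scores[!active]
  cmp <- outer(sa, si, function(a, b) (a < b) + 0.5 * (a == b))
  # numerator is an exact multiple of 1/2, so sum and quotient are exact
  sum(cmp) / (length(sa) * length(si))
}

# brute-force rigid superposition: optimal translation is centroid matching;
# rotations searched on successively refined Euler-angle grids
gridSearchSuperposeRmsd <- function(mobile, reference, tol = 1e-3) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rotM <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  rmsdAt <- function(ang) {
    R <- rotM(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- c(0, 0, 0); bestV <- rmsdAt(best)
  step <- pi / 18   # 10 degrees
  grid <- seq(-pi, pi, by = step)
  for (a in grid) for (b in grid[grid >= 0 & grid <= pi]) for (c in grid) {
    v <- rmsdAt(c(a, b, c))
    if (v < bestV) { bestV <- v; best <- c(a, b, c) }
  }
  while (step > 1e-5) {
    step <- step / 2
    grid <- seq(-3, 3, by = 1) * step
    for (da in grid) for (db in grid) for (dc in grid) {
      v <- rmsdAt(best + c(da, db, dc))
      if (v < bestV) { bestV <- v; best <- best + c(da, db, dc) }
    }
  }
  bestV
}

# exhaustive concordant/discordant Kendall tau-b
bruteKendallTauB <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# random valid distance matrix from random points (Euclidean, so metric)
randomDistanceMatrix <- function(n, dim = 3) {
  pts <- matrix(rnorm(n * dim), ncol = dim)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  DistanceMatrix(m)
}

# toy structure: residues given as list of n x 3 coordinate matrices
# (all atoms carbon "CB" side-chain by default), ligand as one matrix
toyStructure <- function(id, residues, ligand = NULL,
                         elety = "CB", elesy = "C") {
  rows <- do.call(rbind, lapply(seq_along(residues), function(i) {
    xyz <- residues[[i]]
    data.frame(elety = paste0(elety, seq_len(nrow(xyz))), elesy = elesy,
               chain = "A", resno = i, icode = "", resid = "ALA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  lig <- if (is.null(ligand)) NULL else
    data.frame(elety = paste0("C", seq_len(nrow(ligand))), elesy = "C",
               chain = "A", resno = 900, icode = "", resid = "LIG",
               x = ligand[, 1], y = ligand[, 2], z = ligand[, 3],
               stringsAsFactors = FALSE)
  StructureRecord(id, rows, lig, if (is.null(lig)) "" else "LIG")
}
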