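# geometric interaction fingerprints, hinge motif, bit enrichment,
# pose consistency

# minimal one-residue protein + map for direct criterion checks
hingeProtein <- function(atoms, resid = "GLY", label = "hinge.46") {
  prot <- do.call(rbind, lapply(seq_len(nrow(atoms$xyz)), function(i)
    data.frame(elety = atoms$elety[i], elesy = atoms$elesy[i], chain = "A",
               resno = 46L, icode = "", resid = resid,
               x = atoms$xyz[i, 1], y = atoms$xyz[i, 2], z = atoms$xyz[i, 3],
               stringsAsFactors = FALSE)))
  list(protein = StructureRecord("prot", prot),
       map = data.frame(structure_id = "prot", chain = "A", resno = 46L,
                        icode = "", klifs_label = label,
                        stringsAsFactors = FALSE))
}

ligAtom <- function(elety, elesy, xyz, charge = 0, ring = NA_integer_) {
  data.frame(elety = elety, elesy = elesy, chain = "A", resno = 901L,
             icode = "", resid = "LIG", x = xyz[1], y = xyz[2], z = xyz[3],
             charge = charge, ring = ring, stringsAsFactors = FALSE)
}

test_that("hydrogen-bond bits follow the distance and angle criteria", {
  hp <- hingeProtein(list(elety = "O", elesy = "O",
                          xyz = matrix(c(0, 0, 0), 1)))
  # ligand N-H donor with protein backbone O at 2.9 A, D-H...A = 155 degrees
  nPos <- c(2.9, 0, 0)
  th <- (180 - 155) * pi / 180
  hPos <- nPos + 1.0 * c(-cos(th), sin(th), 0)  # H tilted 25 deg off N->O
  pose <- rbind(ligAtom("N1", "N", nPos), ligAtom("H1", "H", hPos))
  fp <- detectInteractions(pose, hp$protein, hp$map)
  expect_equal(fingerprintBits(fp), "hinge.46|hbond.acceptor")
  # same geometry at 4.2 A: beyond the 3.5 A cutoff
  pose2 <- rbind(ligAtom("N1", "N", c(4.2, 0, 0)),
                 ligAtom("H1", "H", c(3.2, 0, 0)))
  expect_length(fingerprintBits(detectInteractions(pose2, hp$protein,
                                                   hp$map)), 0)
  # explicit hydrogen pointing away (D-H...A = 0 deg): angle criterion fails
  pose3 <- rbind(ligAtom("N1", "N", nPos), ligAtom("H1", "H", c(3.9, 0, 0)))
  expect_length(fingerprintBits(detectInteractions(pose3, hp$protein,
                                                   hp$map)), 0)
  # without the hydrogen the distance-only rule applies
  pose4 <- ligAtom("N1", "N", nPos)
  expect_equal(fingerprintBits(detectInteractions(pose4, hp$protein, hp$map)),
               "hinge.46|hbond.acceptor")
})

test_that("hydrophobic contacts respect the apolar C...C cutoff", {
  hp <- hingeProtein(list(elety = "CD1", elesy = "C",
                          xyz = matrix(c(0, 0, 0), 1)), resid = "LEU",
                     label = "aD.55")
  expect_equal(fingerprintBits(detectInteractions(
    ligAtom("C1", "C", c(4.0, 0, 0)), hp$protein, hp$map)),
    "aD.55|hydrophobic")
  expect_length(fingerprintBits(detectInteractions(
    ligAtom("C1", "C", c(4.8, 0, 0)), hp$protein, hp$map)), 0)
  # polar ligand atoms never count as hydrophobic partners
  expect_length(fingerprintBits(detectInteractions(
    ligAtom("O1", "O", c(4.0, 0, 0)), hp$protein, hp$map)), 0)
})

test_that("aromatic and ionic bits follow centroid and charge criteria", {
  ringXyz <- kindock:::hexagonRing(c(0, 0, 0))
  hp <- hingeProtein(list(elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                          elesy = rep("C", 6), xyz = ringXyz), resid = "PHE",
                     label = "a.l.84")
  ligRing <- kindock:::hexagonRing(c(0, 0, 5.0))
  pose <- do.call(rbind, lapply(1:6, function(i)
    ligAtom(sprintf("C%d", i), "C", ligRing[i, ], ring = 1L)))
  expect_equal(fingerprintBits(detectInteractions(pose, hp$protein, hp$map)),
               "a.l.84|aromatic")
  # centroids beyond 5.5 A: no bit
  ligRing2 <- kindock:::hexagonRing(c(0, 0, 5.8))
  pose2 <- do.call(rbind, lapply(1:6, function(i)
    ligAtom(sprintf("C%d", i), "C", ligRing2[i, ], ring = 1L)))
  expect_length(fingerprintBits(detectInteractions(pose2, hp$protein,
                                                   hp$map)), 0)
  # ionic: ASP carboxylate vs positively charged ligand nitrogen
  hp2 <- hingeProtein(list(elety = "OD1", elesy = "O",
                           xyz = matrix(c(0, 0, 0), 1)), resid = "ASP",
                      label = "aC.21")
  expect_equal(fingerprintBits(detectInteractions(
    ligAtom("N1", "N", c(3.8, 0, 0), charge = 1), hp2$protein, hp2$map)),
    "aC.21|ionic")
  expect_length(fingerprintBits(detectInteractions(
    ligAtom("N1", "N", c(4.3, 0, 0), charge = 1), hp2$protein, hp2$map)), 0)
})

test_that("contacts at unmapped residues are kept under a sentinel label", {
  hp <- hingeProtein(list(elety = "CD1", elesy = "C",
                          xyz = matrix(c(0, 0, 0), 1)), resid = "LEU")
  emptyMap <- hp$map[0, ]
  expect_warning(
    fp <- detectInteractions(ligAtom("C1", "C", c(4.0, 0, 0)), hp$protein,
                             emptyMap),
    "unmapped")
  expect_equal(fingerprintBits(fp), "unmapped|hydrophobic")
})

test_that("fingerprints are invariant under joint rigid transforms", {
  cx <- genComplex(complexSpec(nDecoys = 10, seed = 3))
  fp0 <- detectInteractions(cx$pose, cx$protein, cx$map)
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  shift <- c(7, -3, 11)
  rot <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  prot2 <- StructureRecord(structureId(cx$protein),
                           rot(proteinAtoms(cx$protein)))
  fp1 <- detectInteractions(rot(cx$pose), prot2, cx$map)
  expect_identical(fingerprintBits(fp0), fingerprintBits(fp1))
})

test_that("the hinge motif needs hydrogen bonds at both hinge positions", {
  mk <- function(bits) new("Fingerprint", ligandId = "L", conformerId = "c",
                           bits = sort(bits))
  expect_true(hingeMotif(mk(c("hinge.46|hbond.acceptor",
                              "hinge.48|hbond.donor"))))
  expect_true(hingeMotif(mk(c("hinge.46|hbond.donor",
                              "hinge.48|hbond.donor", "aD.55|hydrophobic"))))
  expect_false(hingeMotif(mk("hinge.46|hbond.acceptor")))
  expect_false(hingeMotif(mk(c("hinge.46|hydrophobic",
                               "hinge.48|hbond.donor"))))
  expect_false(hingeMotif(mk(character())))
})

test_that("bit enrichment computes exact frequencies and Fisher p-values", {
  mk <- function(bits, id) new("Fingerprint", ligandId = id,
                               conformerId = "c", bits = sort(bits))
  fps <- c(lapply(1:10, function(i) mk(c("hinge.46|hbond.donor",
                                         "aC.20|hydrophobic"),
                                       sprintf("A%d", i))),
           lapply(1:10, function(i) mk("aC.20|hydrophobic",
                                       sprintf("I%d", i))))
  labels <- rep(c("active", "inactive"), each = 10)
  enr <- bitEnrichment(fps, labels)
  hinge <- enr[enr$bit == "hinge.46|hbond.donor", ]
  expect_equal(hinge$difference, 1.0)
  # exact hypergeometric: both maximally-uneven tables, each 1/choose(20,10)
  expect_equal(hinge$p, 2 / choose(20, 10))
  shared <- enr[enr$bit == "aC.20|hydrophobic", ]
  expect_equal(shared$difference, 0)
  expect_equal(shared$p, 1)
  # sorted by decreasing |difference|
  expect_equal(enr$bit[1], "hinge.46|hbond.donor")
  expect_error(bitEnrichment(fps[1:10], labels[1:10]), "at least one")
})

test_that("label shuffling calibrates the per-bit false-positive rate", {
  set.seed(401)
  nLig <- 40; nBits <- 25
  bits <- sprintf("aC.%d|hydrophobic", 20:(20 + nBits - 1))
  fps <- lapply(1:nLig, function(i)
    new("Fingerprint", ligandId = sprintf("L%d", i), conformerId = "c",
        bits = sort(sample(bits, rbinom(1, nBits, 0.4)))))
  labels <- rep(c("active", "inactive"), each = nLig / 2)
  rates <- replicate(100, {
    enr <- bitEnrichment(fps, sample(labels))
    mean(enr$p < 0.05)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("pose consistency averages pairwise RMSD without re-fitting", {
  base <- matrix(rnorm(30), 10)
  expect_equal(poseConsistency(list(base, base))$mean_rmsd, 0)
  expect_true(poseConsistency(list(base, base))$stable)
  shifted <- base + 3 / sqrt(3)
  pc <- poseConsistency(list(base, shifted))
  expect_equal(pc$mean_rmsd, 3.0, tolerance = 1e-12)
  expect_false(pc$stable)
  # 3-pose hand mean
  s1 <- base + 1 / sqrt(3)
  pc3 <- poseConsistency(list(base, s1, shifted))
  d12 <- 1; d13 <- 3; d23 <- 2
  expect_equal(pc3$mean_rmsd, mean(c(d12, d13, d23)), tolerance = 1e-12)
  expect_error(poseConsistency(list(base, base[1:5, ])), "atom-count mismatch")
  expect_error(poseConsistency(list(base)), "at least 2")
})

test_that("position maps are validated for vocabulary and injectivity", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure_id,chain,resnum,icode,klifs_label",
               "s1,A,955,,hinge.46", "s1,A,957,,hinge.48"), tmp)
  map <- readPositionMapCSV(tmp)
  expect_equal(map$klifs_label, c("hinge.46", "hinge.48"))
  writeLines(c("structure_id,chain,resnum,icode,klifs_label",
               "s1,A,955,,hinge.99"), tmp)
  expect_error(readPositionMapCSV(tmp), "vocabulary")
  writeLines(c("structure_id,chain,resnum,icode,klifs_label",
               "s1,A,955,,hinge.46", "s1,A,957,,hinge.46"), tmp)
  expect_error(readPositionMapCSV(tmp), "injective")
})

test_that("the canonical vocabulary has 85 positions and the expected anchors", {
  v <- klifsPositions()
  expect_length(v, 85)
  expect_true(all(c("GK.45", "hinge.46", "hinge.47", "hinge.48", "aD.55",
                    "g.l.7", "linker.50", "a.l.84") %in% v))
  expect_false(anyDuplicated(sub("^.*\\.", "", v)) > 0)
})
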