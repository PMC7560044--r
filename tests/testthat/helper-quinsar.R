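# shared helpers: tiny molecule builders and a per-session cache of the
# prepared fixture set (preparation shells out to the rdkit helper once)

.qs_cache <- new.env(parent = emptyenv())

# toy atom-cloud molecule with explicit weights (prepared, no bonds)
cloudMol <- function(id, xyz, charge = 0, hydro = 0, hbd = FALSE,
                     hba = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  quinsar:::cloudMolecule(
    id, xyz,
    charge = rep_len(charge, n), hydro = rep_len(hydro, n),
    hbd = rep_len(hbd, n), hba = rep_len(hba, n)
  )
}

# an AlignedSet wrapping already-aligned molecules (identity alignment)
asAlignedSet <- function(mols) {
  names(mols) <- vapply(mols, moleculeId, character(1))
  spec <- new("AlignmentSpec", templateId = names(mols)[1],
              variants = list(list(elements = "C",
                                   bonds = matrix(integer(0), 0, 2))),
              tolerance = 1e6)
  new("AlignedSet", template = mols[[1]], members = mols,
      coreRmsd = stats::setNames(numeric(length(mols)), names(mols)),
      coreIdx = stats::setNames(rep(list(integer(0)), length(mols)),
                                names(mols)),
      spec = spec)
}

# the 16 study quinolones, prepared and aligned once per session
fixtureAlignedSet <- function() {
  if (is.null(.qs_cache$aset)) {
    qs <- loadFixture("quinolones")
    mols <- prepareMolecules(stats::setNames(qs$smiles, qs$id), seed = 1)
    .qs_cache$aset <- alignSet(mols)
  }
  .qs_cache$aset
}

preparedTrovafloxacin <- function() {
  members(fixtureAlignedSet())[["Trovafloxacin"]]
}

# brute-force CoMSIA field: naive loops over molecules, points, atoms
bruteForceField <- function(m, pts, kind, probe) {
  a <- atoms(m)
  w <- switch(kind,
    S = probe@radius^3 * vdwRadius(a$element)^3,
    E = probe@charge * a$charge,
    H = probe@hydro * a$hydro,
    D = probe@hbd * as.numeric(a$hbd),
    A = probe@hba * as.numeric(a$hba)
  )
  out <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    acc <- 0
    for (i in seq_len(nrow(a))) {
      r2 <- (a$x[i] - pts[q, 1])^2 + (a$y[i] - pts[q, 2])^2 +
        (a$z[i] - pts[q, 3])^2
      acc <- acc + w[i] * exp(-probe@alpha * r2)
    }
    out[q] <- -acc
  }
  out
}
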