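#' @include AllClasses.R comsia.R align.R
NULL

# a Molecule from a bare atom table (toy atom clouds; no bonds)
cloudMolecule <- function(id, xyz, charge, hydro, hbd, hba) {
  at <- data.frame(
    element = rep("C", nrow(xyz)), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge, hydro = hydro, hbd = hbd, hba = hba,
    formal = rep(0, nrow(xyz))
  )
  new("Molecule", id = id, atoms = at,
      bonds = data.frame(a1 = integer(0), a2 = integer(0),
                         order = numeric(0)),
      netCharge = sum(charge), prepared = TRUE,
      energies = c(pre = NA_real_, post = NA_real_),
      meta = list(kind = "synthetic atom cloud"))
}

#' Generate an aligned toy set with a planted linear field-activity model
#'
#' Atom positions are jittered copies of a shared scaffold (so the set is
#' aligned by construction), per-atom weights (charge, hydrophobicity, donor
#' and acceptor flags) are drawn per molecule, and activities are
#' \code{y = X beta + noise} where X is the assembled (kept, block-scaled)
#' descriptor matrix computed by the actual field engine. The planted
#' coefficients are therefore recoverable by construction. Bit-identical
#' output for a fixed seed; the caller's RNG state is untouched.
#'
#' By default the planted coefficient vector lies in the span of the top
#' \code{latent} right singular vectors of the centered descriptor matrix,
#' normalized to unit signal standard deviation. Field descriptors at
#' neighbouring lattice points are strongly collinear, so only row-space
#' coefficient vectors are identifiable; restricting the plant to a
#' \code{latent}-dimensional leading subspace additionally guarantees that
#' noise-free activities are fitted exactly by \code{latent} PLS components.
#'
#' @param nMol number of molecules (>= 4).
#' @param nAtoms atoms per molecule.
#' @param sigma activity noise standard deviation (>= 0).
#' @param seed integer seed.
#' When \code{rankLimit} is set the set emulates data generated from exactly
#' that many latent factors: atom positions are shared (no jitter) and each
#' molecule's weight vectors are convex mixtures of \code{rankLimit + 1}
#' prototypes, so the centered descriptor matrix has rank
#' \code{rankLimit} exactly (all field values are linear in the atomic
#' weights at fixed geometry) and the component scan recovers the planted
#' count.
#'
#' @param latent dimension of the planted signal subspace (default 3).
#' @param beta optional planted coefficient vector over the kept, scaled
#'   descriptor columns (overrides the latent-subspace default).
#' @param jitter positional jitter s.d. around the scaffold (Angstrom).
#' @param rankLimit optional exact rank of the centered descriptor matrix.
#' @param spacing,margin,probe,filterSD field-engine settings.
#' @return a \linkS4class{SyntheticSet}.
#' @export
makeToySet <- function(nMol = 20, nAtoms = 8, sigma = 0,
                       seed = 1, latent = 3, beta = NULL, jitter = 0.15,
                       rankLimit = NULL, spacing = 2, margin = 4,
                       probe = probeSpec(), filterSD = 0.05) {
  if (nMol < 4) stop("need at least 4 molecules", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  withPrivateSeed(seed, {
    scaffold <- matrix(stats::runif(nAtoms * 3, -3, 3), ncol = 3)
    if (!is.null(rankLimit)) {
      jitter <- 0
      latent <- min(latent, rankLimit)
      nProto <- rankLimit + 1L
      protoC <- matrix(stats::runif(nProto * nAtoms, -0.5, 0.5), nProto)
      protoH <- matrix(stats::runif(nProto * nAtoms, -1, 1), nProto)
      protoD <- matrix(stats::runif(nProto * nAtoms), nProto)
      protoA <- matrix(stats::runif(nProto * nAtoms), nProto)
      mix <- matrix(stats::runif(nMol * nProto), nMol)
      mix <- mix / rowSums(mix)
    }
    mols <- lapply(seq_len(nMol), function(i) {
      xyz <- scaffold
      if (jitter > 0) {
        xyz <- xyz + matrix(stats::rnorm(nAtoms * 3, sd = jitter), ncol = 3)
      }
      if (!is.null(rankLimit)) {
        cloudMolecule(
          sprintf("toy%02d", i), xyz,
          charge = as.vector(mix[i, ] %*% protoC),
          hydro = as.vector(mix[i, ] %*% protoH),
          hbd = as.vector(mix[i, ] %*% protoD),
          hba = as.vector(mix[i, ] %*% protoA)
        )
      } else {
        cloudMolecule(
          sprintf("toy%02d", i), xyz,
          charge = stats::runif(nAtoms, -0.5, 0.5),
          hydro = stats::runif(nAtoms, -1, 1),
          hbd = stats::runif(nAtoms) < 0.3,
          hba = stats::runif(nAtoms) < 0.3
        )
      }
    })
    names(mols) <- vapply(mols, function(m) m@id, character(1))
    toySpec <- new("AlignmentSpec", templateId = names(mols)[1],
                   variants = list(list(elements = "C",
                                        bonds = matrix(integer(0), 0, 2))),
                   tolerance = 1e6)
    aset <- new("AlignedSet", template = mols[[1]], members = mols,
                coreRmsd = stats::setNames(numeric(nMol), names(mols)),
                coreIdx = stats::setNames(rep(list(integer(0)), nMol),
                                          names(mols)),
                spec = toySpec)
    dm <- computeDescriptorMatrix(aset, probe = probe, filterSD = filterSD,
                                  spacing = spacing, margin = margin)
    X <- plsMatrix(dm)
    if (is.null(beta)) {
      Xc <- scale(X, center = TRUE, scale = FALSE)
      sv <- svd(Xc)
      k <- min(latent, sum(sv$d > 1e-8))
      a <- stats::rnorm(k)
      beta <- as.vector(sv$v[, seq_len(k), drop = FALSE] %*% a)
      sig <- stats::sd(as.vector(Xc %*% beta))
      if (sig > 0) beta <- beta / sig
    } else if (length(beta) != ncol(X)) {
      stop(sprintf("beta must have one entry per kept column (%d)", ncol(X)),
           call. = FALSE)
    }
    y <- as.vector(X %*% beta)
    if (sigma > 0) y <- y + stats::rnorm(nMol, sd = sigma)
    new("SyntheticSet", set = aset, descriptors = dm,
        X = `attr<-`(X, "columns", NULL), beta = as.numeric(beta), y = y,
        sigma = sigma, seed = as.integer(seed))
  })
}
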