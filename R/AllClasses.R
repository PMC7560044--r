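#' @import methods
NULL

#' Molecule: a small molecule with per-atom physicochemical weights
#'
#' Container for one small molecule: element symbols, optional 3-D
#' coordinates (Angstrom), Gasteiger-type partial charges (e), Crippen-type
#' atomic hydrophobicity contributions (unitless atomic logP), and
#' hydrogen-bond donor/acceptor flags. Bonds are stored 1-based. Unprepared
#' molecules (connectivity only) carry NA coordinates.
#'
#' @slot id single molecule identifier.
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge}, \code{hydro}, \code{hbd}, \code{hba},
#'   \code{formal}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   (1-based atom indices).
#' @slot netCharge net formal charge of the molecule.
#' @slot prepared logical; \code{TRUE} once a 3-D conformer, charges and
#'   weights have been assigned.
#' @slot energies numeric; UFF energies (kcal/mol) before and after
#'   minimization for prepared molecules.
#' @slot meta list of provenance notes (force field, charge model, seed).
#'
#' @exportClass Molecule
setClass("Molecule",
  representation(
    id = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    netCharge = "numeric",
    prepared = "logical",
    energies = "numeric",
    meta = "list"
  ),
  prototype(
    netCharge = 0, prepared = FALSE,
    energies = c(pre = NA_real_, post = NA_real_), meta = list()
  )
)

setValidity("Molecule", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "charge", "hydro", "hbd", "hba", "formal")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) == 0L) return("molecule has no atoms")
  if (object@prepared) {
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
      return("prepared molecule has non-finite coordinates")
    }
    if (abs(sum(a$charge) - object@netCharge) > 1e-3) {
      return(sprintf(
        "partial charges sum to %.5f but net formal charge is %g",
        sum(a$charge), object@netCharge
      ))
    }
  }
  TRUE
})

#' AlignmentSpec: the shared-core pattern used for rigid alignment
#'
#' The core is expressed as one or more element-labelled graph variants
#' (vertices = element symbols in a fixed template order, edges = bonds).
#' Each variant is matched as an induced subgraph of the heavy-atom graph;
#' across variants a molecule must match exactly once.
#'
#' @slot templateId identifier of the template molecule.
#' @slot variants list; each element a list with \code{elements} (character)
#'   and \code{bonds} (2-column integer matrix into \code{elements}).
#' @slot tolerance maximum acceptable core RMSD (Angstrom) after alignment.
#'
#' @exportClass AlignmentSpec
setClass("AlignmentSpec",
  representation(templateId = "character", variants = "list",
                 tolerance = "numeric"),
  prototype(tolerance = 1.5)
)

setValidity("AlignmentSpec", function(object) {
  if (length(object@variants) == 0L) return("no core pattern variants")
  for (v in object@variants) {
    if (!all(c("elements", "bonds") %in% names(v))) {
      return("each variant needs 'elements' and 'bonds'")
    }
    if (length(v$bonds) && max(v$bonds) > length(v$elements)) {
      return("bond index out of range")
    }
  }
  if (object@tolerance <= 0) return("tolerance must be positive")
  TRUE
})

#' AlignedSet: molecules rigidly superposed on a common core
#'
#' @slot template the template \linkS4class{Molecule} (also first member).
#' @slot members list of aligned \linkS4class{Molecule} objects.
#' @slot coreRmsd named numeric; residual core RMSD (Angstrom) per member.
#' @slot coreIdx list of integer vectors; per member, the atom indices
#'   matched to the core pattern, in template order.
#' @slot spec the \linkS4class{AlignmentSpec} used.
#'
#' @exportClass AlignedSet
setClass("AlignedSet",
  representation(template = "Molecule", members = "list",
                 coreRmsd = "numeric", coreIdx = "list",
                 spec = "AlignmentSpec")
)

setValidity("AlignedSet", function(object) {
  n <- length(object@members)
  if (n == 0L) return("empty aligned set")
  if (length(object@coreRmsd) != n) return("coreRmsd length mismatch")
  tmpl <- which(names(object@members) == object@template@id)
  if (length(tmpl) == 1L && object@coreRmsd[tmpl] > 1e-9) {
    return("template core RMSD must be 0")
  }
  if (any(object@coreRmsd > object@spec@tolerance)) {
    return("a member exceeds the core RMSD tolerance")
  }
  TRUE
})

#' GridSpec: rectangular field lattice
#'
#' Lattice points are \code{origin + spacing * (i, j, k)} with 0-based
#' indices, the x index varying fastest.
#'
#' @slot origin numeric(3), Angstrom.
#' @slot spacing lattice spacing, Angstrom.
#' @slot dims integer(3), number of points per axis.
#'
#' @exportClass GridSpec
setClass("GridSpec",
  representation(origin = "numeric", spacing = "numeric", dims = "integer")
)

setValidity("GridSpec", function(object) {
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (object@spacing <= 0) return("spacing must be positive")
  if (length(object@dims) != 3L || any(object@dims < 1L)) {
    return("dims must be three counts >= 1")
  }
  TRUE
})

#' ProbeSpec: CoMSIA probe atom
#'
#' The probe carries unit physicochemical weights by convention: charge +1 e,
#' radius 1 Angstrom, hydrophobicity +1, donor and acceptor weights +1, with
#' Gaussian attenuation factor \code{alpha} (per squared Angstrom).
#'
#' @slot alpha Gaussian attenuation factor (1/Angstrom^2), default 0.3.
#' @slot charge probe charge (e).
#' @slot radius probe radius (Angstrom); enters the steric weight cubed.
#' @slot hydro probe hydrophobicity weight.
#' @slot hbd probe hydrogen-bond donor weight.
#' @slot hba probe hydrogen-bond acceptor weight.
#'
#' @exportClass ProbeSpec
setClass("ProbeSpec",
  representation(alpha = "numeric", charge = "numeric", radius = "numeric",
                 hydro = "numeric", hbd = "numeric", hba = "numeric"),
  prototype(alpha = 0.3, charge = 1, radius = 1, hydro = 1, hbd = 1, hba = 1)
)

setValidity("ProbeSpec", function(object) {
  if (object@alpha <= 0) return("alpha must be positive")
  TRUE
})

#' DescriptorMatrix: molecules x grid-point similarity indices, five fields
#'
#' One matrix block per field kind (S, E, H, D, A). Columns with standard
#' deviation below the filter threshold are masked out; each block records a
#' scale factor that equalizes total block variance for PLS (CoMFA-standard
#' style block scaling).
#'
#' @slot blocks named list of numeric matrices (rows = molecules).
#' @slot mask named list of logical vectors (kept columns per block).
#' @slot scaling named numeric; per-block scale factor (NA when a block has
#'   no kept columns).
#' @slot grid the \linkS4class{GridSpec}.
#' @slot probe the \linkS4class{ProbeSpec}.
#' @slot filterSD column standard-deviation filter threshold.
#'
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
  representation(blocks = "list", mask = "list", scaling = "numeric",
                 grid = "GridSpec", probe = "ProbeSpec", filterSD = "numeric")
)

setValidity("DescriptorMatrix", function(object) {
  kinds <- c("S", "E", "H", "D", "A")
  if (!identical(names(object@blocks), kinds)) {
    return("blocks must be named S, E, H, D, A")
  }
  for (k in kinds) {
    if (!all(is.finite(object@blocks[[k]]))) {
      return(sprintf("non-finite values in block %s", k))
    }
    if (length(object@mask[[k]]) != ncol(object@blocks[[k]])) {
      return(sprintf("mask length mismatch in block %s", k))
    }
  }
  TRUE
})

#' PLSModel: fitted partial least squares regression
#'
#' Coefficients are stored on the (centered, block-scaled) model scale used
#' for fitting; \code{coefficients(model, scale = "raw")} returns them on the
#' original descriptor scale.
#'
#' @slot nComponents number of latent components.
#' @slot coefficients numeric vector, model-scale regression vector.
#' @slot intercept intercept on the model scale.
#' @slot xMeans column means used for centering.
#' @slot yMean response mean.
#' @slot stats list with \code{q2}, \code{r2}, \code{SEE}, \code{F}.
#' @slot fieldContributions named fractions per field (empty for plain
#'   matrix fits); sums to 1 when present.
#' @slot columns data.frame describing model columns (field, grid point
#'   index, raw-scale sd, block scale); zero rows for plain matrix fits.
#' @slot meta list of provenance (grid, probe, scaling, filter, fit call).
#'
#' @exportClass PLSModel
setClass("PLSModel",
  representation(
    nComponents = "integer", coefficients = "numeric", intercept = "numeric",
    xMeans = "numeric", yMean = "numeric", stats = "list",
    fieldContributions = "numeric", columns = "data.frame", meta = "list"
  ),
  prototype(fieldContributions = numeric(0),
            columns = data.frame(), meta = list())
)

setValidity("PLSModel", function(object) {
  if (object@nComponents < 1L) return("nComponents must be >= 1")
  if (length(object@fieldContributions)) {
    if (abs(sum(object@fieldContributions) - 1) > 1e-9) {
      return("field contributions must sum to 1")
    }
  }
  TRUE
})

#' CVResult: leave-one-out component scan
#'
#' @slot q2 named numeric; LOO q-squared per candidate component count.
#' @slot chosenN selected component count (smallest count attaining the
#'   maximal q-squared).
#'
#' @exportClass CVResult
setClass("CVResult",
  representation(q2 = "numeric", chosenN = "integer")
)

setValidity("CVResult", function(object) {
  if (length(object@q2) == 0L) return("empty q2 scan")
  best <- max(object@q2)
  if (abs(object@q2[object@chosenN] - best) > 1e-12) {
    return("chosenN does not attain the maximal q2")
  }
  smaller <- which(abs(object@q2 - best) <= 1e-12)[1L]
  if (object@chosenN != smaller) return("ties must break toward smaller n")
  TRUE
})

#' ValidationReport: external validation via predictive r-squared
#'
#' \code{r2pred = 1 - PRESS/SD} where PRESS sums squared
#' (experimental - predicted) deviations over the test set and SD sums
#' squared deviations of test experimental values from the training-set
#' experimental mean.
#'
#' @slot press numeric, PRESS (squared response units).
#' @slot sd numeric, SD (squared response units).
#' @slot r2pred the predictive determination coefficient.
#' @slot table per-compound data.frame: id, experimental, predicted,
#'   relative error (percent).
#'
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(press = "numeric", sd = "numeric", r2pred = "numeric",
                 table = "data.frame")
)

setValidity("ValidationReport", function(object) {
  if (object@sd <= 0) return("SD must be positive")
  if (abs(object@r2pred - (1 - object@press / object@sd)) > 1e-12) {
    return("r2pred must equal 1 - PRESS/SD")
  }
  TRUE
})

#' ContourMap: STDEV*COEFF values and favored/disfavored masks
#'
#' Per field and grid point, the product of the descriptor column standard
#' deviation and the PLS coefficient. Masked (filtered) columns carry value 0
#' and are excluded from percentile computation and masks.
#'
#' @slot values named list (S, E, H, D, A) of numeric vectors over grid
#'   points.
#' @slot kept named list of logical vectors (columns that entered the model).
#' @slot favored named list of logical masks (favored points).
#' @slot disfavored named list of logical masks (disfavored points).
#' @slot percentiles numeric(2): favored and disfavored percentile.
#' @slot grid the \linkS4class{GridSpec}.
#'
#' @exportClass ContourMap
setClass("ContourMap",
  representation(values = "list", kept = "list", favored = "list",
                 disfavored = "list", percentiles = "numeric",
                 grid = "GridSpec")
)

setValidity("ContourMap", function(object) {
  for (k in names(object@values)) {
    f <- object@favored[[k]]; d <- object@disfavored[[k]]
    if (length(f) && length(d) && any(f & d)) {
      return("favored and disfavored masks overlap")
    }
  }
  TRUE
})

#' Trajectory: coordinate frames with an atom-to-residue mapping
#'
#' @slot coords numeric array frames x atoms x 3 (Angstrom).
#' @slot residueIds per-atom residue identifier (e.g. "GLN149").
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", residueIds = "character")
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L) {
    return("coords must be frames x atoms x 3")
  }
  if (length(object@residueIds) != d[2]) {
    return("residueIds length must equal the atom count")
  }
  TRUE
})

#' SyntheticSet: aligned toy molecules with a planted linear field model
#'
#' Activities are \code{y = X beta + noise} where X is the actual
#' (kept, block-scaled) descriptor matrix computed by the CoMSIA engine, so
#' the planted coefficients are recoverable by construction.
#'
#' @slot set the \linkS4class{AlignedSet} of toy molecules.
#' @slot descriptors the \linkS4class{DescriptorMatrix}.
#' @slot X the assembled model matrix (kept, scaled columns).
#' @slot beta planted coefficient vector over the columns of X.
#' @slot y activities.
#' @slot sigma noise standard deviation.
#' @slot seed generator seed.
#'
#' @exportClass SyntheticSet
setClass("SyntheticSet",
  representation(set = "AlignedSet", descriptors = "DescriptorMatrix",
                 X = "matrix", beta = "numeric", y = "numeric",
                 sigma = "numeric", seed = "integer")
)

setValidity("SyntheticSet", function(object) {
  if (length(object@y) != nrow(object@X)) return("y/X row mismatch")
  if (length(object@beta) != ncol(object@X)) return("beta/X column mismatch")
  if (object@sigma < 0) return("sigma must be non-negative")
  TRUE
})
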