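#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("moleculeId", "Molecule", function(object) object@id)

#' @rdname accessors
setMethod("atoms", "Molecule", function(object) object@atoms)

#' @rdname accessors
setMethod("bonds", "Molecule", function(object) object@bonds)

#' @rdname accessors
setMethod("nAtoms", "Molecule", function(object) nrow(object@atoms))

#' @rdname accessors
setMethod("coords", "Molecule", function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
})

#' @rdname accessors
setMethod("netCharge", "Molecule", function(object) object@netCharge)

#' @rdname accessors
setMethod("isPrepared", "Molecule", function(object) object@prepared)

#' @rdname accessors
setMethod("members", "AlignedSet", function(object) object@members)

#' @rdname accessors
setMethod("coreRmsd", "AlignedSet", function(object) object@coreRmsd)

#' @rdname accessors
setMethod("keptMask", "DescriptorMatrix", function(object) object@mask)

#' @rdname accessors
setMethod("blockScaling", "DescriptorMatrix", function(object) object@scaling)

#' @rdname accessors
setMethod("fieldBlock", "DescriptorMatrix", function(object, kind) {
  kind <- match.arg(kind, c("S", "E", "H", "D", "A"))
  object@blocks[[kind]]
})

#' @rdname accessors
setMethod("nComponents", "PLSModel", function(object) object@nComponents)

#' @rdname accessors
setMethod("modelCoefficients", "PLSModel", function(object,
                                                   scale = c("model", "raw")) {
  scale <- match.arg(scale)
  b <- object@coefficients
  if (scale == "raw") {
    if (nrow(object@columns) == 0L) return(b)
    b <- b * object@columns$blockScale
  }
  b
})

#' @rdname accessors
setMethod("modelStatsOf", "PLSModel", function(object) object@stats)

#' @rdname accessors
setMethod("fieldContributionsOf", "PLSModel",
          function(object) object@fieldContributions)

#' @rdname accessors
setMethod("chosenComponents", "CVResult", function(object) object@chosenN)

#' @rdname accessors
setMethod("q2Scan", "CVResult", function(object) object@q2)

#' @rdname accessors
setMethod("r2Pred", "ValidationReport", function(object) object@r2pred)

#' @rdname accessors
setMethod("validationTable", "ValidationReport", function(object) object@table)

#' @rdname accessors
setMethod("nFrames", "Trajectory", function(object) dim(object@coords)[1L])

setMethod("show", "Molecule", function(object) {
  cat(sprintf(
    "Molecule '%s': %d atoms (%d heavy), net charge %+g, %s\n",
    object@id, nrow(object@atoms), sum(object@atoms$element != "H"),
    object@netCharge,
    if (object@prepared) "prepared (3-D)" else "connectivity only"
  ))
})

setMethod("show", "AlignedSet", function(object) {
  cat(sprintf(
    "AlignedSet: %d molecules on template '%s' (max core RMSD %.3f A)\n",
    length(object@members), object@template@id, max(object@coreRmsd)
  ))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
    object@dims[1], object@dims[2], object@dims[3], object@spacing,
    object@origin[1], object@origin[2], object@origin[3]
  ))
})

setMethod("show", "DescriptorMatrix", function(object) {
  kept <- vapply(object@mask, sum, integer(1))
  cat(sprintf(
    "DescriptorMatrix: %d molecules x %d grid points per field\n",
    nrow(object@blocks$S), ncol(object@blocks$S)
  ))
  cat("  kept columns: ",
      paste(sprintf("%s=%d", names(kept), kept), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "PLSModel", function(object) {
  s <- object@stats
  cat(sprintf("PLSModel: %d components\n", object@nComponents))
  if (length(s)) {
    cat(sprintf("  q2 = %.4f, r2 = %.4f, SEE = %.4f, F = %.3f\n",
                s$q2, s$r2, s$SEE, s$F))
  }
  if (length(object@fieldContributions)) {
    cat("  field contributions: ",
        paste(sprintf("%s=%.1f%%", names(object@fieldContributions),
                      100 * object@fieldContributions), collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: chosen n = %d (q2 = %.4f)\n",
              object@chosenN, object@q2[object@chosenN]))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: r2pred = %.4f (PRESS = %.5f, SD = %.5f)\n",
              object@r2pred, object@press, object@sd))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (%d residues)\n",
              d[1], d[2], length(unique(object@residueIds))))
})
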