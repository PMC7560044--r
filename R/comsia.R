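#' @include AllClasses.R utils.R
NULL

FIELD_KINDS <- c("S", "E", "H", "D", "A")

#' Construct a ProbeSpec
#'
#' @param alpha Gaussian attenuation factor (1/Angstrom^2); default 0.3, the
#'   conventional CoMSIA value.
#' @param charge,radius,hydro,hbd,hba probe weights (defaults +1 each;
#'   radius in Angstrom, entering the steric weight as radius cubed).
#' @return a \linkS4class{ProbeSpec}.
#' @export
probeSpec <- function(alpha = 0.3, charge = 1, radius = 1, hydro = 1,
                      hbd = 1, hba = 1) {
  new("ProbeSpec", alpha = alpha, charge = charge, radius = radius,
      hydro = hydro, hbd = hbd, hba = hba)
}

#' Build the field lattice around an aligned set
#'
#' The box encloses every atom of every member plus \code{margin} on all
#' sides; lattice points sit at \code{origin + spacing * (i, j, k)} with
#' 0-based indices, x varying fastest.
#'
#' @param aset an \linkS4class{AlignedSet}, or an atom coordinate matrix.
#' @param spacing lattice spacing (Angstrom), default 2.
#' @param margin margin (Angstrom) added on all sides, default 4.
#' @return a \linkS4class{GridSpec}.
#' @export
buildGrid <- function(aset, spacing = 2, margin = 4) {
  xyz <- if (is(aset, "AlignedSet")) {
    do.call(rbind, lapply(aset@members, coords))
  } else as.matrix(aset)
  if (nrow(xyz) == 0L) stop("cannot build a grid around an empty set",
                            call. = FALSE)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  new("GridSpec", origin = lo, spacing = spacing, dims = dims)
}

#' @rdname accessors
setMethod("gridPoints", "GridSpec", function(object) {
  d <- object@dims
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]) - 1L,
                               j = seq_len(d[2]) - 1L,
                               k = seq_len(d[3]) - 1L))
  sweep(ijk * object@spacing, 2, object@origin, "+")
})

# per-atom weight vector for a field kind (includes the probe factor)
atomWeights <- function(m, kind, probe) {
  a <- m@atoms
  switch(kind,
    S = probe@radius^3 * vdwRadius(a$element)^3,
    E = probe@charge * a$charge,
    H = probe@hydro * a$hydro,
    D = probe@hbd * as.numeric(a$hbd),
    A = probe@hba * as.numeric(a$hba),
    stop(sprintf("unknown field kind '%s'", kind), call. = FALSE)
  )
}

#' CoMSIA similarity-index value of one field at one point
#'
#' \code{A(q) = - sum_i w_probe * w_i * exp(-alpha * r_iq^2)}, summed over
#' every atom (no distance cutoff).
#'
#' @param m a prepared \linkS4class{Molecule}.
#' @param point numeric(3) or an n x 3 matrix of query points (Angstrom).
#' @param kind one of \code{"S"}, \code{"E"}, \code{"H"}, \code{"D"},
#'   \code{"A"}.
#' @param probe a \linkS4class{ProbeSpec}.
#' @return numeric similarity index value(s).
#' @export
fieldValue <- function(m, point, kind, probe = probeSpec()) {
  kind <- match.arg(kind, FIELD_KINDS)
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  w <- atomWeights(m, kind, probe)
  G <- gaussMatrix(coords(m), pts, probe@alpha)
  v <- -as.vector(w %*% G)
  if (nrow(pts) == 1L) v[[1L]] else v
}

# atoms x points matrix of exp(-alpha * d^2)
gaussMatrix <- function(xyz, pts, alpha) {
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(xyz)), rowSums(pts^2)) - 2 * xyz %*% t(pts)
  d2[d2 < 0] <- 0
  exp(-alpha * d2)
}

#' Compute the five-field descriptor matrix of an aligned set
#'
#' Fills one molecules x grid-points block per field, masks columns whose
#' standard deviation falls below \code{filterSD} (similarity units), and
#' records per-block scale factors that give every block equal total
#' variance in the assembled PLS matrix.
#'
#' @param aset an \linkS4class{AlignedSet}.
#' @param grid a \linkS4class{GridSpec}; built from \code{aset} with the
#'   default spacing/margin when \code{NULL}.
#' @param probe a \linkS4class{ProbeSpec}.
#' @param filterSD column standard-deviation filter threshold, default 0.05.
#' @param spacing,margin grid parameters used when \code{grid} is NULL.
#' @return a \linkS4class{DescriptorMatrix}.
#' @export
computeDescriptorMatrix <- function(aset, grid = NULL, probe = probeSpec(),
                                    filterSD = 0.05, spacing = 2, margin = 4) {
  stopifnot(is(aset, "AlignedSet"))
  if (is.null(grid)) grid <- buildGrid(aset, spacing = spacing, margin = margin)
  pts <- gridPoints(grid)
  n <- length(aset@members)
  blocks <- lapply(FIELD_KINDS, function(k) {
    matrix(0, n, nrow(pts), dimnames = list(names(aset@members), NULL))
  })
  names(blocks) <- FIELD_KINDS
  for (i in seq_len(n)) {
    m <- aset@members[[i]]
    G <- gaussMatrix(coords(m), pts, probe@alpha)
    for (k in FIELD_KINDS) {
      blocks[[k]][i, ] <- -as.vector(atomWeights(m, k, probe) %*% G)
    }
  }
  mask <- lapply(blocks, function(B) {
    apply(B, 2, stats::sd) >= filterSD
  })
  scaling <- vapply(FIELD_KINDS, function(k) {
    kept <- mask[[k]]
    if (!any(kept)) return(NA_real_)
    tv <- sum(apply(blocks[[k]][, kept, drop = FALSE], 2, stats::var))
    if (tv <= 0) NA_real_ else 1 / sqrt(tv)
  }, numeric(1))
  new("DescriptorMatrix", blocks = blocks, mask = mask, scaling = scaling,
      grid = grid, probe = probe, filterSD = filterSD)
}

#' Assemble the PLS model matrix from a DescriptorMatrix
#'
#' Concatenates the kept columns of every block, multiplied by the block
#' scale factor when \code{scaled = TRUE}. Column metadata (field, grid point
#' index, raw-scale sd, block scale) is attached as attribute
#' \code{"columns"}.
#'
#' @param dm a \linkS4class{DescriptorMatrix}.
#' @param scaled apply block scaling (default TRUE).
#' @return numeric matrix, molecules x kept columns.
#' @export
plsMatrix <- function(dm, scaled = TRUE) {
  parts <- list()
  info <- list()
  for (k in FIELD_KINDS) {
    kept <- which(dm@mask[[k]])
    if (!length(kept)) next
    B <- dm@blocks[[k]][, kept, drop = FALSE]
    s <- dm@scaling[[k]]
    if (is.na(s)) next
    sdRaw <- apply(B, 2, stats::sd)
    if (scaled) B <- B * s
    colnames(B) <- paste0(k, ":", kept)
    parts[[k]] <- B
    info[[k]] <- data.frame(field = k, point = kept, sdRaw = sdRaw,
                            blockScale = if (scaled) s else 1,
                            stringsAsFactors = FALSE)
  }
  if (!length(parts)) stop("no kept columns in any block", call. = FALSE)
  X <- do.call(cbind, parts)
  attr(X, "columns") <- do.call(rbind, c(info, list(make.row.names = FALSE)))
  X
}

#' Export a descriptor matrix as a dense delimited point table
#'
#' @param dm a \linkS4class{DescriptorMatrix}.
#' @param path output path (tab-separated); when NULL the data.frame is
#'   returned without writing.
#' @return (invisibly) the exported data.frame with columns x, y, z, field,
#'   point, kept, and one value column per molecule.
#' @export
exportDescriptors <- function(dm, path = NULL) {
  pts <- gridPoints(dm@grid)
  out <- do.call(rbind, lapply(FIELD_KINDS, function(k) {
    B <- dm@blocks[[k]]
    df <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], field = k,
                     point = seq_len(ncol(B)), kept = dm@mask[[k]])
    cbind(df, as.data.frame(t(B)))
  }))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(out)
}
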