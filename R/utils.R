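#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation \code{R} and translation that minimize the RMSD
#' between the rows of \code{P} (moving) and \code{Q} (target):
#' \code{P \%*\% R + t} approximates \code{Q}.
#'
#' @param P n x 3 matrix of moving coordinates.
#' @param Q n x 3 matrix of target coordinates.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd} after superposition.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tr <- cq - as.vector(cp %*% R)
  moved <- P %*% R + matrix(tr, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

applyRigid <- function(X, rotation, translation) {
  X %*% rotation + matrix(translation, nrow(X), 3, byrow = TRUE)
}

#' Bondi van der Waals radii (Angstrom) used for steric weights
#'
#' @param elements character vector of element symbols.
#' @return numeric radii; unlisted elements fall back to 1.75 A.
#' @export
vdwRadius <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Si = 2.10, Br = 1.85, I = 1.98, B = 1.92)
  r <- unname(tab[elements])
  r[is.na(r)] <- 1.75
  r
}

# run a block with a private RNG stream, restoring the caller's state
withPrivateSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}
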