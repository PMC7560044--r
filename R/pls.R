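#' @include AllClasses.R comsia.R
NULL

# NIPALS PLS1 on a centered problem; deterministic, convergence-free for a
# single response (each component is a closed-form power step).
nipalsPLS1 <- function(Xc, yc, n) {
  p <- ncol(Xc)
  W <- matrix(0, p, n)
  P <- matrix(0, p, n)
  qv <- numeric(n)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(n)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf(
        "component %d exceeds the effective rank of the predictors", a
      ), call. = FALSE)
    }
    w <- w / nw
    t <- as.vector(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      stop(sprintf(
        "component %d exceeds the effective rank of the predictors", a
      ), call. = FALSE)
    }
    pvec <- crossprod(Xd, t) / tt
    qv[a] <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - qv[a] * t
    W[, a] <- w
    P[, a] <- pvec
  }
  B <- W %*% solve(crossprod(P, W), qv)
  as.vector(B)
}

#' Fit a PLS regression (NIPALS, single response)
#'
#' Predictors are mean-centered internally; the response is mean-centered.
#' The fit is fully deterministic. Supply either a plain numeric matrix or a
#' \linkS4class{DescriptorMatrix} (whose kept, block-scaled columns are
#' used).
#'
#' @param X numeric matrix (samples x descriptors) or a
#'   \linkS4class{DescriptorMatrix}.
#' @param y numeric response (e.g. log fb).
#' @param n number of latent components.
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y, n) {
  colsInfo <- data.frame()
  meta <- list()
  if (is(X, "DescriptorMatrix")) {
    meta <- list(grid = X@grid, probe = X@probe, scaling = X@scaling,
                 filterSD = X@filterSD)
    Xm <- plsMatrix(X)
    colsInfo <- attr(Xm, "columns")
    X <- Xm
  }
  X <- as.matrix(X)
  n <- as.integer(n)
  if (length(y) != nrow(X)) stop("rows of X must match length(y)",
                                 call. = FALSE)
  if (nrow(X) < n + 2L) {
    stop("need at least n + 2 samples to fit n components", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("constant response: nothing to model",
                              call. = FALSE)
  xm <- colMeans(X)
  ym <- mean(y)
  B <- nipalsPLS1(sweep(X, 2, xm), y - ym, n)
  mod <- new("PLSModel", nComponents = n, coefficients = B,
             intercept = ym - sum(xm * B), xMeans = xm, yMean = ym,
             stats = list(), fieldContributions = numeric(0),
             columns = colsInfo, meta = meta)
  yhat <- as.vector(X %*% B) + mod@intercept
  mod@stats <- tryCatch(modelStats(y, yhat, n), error = function(e) list())
  if (nrow(colsInfo)) {
    mod@fieldContributions <- fieldContributions(mod)
  }
  mod
}

#' Predict from a fitted PLSModel
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newX matrix on the same (kept, scaled) column layout used in the
#'   fit, or a \linkS4class{DescriptorMatrix} with matching layout.
#' @return numeric predictions.
#' @export
predictPLS <- function(object, newX) {
  stopifnot(is(object, "PLSModel"))
  if (is(newX, "DescriptorMatrix")) newX <- plsMatrix(newX)
  newX <- as.matrix(newX)
  if (ncol(newX) != length(object@coefficients)) {
    stop("column count does not match the fitted model", call. = FALSE)
  }
  as.vector(newX %*% object@coefficients) + object@intercept
}

#' Leave-one-out cross-validated q-squared
#'
#' \code{q2 = 1 - sum (y_i - yhat_(-i))^2 / sum (y_i - mean(y))^2}, with the
#' reference mean taken over all training responses; may be negative.
#'
#' @inheritParams fitPLS
#' @return the LOO q-squared.
#' @export
looQ2 <- function(X, y, n) {
  if (is(X, "DescriptorMatrix")) X <- plsMatrix(X)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 3L) stop("need at least 3 samples for leave-one-out", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero variance in y", call. = FALSE)
  press <- 0
  for (i in seq_len(N)) {
    fit <- fitPLS(X[-i, , drop = FALSE], y[-i], n)
    press <- press + (y[i] - predictPLS(fit, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Scan component counts by leave-one-out q-squared
#'
#' @inheritParams fitPLS
#' @param maxN largest component count to scan.
#' @return a \linkS4class{CVResult}; the chosen count is the smallest one
#'   attaining the maximal q-squared (deterministic tie-break).
#' @export
selectComponents <- function(X, y, maxN) {
  if (is(X, "DescriptorMatrix")) X <- plsMatrix(X)
  X <- as.matrix(X)
  maxN <- as.integer(min(maxN, nrow(X) - 3L, ncol(X)))
  if (maxN < 1L) stop("too few samples to scan components", call. = FALSE)
  q2 <- vapply(seq_len(maxN), function(n) {
    tryCatch(looQ2(X, y, n), error = function(e) -Inf)
  }, numeric(1))
  names(q2) <- seq_len(maxN)
  chosen <- which(abs(q2 - max(q2)) <= 1e-12)[1L]
  new("CVResult", q2 = q2, chosenN = as.integer(chosen))
}

#' Training-fit statistics: r-squared, SEE and F
#'
#' \code{r2 = 1 - RSS/TSS}; \code{SEE = sqrt(RSS / (N - n - 1))};
#' \code{F = (r2/n) / ((1 - r2)/(N - n - 1))}. A perfect fit returns
#' \code{F = Inf}.
#'
#' @param y observed responses.
#' @param yhat fitted values.
#' @param n number of model components.
#' @return list with \code{r2}, \code{SEE}, \code{F} (and \code{q2} slot
#'   left to the caller).
#' @export
modelStats <- function(y, yhat, n) {
  N <- length(y)
  stopifnot(length(yhat) == N)
  if (N <= n + 1L) stop("need more than n + 1 samples", call. = FALSE)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero variance in y", call. = FALSE)
  r2 <- 1 - rss / tss
  see <- sqrt(rss / (N - n - 1))
  f <- if (rss == 0) Inf else (r2 / n) / ((1 - r2) / (N - n - 1))
  list(r2 = r2, SEE = see, F = f)
}

#' Per-field contributions of a fitted CoMSIA model
#'
#' \code{contribution_k = sum_{j in field k} |coef_j * sd_j| / total}, with
#' coefficients and column standard deviations taken on the model (scaled)
#' descriptor scale. Fractions sum to 1.
#'
#' @param model a \linkS4class{PLSModel} fitted on a
#'   \linkS4class{DescriptorMatrix}, or a plain coefficient vector.
#' @param sds column standard deviations (only for the vector form).
#' @param fields field label per column (only for the vector form).
#' @return named numeric fractions.
#' @export
fieldContributions <- function(model, sds = NULL, fields = NULL) {
  if (is(model, "PLSModel")) {
    if (nrow(model@columns) == 0L) {
      stop("model carries no field metadata", call. = FALSE)
    }
    coef <- model@coefficients
    sds <- model@columns$sdRaw * model@columns$blockScale
    fields <- model@columns$field
  } else {
    coef <- as.numeric(model)
  }
  mass <- abs(coef * sds)
  tot <- sum(mass)
  if (tot == 0) stop("all coefficient-sd products are zero", call. = FALSE)
  out <- vapply(FIELD_KINDS, function(k) sum(mass[fields == k]) / tot,
                numeric(1))
  out[!is.na(out)]
}

#' Fit a complete CoMSIA model on an aligned set
#'
#' Convenience wrapper: builds the grid and descriptor matrix, scans the
#' component count by leave-one-out q-squared, fits the final PLS model, and
#' attaches cross-validation and training statistics plus per-field
#' contributions.
#'
#' @param aset an \linkS4class{AlignedSet} (or a precomputed
#'   \linkS4class{DescriptorMatrix}).
#' @param y activities (log fb), one per member, in member order.
#' @param maxComponents largest component count scanned (default 10).
#' @param probe,filterSD,spacing,margin forwarded to
#'   \code{\link{computeDescriptorMatrix}}.
#' @return list with \code{model} (\linkS4class{PLSModel}), \code{cv}
#'   (\linkS4class{CVResult}) and \code{descriptors}
#'   (\linkS4class{DescriptorMatrix}).
#' @export
comsiaModel <- function(aset, y, maxComponents = 10, probe = probeSpec(),
                        filterSD = 0.05, spacing = 2, margin = 4) {
  dm <- if (is(aset, "DescriptorMatrix")) aset else
    computeDescriptorMatrix(aset, probe = probe, filterSD = filterSD,
                            spacing = spacing, margin = margin)
  X <- plsMatrix(dm)
  cv <- selectComponents(X, y, maxComponents)
  model <- fitPLS(dm, y, chosenComponents(cv))
  model@stats$q2 <- unname(q2Scan(cv)[chosenComponents(cv)])
  list(model = model, cv = cv, descriptors = dm)
}

#' Serialize a PLSModel to a self-describing JSON document
#'
#' @param model a \linkS4class{PLSModel}.
#' @param path output path; when NULL the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
serializeModel <- function(model, path = NULL) {
  stopifnot(is(model, "PLSModel"))
  doc <- list(
    nComponents = model@nComponents,
    intercept = model@intercept,
    coefficients = model@coefficients,
    xMeans = model@xMeans,
    yMean = model@yMean,
    stats = model@stats,
    fieldContributions = as.list(model@fieldContributions),
    columns = model@columns
  )
  if (length(model@meta)) {
    g <- model@meta$grid
    p <- model@meta$probe
    doc$grid <- if (!is.null(g)) list(origin = g@origin, spacing = g@spacing,
                                      dims = g@dims)
    doc$probe <- if (!is.null(p)) list(alpha = p@alpha, charge = p@charge,
                                       radius = p@radius, hydro = p@hydro,
                                       hbd = p@hbd, hba = p@hba)
    doc$blockScaling <- as.list(model@meta$scaling)
    doc$filterSD <- model@meta$filterSD
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
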