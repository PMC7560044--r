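#' @include AllClasses.R pls.R
NULL

#' STDEV*COEFF contour values of a fitted CoMSIA model
#'
#' For every kept column the contour value is the product of the raw-scale
#' column standard deviation and the model coefficient on the raw descriptor
#' scale (the product is invariant to the block scaling). Masked columns
#' carry value 0 and are excluded from percentile thresholds.
#'
#' @param model a \linkS4class{PLSModel} fitted on \code{dm}.
#' @param dm the \linkS4class{DescriptorMatrix} used in the fit.
#' @param favPct,disfavPct favored/disfavored percentiles, defaults 80/20.
#' @return a \linkS4class{ContourMap} with thresholded masks.
#' @export
stdevCoeffMap <- function(model, dm, favPct = 80, disfavPct = 20) {
  stopifnot(is(model, "PLSModel"), is(dm, "DescriptorMatrix"))
  if (nrow(model@columns) == 0L) {
    stop("model was not fitted on a DescriptorMatrix", call. = FALSE)
  }
  npts <- ncol(dm@blocks$S)
  cols <- model@columns
  if (!all(cols$point <= npts) ||
      !identical(sort(unique(cols$field)),
                 sort(names(which(vapply(dm@mask, any, logical(1))))))) {
    stop("model and descriptor matrix layouts do not match", call. = FALSE)
  }
  values <- lapply(FIELD_KINDS, function(k) numeric(npts))
  kept <- lapply(FIELD_KINDS, function(k) logical(npts))
  names(values) <- names(kept) <- FIELD_KINDS
  sc <- cols$sdRaw * cols$blockScale  # scaled-column sd
  for (k in unique(cols$field)) {
    sel <- cols$field == k
    # sd_scaled * coef_scaled == sd_raw * coef_raw
    values[[k]][cols$point[sel]] <- sc[sel] * model@coefficients[sel]
    kept[[k]][cols$point[sel]] <- TRUE
  }
  map <- new("ContourMap", values = values, kept = kept,
             favored = lapply(kept, function(x) x & FALSE),
             disfavored = lapply(kept, function(x) x & FALSE),
             percentiles = c(favored = favPct, disfavored = disfavPct),
             grid = dm@grid)
  thresholdContours(map, favPct, disfavPct)
}

#' Threshold contour values into favored/disfavored masks
#'
#' Percentiles are computed per field over kept columns only, with linear
#' interpolation (\code{quantile} type 7). A point is favored when its value
#' is at least the favored percentile and strictly above the disfavored one
#' (and conversely), so degenerate all-equal fields produce empty masks and
#' the two masks can never overlap.
#'
#' @param map a \linkS4class{ContourMap}.
#' @param favPct favored percentile (default 80).
#' @param disfavPct disfavored percentile (default 20); must be strictly
#'   below \code{favPct}.
#' @return the map with updated masks.
#' @export
thresholdContours <- function(map, favPct = 80, disfavPct = 20) {
  stopifnot(is(map, "ContourMap"))
  if (favPct <= disfavPct) {
    stop("favored percentile must exceed the disfavored percentile",
         call. = FALSE)
  }
  for (k in names(map@values)) {
    keep <- map@kept[[k]]
    fav <- dis <- logical(length(keep))
    if (any(keep)) {
      v <- map@values[[k]][keep]
      qf <- stats::quantile(v, favPct / 100, type = 7, names = FALSE)
      qd <- stats::quantile(v, disfavPct / 100, type = 7, names = FALSE)
      fav[keep] <- v >= qf & v > qd
      dis[keep] <- v <= qd & v < qf
    }
    map@favored[[k]] <- fav
    map@disfavored[[k]] <- dis
  }
  map@percentiles <- c(favored = favPct, disfavored = disfavPct)
  validObject(map)
  map
}

#' Summarize contour favorability around labelled substitution sites
#'
#' For each site and field, the grid points within \code{radius} of the site
#' are tallied; the site is flagged favored or disfavored by majority of
#' favored vs disfavored points, neutral otherwise. Sites with no grid point
#' in range are neutral, with a warning.
#'
#' @param map a thresholded \linkS4class{ContourMap}.
#' @param sites numeric matrix of site coordinates (rows named by site
#'   label), Angstrom.
#' @param radius sphere radius around each site, Angstrom (default 3).
#' @return data.frame: site, field, favored points, disfavored points, flag.
#' @export
summarizeSites <- function(map, sites, radius = 3) {
  stopifnot(is(map, "ContourMap"))
  sites <- as.matrix(sites)
  if (is.null(rownames(sites))) {
    rownames(sites) <- paste0("site", seq_len(nrow(sites)))
  }
  pts <- gridPoints(map@grid)
  out <- list()
  for (s in rownames(sites)) {
    d2 <- rowSums(sweep(pts, 2, sites[s, ])^2)
    near <- d2 <= radius^2
    if (!any(near)) {
      warning(sprintf("site '%s': no grid points within %.2f A", s, radius))
    }
    for (k in names(map@values)) {
      nf <- sum(map@favored[[k]][near])
      nd <- sum(map@disfavored[[k]][near])
      flag <- if (nf > nd) "favored" else if (nd > nf) "disfavored"
              else "neutral"
      out[[length(out) + 1L]] <- data.frame(
        site = s, field = k, favoredPoints = nf, disfavoredPoints = nd,
        flag = flag, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Export a contour map as a delimited point table
#'
#' @param map a \linkS4class{ContourMap}.
#' @param path output path (tab-separated); NULL to return only.
#' @return (invisibly) data.frame with x, y, z, field, value, class.
#' @export
exportContours <- function(map, path = NULL) {
  pts <- gridPoints(map@grid)
  out <- do.call(rbind, lapply(names(map@values), function(k) {
    cls <- rep("neutral", nrow(pts))
    cls[!map@kept[[k]]] <- "masked"
    cls[map@favored[[k]]] <- "favored"
    cls[map@disfavored[[k]]] <- "disfavored"
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], field = k,
               value = map@values[[k]], class = cls,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

# ---- derivative enumeration ------------------------------------------------

# Substituent fragments as SMILES attachments. Site 1 is the exocyclic
# substituent on the azabicyclohexane apex carbon (amine in the parent);
# site 5 is ring position 5 of the naphthyridone (H in the parent).
GROUP_SMILES <- c(
  "NH2" = "N", "H" = "", "CH3" = "C", "C2H3" = "C=C", "C2H5" = "CC",
  "C3H7" = "CCC", "NO2" = "[N+](=O)[O-]", "OCH3" = "OC", "SH" = "S",
  "SiH3" = "[SiH3]", "PH2" = "P"
)

trovaSmilesWith <- function(site1, site5) {
  g1 <- GROUP_SMILES[[site1]]
  s1 <- if (nzchar(g1)) sprintf("(%s)", g1) else ""
  g5 <- if (nzchar(site5)) GROUP_SMILES[[site5]] else ""
  s5 <- if (nzchar(g5)) sprintf("(%s)", g5) else ""
  sprintf(
    "OC(=O)C1=CN(c2ccc(F)cc2F)c3nc(N4CC5C%sC5C4)c(F)c%sc3C1=O",
    s1, s5
  )
}

#' The registered trovafloxacin substitution scheme
#'
#' The 16-derivative registry: the site-1 exocyclic amine replaced by H,
#' CH3, C2H3, C2H5, C3H7, NO2, OCH3 or SH, the ring-5 hydrogen by SiH3 or
#' PH2, and six bis-substituted combinations. Names follow the
#' "1-X-5-Y-Trovafloxacin" convention.
#'
#' @return data.frame with columns \code{name}, \code{site1}, \code{site5}.
#' @export
trovafloxacinRegistry <- function() {
  data.frame(
    name = paste0("Derivative-", 1:16),
    site1 = c("NO2", "C2H5", "C3H7", "NH2", "NH2", "NO2", "OCH3", "OCH3",
              "SH", "C2H5", "C3H7", "H", "CH3", "C2H3", "OCH3", "SH"),
    site5 = c("", "", "", "SiH3", "PH2", "SiH3", "SiH3", "PH2", "PH2",
              "PH2", "PH2", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

#' Enumerate derivative structures from a substitution registry
#'
#' Builds one structure per registry row by attaching the named substituents
#' to the trovafloxacin scaffold, and validates each product's valence by
#' parsing it. Invalid rows are reported (column \code{valid}) and the run
#' continues.
#'
#' @param registry data.frame with columns \code{name}, \code{site1},
#'   \code{site5} (default \code{\link{trovafloxacinRegistry}()}).
#' @return data.frame: name, site1, site5, smiles, valid, formula.
#' @export
enumerateDerivatives <- function(registry = trovafloxacinRegistry()) {
  need <- c("name", "site1", "site5")
  if (!all(need %in% names(registry))) {
    stop("registry needs columns name, site1, site5", call. = FALSE)
  }
  if (nrow(registry) == 0L) {
    return(data.frame(name = character(0), site1 = character(0),
                      site5 = character(0), smiles = character(0),
                      valid = logical(0), formula = character(0),
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(c(registry$site1, registry$site5[nzchar(registry$site5)]),
                 names(GROUP_SMILES))
  if (length(bad)) {
    stop("unknown substituent group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  smiles <- mapply(trovaSmilesWith, registry$site1, registry$site5)
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste(smiles, registry$name, sep = "\t"), f)
  recs <- runMolprep(f, "smi", embed = FALSE)
  valid <- vapply(recs, function(r) is.null(r$error), logical(1))
  formula <- vapply(recs, function(r) {
    if (is.null(r$formula)) NA_character_ else r$formula
  }, character(1))
  data.frame(name = registry$name, site1 = registry$site1,
             site5 = registry$site5, smiles = unname(smiles),
             valid = valid, formula = formula, stringsAsFactors = FALSE)
}

#' Cross-product substituent enumeration
#'
#' Generic enumerator: every combination of one group per site. Unlike the
#' registry path this generates the full cartesian product.
#'
#' @param site1 character vector of group labels for site 1.
#' @param site5 character vector of group labels for site 5 (may include
#'   \code{""} for unsubstituted).
#' @return registry-shaped data.frame suitable for
#'   \code{\link{enumerateDerivatives}}.
#' @export
crossProductRegistry <- function(site1, site5 = "") {
  g <- expand.grid(site1 = site1, site5 = site5, stringsAsFactors = FALSE)
  nm <- ifelse(
    nzchar(g$site5),
    sprintf("1-%s-5-%s-Trovafloxacin", g$site1, g$site5),
    sprintf("1-%s-Trovafloxacin", g$site1)
  )
  data.frame(name = nm, site1 = g$site1, site5 = g$site5,
             stringsAsFactors = FALSE)
}
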