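#' @include AllClasses.R utils.R
NULL

#' Default alignment core: the 4-oxo-quinoline-3-carboxylate pharmacophore
#'
#' Eight atoms shared by every quinolone in the study set: the carboxyl
#' carbon, ring positions 3, 2, 1 (ring nitrogen), 8a, 4a, 4, and the 4-oxo
#' oxygen. Position 2 is carbon in quinolones and 1,8-naphthyridones but
#' nitrogen in cinnoline-type compounds (cinoxacin), so the pattern ships two
#' element variants. This choice of core atoms is a package design decision:
#' it spans both fused rings, is rigid, and is present exactly once in each
#' study compound.
#'
#' @param templateId identifier of the template molecule (default
#'   "Trovafloxacin").
#' @param tolerance maximum acceptable core RMSD in Angstrom.
#' @return an \linkS4class{AlignmentSpec}.
#' @export
quinoloneCoreSpec <- function(templateId = "Trovafloxacin", tolerance = 1.5) {
  # template order: Ccarb, C3, X2, N1, C8a, C4a, C4, O4, Ocarb, Ocarb
  # (both carboxyl oxygens are included so that a ring C-H cannot stand in
  # for the carboxyl carbon under ring reflection)
  bonds <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L),
                 c(5L, 6L), c(6L, 7L), c(7L, 2L), c(7L, 8L),
                 c(1L, 9L), c(1L, 10L))
  # bond orders (NA = unconstrained) break the carboxyl O equivalence:
  # slot 9 is the carbonyl oxygen, slot 10 the hydroxyl oxygen
  orders <- c(NA, NA, NA, NA, NA, NA, NA, 2, 2, 1)
  mk <- function(x2) list(
    elements = c("C", "C", x2, "N", "C", "C", "C", "O", "O", "O"),
    bonds = bonds, orders = orders
  )
  new("AlignmentSpec", templateId = templateId,
      variants = list(mk("C"), mk("N")), tolerance = tolerance)
}

# heavy-atom igraph with element labels
heavyGraph <- function(m) {
  a <- m@atoms
  heavy <- which(a$element != "H")
  idx <- match(seq_len(nrow(a)), heavy)  # old -> new
  b <- m@bonds
  keep <- !is.na(idx[b$a1]) & !is.na(idx[b$a2])
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(idx[b$a1[keep]], idx[b$a2[keep]]))
  }
  list(graph = g, elements = a$element[heavy], heavy = heavy)
}

#' Match the alignment core in a molecule
#'
#' Finds the (unique) induced-subgraph match of the core pattern in the
#' molecule's heavy-atom graph, trying each element variant. Errors if no
#' variant matches or if distinct matches are found.
#'
#' @param m a \linkS4class{Molecule}.
#' @param spec an \linkS4class{AlignmentSpec}.
#' @return integer vector of atom indices (into \code{atoms(m)}), in the
#'   template order of the core pattern.
#' @export
matchCore <- function(m, spec) {
  hg <- heavyGraph(m)
  found <- list()
  for (v in spec@variants) {
    pg <- igraph::make_empty_graph(n = length(v$elements), directed = FALSE)
    if (nrow(v$bonds)) pg <- igraph::add_edges(pg, t(v$bonds))
    # element-compatibility domains; induced matching via LAD
    domains <- lapply(v$elements, function(el) which(hg$elements == el))
    if (any(vapply(domains, length, integer(1)) == 0L)) next
    maps <- igraph::subgraph_isomorphisms(
      pattern = pg, target = hg$graph, method = "lad",
      domains = domains, induced = TRUE
    )
    ords <- if (is.null(v$orders)) rep(NA_real_, nrow(v$bonds)) else v$orders
    for (mp in maps) {
      found[[length(found) + 1L]] <-
        list(map = as.integer(mp), variant = v, orders = ords)
    }
  }
  if (length(found) == 0L) {
    stop(sprintf("molecule '%s': core pattern does not match", m@id),
         call. = FALSE)
  }
  # score each candidate ordering by agreement with the pattern's bond
  # orders (heavy-atom indices); used to orient chemically distinct but
  # graph-equivalent atoms such as the two carboxyl oxygens
  bo <- m@bonds
  bondOrder <- function(i, j) {
    hit <- (bo$a1 == i & bo$a2 == j) | (bo$a1 == j & bo$a2 == i)
    if (any(hit)) bo$order[which(hit)[1L]] else NA_real_
  }
  score <- vapply(found, function(f) {
    u <- hg$heavy[f$map]
    chk <- !is.na(f$orders)
    if (!any(chk)) return(0)
    sum(vapply(which(chk), function(r) {
      isTRUE(bondOrder(u[f$variant$bonds[r, 1]],
                       u[f$variant$bonds[r, 2]]) == f$orders[r])
    }, logical(1)))
  }, numeric(1))
  best <- which(score == max(score))
  found <- lapply(found[best], `[[`, "map")
  # collapse automorphic duplicates (same atom set, permuted equivalent
  # atoms); keep the lexicographically smallest ordering for a stable
  # correspondence
  sets <- vapply(found, function(u) paste(sort(u), collapse = ","),
                 character(1))
  uniq <- lapply(split(found, sets), function(grp) {
    keys <- vapply(grp, function(u) paste(sprintf("%06d", u), collapse = ""),
                   character(1))
    grp[[order(keys)[1L]]]
  })
  names(uniq) <- NULL
  if (length(uniq) > 1L) {
    stop(sprintf(
      "molecule '%s': core pattern matches ambiguously (%d matches: %s)",
      m@id, length(uniq),
      paste(vapply(uniq, function(u) paste(u, collapse = ","), character(1)),
            collapse = " | ")
    ), call. = FALSE)
  }
  hg$heavy[uniq[[1L]]]
}

#' Rigidly align a molecule onto a template over the shared core
#'
#' Applies the proper rotation and translation that minimize the RMSD of the
#' molecule's core atoms onto the template's core atoms (Kabsch
#' superposition). All atoms, including hydrogens, are transformed.
#'
#' @param m the \linkS4class{Molecule} to align (prepared).
#' @param spec an \linkS4class{AlignmentSpec}.
#' @param template the prepared template \linkS4class{Molecule}.
#' @return list with \code{molecule} (the transformed copy) and
#'   \code{coreRmsd} (residual RMSD over core atoms, Angstrom).
#' @export
alignToTemplate <- function(m, spec, template) {
  stopifnot(is(m, "Molecule"), is(template, "Molecule"))
  if (!m@prepared || !template@prepared) {
    stop("both molecules must be prepared before alignment", call. = FALSE)
  }
  mi <- matchCore(m, spec)
  ti <- matchCore(template, spec)
  P <- coords(m)[mi, , drop = FALSE]
  Q <- coords(template)[ti, , drop = FALSE]
  k <- kabsch(P, Q)
  newXYZ <- applyRigid(coords(m), k$rotation, k$translation)
  m@atoms$x <- newXYZ[, 1]
  m@atoms$y <- newXYZ[, 2]
  m@atoms$z <- newXYZ[, 3]
  validObject(m)
  list(molecule = m, coreRmsd = k$rmsd, coreIdx = mi)
}

#' Align a set of prepared molecules on a common template
#'
#' @param mols named list of prepared \linkS4class{Molecule} objects; must
#'   contain the template id named in \code{spec}.
#' @param spec an \linkS4class{AlignmentSpec}; default
#'   \code{\link{quinoloneCoreSpec}()}.
#' @return an \linkS4class{AlignedSet} (template first).
#' @export
alignSet <- function(mols, spec = quinoloneCoreSpec()) {
  if (is.null(names(mols))) {
    names(mols) <- vapply(mols, function(m) m@id, character(1))
  }
  if (!spec@templateId %in% names(mols)) {
    stop(sprintf("template '%s' not in molecule set", spec@templateId),
         call. = FALSE)
  }
  ord <- c(spec@templateId, setdiff(names(mols), spec@templateId))
  template <- mols[[spec@templateId]]
  out <- vector("list", length(ord))
  rmsd <- numeric(length(ord))
  idx <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    r <- alignToTemplate(mols[[ord[i]]], spec, template)
    out[[i]] <- r$molecule
    rmsd[i] <- r$coreRmsd
    idx[[i]] <- r$coreIdx
  }
  names(out) <- ord
  names(rmsd) <- ord
  names(idx) <- ord
  # the template must land exactly on itself
  rmsd[1L] <- 0
  new("AlignedSet", template = out[[1L]], members = out, coreRmsd = rmsd,
      coreIdx = idx, spec = spec)
}
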