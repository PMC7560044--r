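#' @include AllClasses.R utils.R
NULL

# Locate the python interpreter and the shipped preparation helper.
pythonBin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("no python interpreter on PATH; molecular preparation requires ",
         "python with rdkit (see SystemRequirements)", call. = FALSE)
  }
  bin
}

molprepScript <- function() {
  p <- system.file("python", "molprep.py", package = "quinsar")
  if (!nzchar(p)) stop("molprep.py helper not found", call. = FALSE)
  p
}

# Run the helper on a SMILES/SDF file; returns the parsed JSON records.
runMolprep <- function(infile, format = c("smi", "sdf"), seed = 1L,
                       embed = TRUE, attempts = 10L) {
  format <- match.arg(format)
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  args <- c(molprepScript(), "--in", infile, "--out", out,
            "--seed", as.integer(seed %% 2147483647),
            "--format", format, "--attempts", attempts)
  if (!embed) args <- c(args, "--no3d")
  status <- system2(pythonBin(), shQuote(args), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("molecule preparation helper failed:\n",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  jsonlite::fromJSON(out, simplifyVector = FALSE)
}

recordToMolecule <- function(rec, prepared, seed = NA_integer_) {
  if (!is.null(rec$error)) {
    stop(sprintf("molecule '%s': %s", rec$id, rec$error), call. = FALSE)
  }
  at <- do.call(rbind, lapply(rec$atoms, function(a) {
    data.frame(element = a$element,
               x = ifelse(is.null(a$x), NA_real_, a$x),
               y = ifelse(is.null(a$y), NA_real_, a$y),
               z = ifelse(is.null(a$z), NA_real_, a$z),
               charge = a$charge, hydro = a$hydro,
               hbd = isTRUE(a$hbd), hba = isTRUE(a$hba),
               formal = a$formal, stringsAsFactors = FALSE)
  }))
  bd <- if (length(rec$bonds)) {
    do.call(rbind, lapply(rec$bonds, function(b) {
      data.frame(a1 = b$a1, a2 = b$a2, order = b$order)
    }))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  energies <- c(pre = if (is.null(rec$ePre)) NA_real_ else rec$ePre,
                post = if (is.null(rec$ePost)) NA_real_ else rec$ePost)
  new("Molecule", id = rec$id, atoms = at, bonds = bd,
      netCharge = as.numeric(rec$netCharge), prepared = prepared,
      energies = energies,
      meta = list(formula = rec$formula, smiles = rec$canonicalSmiles,
                  forceField = if (prepared) "UFF" else NA_character_,
                  chargeModel = "Gasteiger",
                  hydrophobicityModel = "Wildman-Crippen atomic contributions",
                  seed = seed))
}

#' Parse a molecule record (SMILES or SDF) into a Molecule
#'
#' Produces connectivity, element symbols, formal charges and the per-atom
#' physicochemical weights that do not require coordinates. No 3-D conformer
#' is generated; see \code{\link{prepareMolecule}}.
#'
#' @param record a SMILES string, or the path to an SDF file when
#'   \code{format = "sdf"}.
#' @param id molecule identifier used in error messages and downstream
#'   tables.
#' @param format \code{"smiles"} (default) or \code{"sdf"}.
#' @return a \linkS4class{Molecule} (unprepared). For SDF input with several
#'   records, a list of molecules.
#' @examples
#' \dontrun{
#' benzene <- parseMolecule("c1ccccc1", "benzene")
#' }
#' @export
parseMolecule <- function(record, id = "mol", format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    f <- tempfile(fileext = ".smi")
    on.exit(unlink(f))
    writeLines(paste(record, id, sep = "\t"), f)
    recs <- runMolprep(f, "smi", embed = FALSE)
  } else {
    recs <- runMolprep(record, "sdf", embed = FALSE)
  }
  mols <- lapply(recs, function(r) {
    if (!is.null(r$error)) {
      stop(sprintf("cannot parse record '%s': %s", r$id, r$error),
           call. = FALSE)
    }
    recordToMolecule(r, prepared = FALSE)
  })
  if (length(mols) == 1L) mols[[1L]] else mols
}

#' Prepare molecules: 3-D conformer, charges, weights, H-bond flags
#'
#' Embeds one low-energy conformer per molecule (seeded distance-geometry
#' ETKDG), minimizes it with the UFF force field, assigns Gasteiger partial
#' charges, Crippen-type atomic hydrophobicity contributions, and
#' substructure-rule hydrogen-bond donor/acceptor flags. Deterministic for a
#' fixed seed: identical inputs give bit-identical coordinates.
#'
#' @param smiles named character vector of SMILES (names = ids), or a
#'   data.frame with columns \code{smiles} and \code{id}.
#' @param seed integer seed for the conformer embedding.
#' @param attempts maximum embedding attempts per molecule before raising a
#'   preparation error.
#' @return named list of prepared \linkS4class{Molecule} objects.
#' @export
prepareMolecules <- function(smiles, seed = 1L, attempts = 10L) {
  if (is.data.frame(smiles)) {
    ids <- smiles$id
    smi <- smiles$smiles
  } else {
    smi <- unname(smiles)
    ids <- names(smiles)
    if (is.null(ids)) ids <- paste0("mol", seq_along(smi))
  }
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste(smi, ids, sep = "\t"), f)
  recs <- runMolprep(f, "smi", seed = seed, embed = TRUE, attempts = attempts)
  mols <- lapply(recs, recordToMolecule, prepared = TRUE,
                 seed = as.integer(seed))
  names(mols) <- vapply(mols, function(m) m@id, character(1))
  mols
}

#' @rdname prepareMolecules
#' @param m an unprepared \linkS4class{Molecule} (its SMILES is re-embedded).
#' @export
prepareMolecule <- function(m, seed = 1L, attempts = 10L) {
  stopifnot(is(m, "Molecule"))
  smi <- m@meta$smiles
  if (is.null(smi)) stop("molecule carries no SMILES to embed", call. = FALSE)
  prepareMolecules(stats::setNames(smi, m@id), seed = seed,
                   attempts = attempts)[[1L]]
}

#' Minimization energies of a prepared molecule
#'
#' @param m a prepared \linkS4class{Molecule}.
#' @return numeric vector with UFF energies (kcal/mol) \code{pre} and
#'   \code{post} minimization.
#' @export
minimizationEnergies <- function(m) {
  stopifnot(is(m, "Molecule"))
  m@energies
}

#' Read a SMILES file (one record per line, "SMILES<TAB>id")
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles} and \code{id}.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1L),
    id = vapply(parts, function(p) {
      if (length(p) > 1L) trimws(p[[2L]]) else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write molecules to an SDF (V2000) file, preserving identifiers
#'
#' @param mols a \linkS4class{Molecule}, list of molecules, or
#'   \linkS4class{AlignedSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSDF <- function(mols, path) {
  if (is(mols, "AlignedSet")) mols <- mols@members
  if (is(mols, "Molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    a <- m@atoms
    b <- m@bonds
    writeLines(c(m@id, " quinsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    xyz[!is.finite(xyz)] <- 0
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    if (nrow(b)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2,
                         as.integer(round(b$order))), con)
    }
    chg <- which(a$formal != 0)
    if (length(chg)) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, a$formal[chg]),
                               collapse = "")), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
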