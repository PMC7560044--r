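#' @include AllClasses.R validation.R
NULL

HARTREE_TO_KCAL <- 627.5095

#' Convert log fb to the bound percentage (and back)
#'
#' log fb is the base-10 logarithm of the percentage of drug bound to plasma
#' protein, so \code{fb = 10^logfb}.
#'
#' @param logfb numeric log fb value(s).
#' @return percent bound.
#' @examples
#' logFbToFb(1.628)  # 42.462
#' @export
logFbToFb <- function(logfb) 10^logfb

#' @rdname logFbToFb
#' @param fb percent bound.
#' @export
fbToLogFb <- function(fb) log10(fb)

#' Relative change of an endpoint versus the parent compound
#'
#' Shared formula for every relative-change column:
#' \code{(value - parent) / parent * 100}.
#'
#' @param value derivative endpoint value(s).
#' @param parent parent-compound value; must be nonzero.
#' @return signed percent change(s).
#' @export
relativeChange <- function(value, parent) relativeError(value, parent)

#' Relative change of the bound percentage versus the parent compound
#'
#' Computed on the percentage scale, \code{fb = 10^logfb}. The reference
#' can optionally be rounded to one decimal before the percent is taken
#' (\code{roundedParent = TRUE}), the convention implied by published
#' binding-rate change tables; the default uses the unrounded parent value.
#'
#' @param logfb derivative log fb value(s).
#' @param parentLogfb parent log fb.
#' @param roundedParent round the parent percentage to 0.1 before use.
#' @return signed percent change(s) of the bound percentage.
#' @export
fbRelativeChange <- function(logfb, parentLogfb, roundedParent = FALSE) {
  parent <- logFbToFb(parentLogfb)
  if (roundedParent) parent <- round(parent, 1)
  relativeError(logFbToFb(logfb), parent)
}

#' Screen derivatives with binding rate below the parent
#'
#' @param table data.frame with columns \code{name} (or \code{id}) and
#'   \code{logfb}.
#' @param parentLogfb parent log fb.
#' @return character ids with log fb strictly below the parent, sorted by
#'   ascending log fb (strongest reduction first).
#' @export
screenLowerBinding <- function(table, parentLogfb) {
  idcol <- intersect(c("name", "id"), names(table))[1L]
  if (is.na(idcol) || !"logfb" %in% names(table)) {
    stop("table needs an id/name column and a 'logfb' column", call. = FALSE)
  }
  sel <- table$logfb < parentLogfb
  ids <- table[[idcol]][sel]
  ids[order(table$logfb[sel])]
}

#' Gibbs free energy change of a reaction (hartree in, kcal/mol out)
#'
#' \code{dG = (sum G_products - sum G_reactants) * 627.5095}, the
#' hartree-to-kcal/mol conversion.
#'
#' @param gReact total Gibbs energy of the reactant side (hartree).
#' @param gProd total Gibbs energy of the product side (hartree).
#' @return dG in kcal/mol (negative = spontaneous).
#' @export
deltaG <- function(gReact, gProd) (gProd - gReact) * HARTREE_TO_KCAL

#' Vibrational stability check
#'
#' A molecule at a true energy minimum has all vibrational frequencies
#' positive; stability holds iff the minimum frequency exceeds zero.
#'
#' @param frequencies numeric vector of vibrational frequencies (1/cm), or
#'   the minimum frequency alone.
#' @return logical: stable?
#' @export
stabilityCheck <- function(frequencies) {
  if (!length(frequencies)) stop("empty frequency list", call. = FALSE)
  min(frequencies) > 0
}

#' Residue hydropathy classes (20 residues)
#'
#' The class table is fixed: Ala, Cys, Ile, Leu, Met, Phe, Pro, Tyr and Val
#' are hydrophobic; the remainder (Arg, Asn, Asp, Gln, Glu, Gly, His, Lys,
#' Ser, Thr, Trp) hydrophilic, following the sign of the Kyte-Doolittle
#' scale except for Tyr and Pro, which are classed hydrophobic with the
#' aromatic/aliphatic ring residues.
#'
#' @return named character vector mapping 3-letter codes (upper case) to
#'   \code{"hydrophobic"} or \code{"hydrophilic"}.
#' @export
residueHydropathy <- function() {
  c(ALA = "hydrophobic", CYS = "hydrophobic", ILE = "hydrophobic",
    LEU = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
    PRO = "hydrophobic", TYR = "hydrophobic", VAL = "hydrophobic",
    ARG = "hydrophilic", ASN = "hydrophilic", ASP = "hydrophilic",
    GLN = "hydrophilic", GLU = "hydrophilic", GLY = "hydrophilic",
    HIS = "hydrophilic", LYS = "hydrophilic", SER = "hydrophilic",
    THR = "hydrophilic", TRP = "hydrophilic")
}

#' Classify protein-ligand contact residues by hydropathy
#'
#' @param residues data.frame with columns \code{code} (3-letter residue
#'   code) and \code{count} (multiplicity), or a character vector of codes
#'   (each counted once).
#' @return named numeric: \code{hydrophobic} and \code{hydrophilic} counts
#'   with multiplicities.
#' @export
classifyContacts <- function(residues) {
  if (is.character(residues)) {
    residues <- data.frame(code = residues,
                           count = rep(1, length(residues)))
  }
  if (nrow(residues) == 0L) {
    return(c(hydrophobic = 0, hydrophilic = 0))
  }
  lut <- residueHydropathy()
  codes <- toupper(residues$code)
  unknown <- setdiff(codes, names(lut))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cls <- lut[codes]
  c(hydrophobic = sum(residues$count[cls == "hydrophobic"]),
    hydrophilic = sum(residues$count[cls == "hydrophilic"]))
}

#' Mean contact distance
#'
#' Arithmetic mean of site-residue distances, reported at 0.1 Angstrom
#' precision as in contact tables.
#'
#' @param distances numeric distances (Angstrom), non-empty and positive.
#' @return mean distance rounded to one decimal.
#' @export
meanContactDistance <- function(distances) {
  if (!length(distances)) stop("empty distance list", call. = FALSE)
  if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
  round(mean(distances), 1)
}
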