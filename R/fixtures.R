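#' @include AllClasses.R molprep.R
NULL

# name -> (file, md5, reader); checksums pin the shipped transcriptions
FIXTURES <- list(
  table1 = list(file = "table1_logfb.csv",
                md5 = "39f2ae18beade92f2ac390d4375739e1", reader = "csv"),
  table2 = list(file = "table2_derivatives.csv",
                md5 = "dd5da4d2e2f56fa61f93596c857da5af", reader = "csv"),
  table3 = list(file = "table3_env.csv",
                md5 = "c91e8d39ee1bb791d2f370e10c045bf0", reader = "csv"),
  table4 = list(file = "table4_frequencies.csv",
                md5 = "07744e03f5f58e6cee91830905e91fd5", reader = "csv"),
  table5 = list(file = "table5_gibbs.csv",
                md5 = "20e9b58d4bd5aa60859ecf168380d200", reader = "csv"),
  table6 = list(file = "table6_libdock.csv",
                md5 = "c2075a3a2ac08400d3473ce943ea80f0", reader = "csv"),
  table7 = list(file = "table7_contacts.csv",
                md5 = "587f45b24dbb36ab750de1c490f99b48", reader = "csv"),
  table8 = list(file = "table8_distances.csv",
                md5 = "ad8d714893ead1535446ca4c490c0ae3", reader = "csv"),
  quinolones = list(file = "quinolones.smi",
                    md5 = "3cc5f2b36fcded40e10a739996ae905c",
                    reader = "smi"),
  derivatives = list(file = "trovafloxacin_derivatives.smi",
                     md5 = "58abfdab54ab3ea973ab5b56ac15a851",
                     reader = "smi")
)

#' Load a shipped fixture table or structure set
#'
#' Fixtures are the delimited transcriptions of the published endpoint tables
#' plus the repository structure sets: \code{table1} (experimental and
#' predicted log fb with the 13/3 train/test split), \code{table2}
#' (derivative predictions + the substitution registry), \code{table3}
#' (bioconcentration and photodegradation endpoints), \code{table4}
#' (minimum vibrational frequencies), \code{table5} (Gibbs energies),
#' \code{table6} (docking scores), \code{table7} (contact residue counts),
#' \code{table8} (contact distances), \code{quinolones} (fixture SMILES for
#' the 16 study compounds) and \code{derivatives} (fixture SMILES for the 16
#' registry derivatives). Files are checksum-verified on load.
#'
#' @param name fixture name (see above).
#' @return data.frame; structure sets have columns \code{smiles}, \code{id}.
#' @export
loadFixture <- function(name) {
  if (!name %in% names(FIXTURES)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(FIXTURES), collapse = ", ")), call. = FALSE)
  }
  fx <- FIXTURES[[name]]
  path <- system.file("extdata", fx$file, package = "quinsar")
  if (!nzchar(path)) stop("fixture file missing: ", fx$file, call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, fx$md5)) {
    stop(sprintf("fixture '%s' failed its checksum (%s != %s)",
                 name, sum, fx$md5), call. = FALSE)
  }
  if (fx$reader == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    readSmilesFile(path)
  }
}
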