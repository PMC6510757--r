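.SL_PROPERTIES <- c("shift", "slide", "rise", "tilt", "roll", "twist",
                    "enthalpy", "entropy", "free_energy", "hydrophilicity")

#' Dinucleotide physico-chemical property table
#'
#' Returns the bundled table of 16 RNA dinucleotides by 10 properties used by
#' the structure-based encoder: the helical step parameters shift, slide,
#' rise (translational) and tilt, roll, twist (rotational), plus the
#' physico-chemical properties enthalpy, entropy, free energy (Watson-Crick
#' nearest-neighbor thermodynamics) and hydrophilicity. Dinucleotides are
#' keyed over the RNA alphabet (A/C/G/U), 5'->3'. Per-property provenance is
#' recorded as comments in the bundled file
#' (`system.file("extdata", "dinuc_properties.tsv", package = "stemloopr")`).
#'
#' Values are used raw (unscaled): the tree ensembles consuming them are
#' invariant to monotone rescaling.
#'
#' @param path Optional path to an alternative property TSV with the same
#'   layout (`dinucleotide` column plus the 10 property columns).
#' @return A 16-row tibble with columns `dinucleotide`, `shift`, `slide`,
#'   `rise`, `tilt`, `roll`, `twist`, `enthalpy`, `entropy`, `free_energy`,
#'   `hydrophilicity`.
#' @export
dinuc_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinuc_properties.tsv",
                        package = "stemloopr", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_property_table(tab)
}

validate_property_table <- function(tab) {
  if (!identical(names(tab), c("dinucleotide", .SL_PROPERTIES))) {
    abort("Property table must have columns: dinucleotide, then the 10 named properties.")
  }
  rna_dinucs <- gsub("T", "U", .SL_DINUCS_DNA)
  if (nrow(tab) != 16L || !setequal(tab$dinucleotide, rna_dinucs)) {
    abort("Property table must have exactly the 16 A/C/G/U dinucleotides as rows.")
  }
  vals <- as.matrix(tab[, .SL_PROPERTIES])
  if (!all(is.finite(vals))) abort("Property table values must all be finite.")
  tab[match(rna_dinucs, tab$dinucleotide), ]
}
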