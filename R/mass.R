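#' Cellular RNA bookkeeping model
#'
#' Parameters for estimating how much sequencing is needed to exhaust the
#' RNA of a single cell, and what fraction of the non-ribosomal,
#' non-mitochondrial RNA a polyA selection captures.
#'
#' @param total_rna_g Total RNA per mammalian cell in grams (default
#'   20 pg = 2e-11 g).
#' @param informative_fraction Non-ribosomal, non-mitochondrial fraction
#'   of total RNA by mass (default 0.06).
#' @param informative_fraction_range Stated range of that fraction
#'   (default 0.04-0.08).
#' @param mean_read_length_nt Mean read length in nucleotides (default 35).
#' @param residue_mass_g_mol Mean mass of an internal ribonucleotide
#'   monophosphate residue in g/mol (default 340; reproduces the 2e-20 g
#'   per 35-base read figure at one significant digit).
#' @param polya_yield_range Fraction of total RNA recovered by one polyA
#'   selection (default 0.01-0.02).
#' @param polya_contamination Fraction of the polyA-selected material that
#'   is still ribosomal or mitochondrial (default 0.5).
#' @return An object of class `"cell_rna_model"`.
#' @export
cell_rna_model <- function(total_rna_g = 20e-12,
                           informative_fraction = 0.06,
                           informative_fraction_range = c(0.04, 0.08),
                           mean_read_length_nt = 35,
                           residue_mass_g_mol = 340,
                           polya_yield_range = c(0.01, 0.02),
                           polya_contamination = 0.5) {
  m <- list(total_rna_g = total_rna_g,
            informative_fraction = informative_fraction,
            informative_fraction_range = informative_fraction_range,
            mean_read_length_nt = mean_read_length_nt,
            residue_mass_g_mol = residue_mass_g_mol,
            polya_yield_range = polya_yield_range,
            polya_contamination = polya_contamination)
  stopifnot(total_rna_g > 0, mean_read_length_nt > 0, residue_mass_g_mol > 0,
            informative_fraction > 0, informative_fraction < 1,
            all(informative_fraction_range > 0), all(informative_fraction_range < 1),
            all(polya_yield_range > 0), all(polya_yield_range < 1),
            polya_contamination >= 0, polya_contamination <= 1)
  structure(m, class = "cell_rna_model")
}

AVOGADRO <- 6.02214076e23

#' Mass of a single RNA read
#'
#' `length_nt * residue_mass / N_A` grams; a 35-base read at 340 g/mol per
#' residue masses ~2e-20 g.
#'
#' @param length_nt Read length in nucleotides (>= 0).
#' @param residue_mass_g_mol Mean residue mass (g/mol).
#' @return Mass in grams.
#' @export
read_mass <- function(length_nt, residue_mass_g_mol = 340) {
  if (any(length_nt < 0)) stop("read length must be nonnegative", call. = FALSE)
  length_nt * residue_mass_g_mol / AVOGADRO
}

#' Reads needed to sequence the RNA of one cell
#'
#' Divides the total (undepleted) RNA mass of a cell by the mass of an
#' average read: the ribosomal and mitochondrial RNA cannot be physically
#' pre-selected away, so sequencing through the whole pool is what a
#' single-cell-equivalent experiment costs. At the defaults (20 pg, 35 nt
#' reads of ~2e-20 g) this is about 1e9 reads — comfortably above the
#' hundred-million-read scale. The informative reads among them are
#' `reads * informative_fraction`.
#'
#' @param model A [cell_rna_model()].
#' @return List with `total_reads` and `informative_reads`.
#' @export
reads_needed <- function(model = cell_rna_model()) {
  rm1 <- read_mass(model$mean_read_length_nt, model$residue_mass_g_mol)
  if (rm1 <= 0) stop("read mass must be positive", call. = FALSE)
  total <- model$total_rna_g / rm1
  list(total_reads = total,
       informative_reads = total * model$informative_fraction)
}

#' PolyA-selected fraction of the informative RNA pool
#'
#' Bounds on the fraction of non-ribosomal, non-mitochondrial RNA that a
#' single polyA selection represents:
#' `(yield * (1 - contamination)) / informative_fraction`, evaluated at
#' the extreme pairings (minimum yield with maximum informative fraction
#' and vice versa). At the defaults the bounds are 6.25% and 25%.
#'
#' @param model A [cell_rna_model()].
#' @return Named vector `c(lower, upper)` of fractions in `[0, 1]`.
#' @export
polya_informative_fraction <- function(model = cell_rna_model()) {
  clean <- 1 - model$polya_contamination
  lower <- model$polya_yield_range[1] * clean / model$informative_fraction_range[2]
  upper <- model$polya_yield_range[2] * clean / model$informative_fraction_range[1]
  c(lower = lower, upper = upper)
}
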