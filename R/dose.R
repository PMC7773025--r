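#' An RNA dose specification
#'
#' @param concentration Mass concentration in ng/µl (>= 0).
#' @param length Length in nt (single-stranded) or duplex length in bp.
#' @param strandedness `"duplex"` or `"single"`.
#' @param label Free-text label.
#' @return A one-row tibble of class `dose_spec`.
#' @export
dose_spec <- function(concentration, length,
                      strandedness = c("duplex", "single"), label = "") {
  strandedness <- match.arg(strandedness)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (length < 1) stop("length must be >= 1 nt", call. = FALSE)
  out <- tibble::tibble(concentration = concentration,
                        length = as.integer(length),
                        strandedness = strandedness, label = label)
  class(out) <- c("dose_spec", class(out))
  out
}

# conventional average molar masses: 660 g/mol per bp of duplex,
# 330 g/mol per nt of single strand
unit_mass <- function(strandedness) {
  ifelse(strandedness == "duplex", 660, 330)
}

#' Molar concentration of an RNA dose
#'
#' Converts a mass concentration to molarity:
#' `µM = 1000 * (ng/µl) / (length * unit mass)`, with the unit mass 660
#' g/mol per bp for duplexes and 330 g/mol per nt for single strands.
#' A 20 ng/µl dose of a 139-bp duplex is 0.22 µM; 1.4 ng/µl of a 22-bp
#' duplex is 0.1 µM.
#'
#' @param dose A [dose_spec()] (or a tibble with the same columns).
#' @return Molarity in µM (vectorised over rows).
#' @export
molar_concentration <- function(dose) {
  if (any(dose$length < 1)) stop("length must be >= 1", call. = FALSE)
  1000 * dose$concentration / (dose$length * unit_mass(dose$strandedness))
}

#' Phased siRNA yield of a dsRNA duplex
#'
#' Number of non-overlapping phased siRNA units a duplex can be diced into:
#' `floor(duplex_length / sirna_length)`. A 139-bp duplex yields 6 phased
#' 22-nt siRNAs; a 322-bp duplex yields 14.
#'
#' @param duplex_length Duplex length in bp (>= 1).
#' @param sirna_length siRNA unit length in nt (default 22).
#' @return Integer count.
#' @export
phased_sirna_yield <- function(duplex_length, sirna_length = 22L) {
  if (any(sirna_length <= 0)) stop("sirna_length must be positive", call. = FALSE)
  if (any(duplex_length < 1)) stop("duplex_length must be >= 1", call. = FALSE)
  as.integer(floor(duplex_length / sirna_length))
}

#' Molar and effective-molarity ratio of a dose against a reference
#'
#' The molar ratio is the dose's molarity over the reference's; the effective
#' ratio additionally multiplies by the dose's phased siRNA yield, treating
#' each potential phased siRNA as one effective silencing unit.
#' `reference_molarity_override` exists because published comparisons often
#' divide by a rounded reference molarity (e.g. 0.1 µM rather than the exact
#' 0.0964 µM of 1.4 ng/µl x 22 bp).
#'
#' @param dose,reference [dose_spec()] rows.
#' @param reference_molarity_override Optional µM value used instead of the
#'   computed reference molarity.
#' @param sirna_length Phasing unit for the yield (default 22 nt).
#' @return A list `molar_ratio`, `effective_ratio`, `dose_molarity`,
#'   `reference_molarity`, `sirna_yield`.
#' @export
effective_molarity_ratio <- function(dose, reference,
                                     reference_molarity_override = NULL,
                                     sirna_length = 22L) {
  ref_m <- reference_molarity_override %||% molar_concentration(reference)
  if (ref_m <= 0) stop("reference molarity must be > 0", call. = FALSE)
  dm <- molar_concentration(dose)
  yield <- phased_sirna_yield(dose$length, sirna_length)
  list(molar_ratio = dm / ref_m,
       effective_ratio = dm / ref_m * yield,
       dose_molarity = dm, reference_molarity = ref_m, sirna_yield = yield)
}

#' Sum per-reaction synthesis yields
#'
#' @param per_reaction_yields Numeric vector of per-reaction yields in µg
#'   (all >= 0).
#' @return The total in µg, rounded to one decimal.
#' @export
sum_yields <- function(per_reaction_yields) {
  if (any(per_reaction_yields < 0)) {
    stop("yields must be >= 0", call. = FALSE)
  }
  round(sum(per_reaction_yields), 1)
}

#' Full molar bookkeeping for a dose
#'
#' @param dose A [dose_spec()].
#' @param sirna_length Phasing unit (default 22 nt).
#' @return A tibble: `label`, `molarity` (µM), `sirna_yield`,
#'   `effective_molarity` (µM, molarity x yield).
#' @export
molar_result <- function(dose, sirna_length = 22L) {
  m <- molar_concentration(dose)
  y <- phased_sirna_yield(dose$length, sirna_length)
  tibble::tibble(label = dose$label, molarity = m, sirna_yield = y,
                 effective_molarity = m * y)
}
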