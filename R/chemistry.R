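#' Protein mass balance and extraction yield
#'
#' The extraction yield of a protein-isolation run is computed from a
#' three-step mass balance: the protein mass in the feed (initial cake mass
#' times its protein content), the protein mass in the dried isolate
#' (isolate mass times its Kjeldahl protein content), and their ratio as a
#' percentage.
#'
#' @param m0 initial rapeseed-cake mass, g.
#' @param mp protein content of the cake, % dry weight (0-100).
#' @return protein mass in the feed, g.
#' @examples
#' m1 <- protein_mass_in_feed(100, 40.42) # 40.42 g
#' m3 <- protein_mass_in_isolate(15, 80)  # 12 g
#' extraction_yield(m1, m3)               # 29.69 %
#' @export
protein_mass_in_feed <- function(m0, mp) {
  stop_if_not_scalar_number(m0, "m0", allow_negative = FALSE)
  check_percentage(mp, "mp")
  m0 * mp / 100
}

#' @rdname protein_mass_in_feed
#' @param m2 dried isolate mass, g.
#' @param p protein content of the isolate, % (0-100).
#' @return protein mass in the isolate, g.
#' @export
protein_mass_in_isolate <- function(m2, p) {
  stop_if_not_scalar_number(m2, "m2", allow_negative = FALSE)
  check_percentage(p, "p")
  m2 * p / 100
}

#' @rdname protein_mass_in_feed
#' @param m1 protein mass in the feed, g (> 0).
#' @param m3 protein mass in the isolate, g.
#' @return extraction yield, %.
#' @export
extraction_yield <- function(m1, m3) {
  stop_if_not_scalar_number(m1, "m1", allow_negative = FALSE)
  stop_if_not_scalar_number(m3, "m3", allow_negative = FALSE)
  if (m1 == 0) stop("'m1' must be positive: no protein in the feed", call. = FALSE)
  m3 * 100 / m1
}

check_percentage <- function(x, name) {
  stop_if_not_scalar_number(x, name, allow_negative = FALSE)
  if (x > 100) stop(sprintf("'%s' is a percentage and must be <= 100", name),
                    call. = FALSE)
  invisible(x)
}

#' Soluble-protein concentration from a Bradford reading
#'
#' Converts an absorbance at 595 nm into mg/mL of soluble protein through a
#' BSA calibration factor:
#' `c = Abs * factor * dilution / volume`. The default factor 1.9899 is the
#' slope-derived constant of the BSA calibration curve used for rapeseed
#' protein solubility work.
#'
#' @param abs595 absorbance at 595 nm (>= 0).
#' @param dilution pre-measurement dilution factor (>= 1).
#' @param volume aliquot volume, mL (> 0).
#' @param factor calibration constant (default 1.9899).
#' @return concentration, mg/mL.
#' @examples
#' bradford_concentration(1.0) # 1.9899 mg/mL
#' @export
bradford_concentration <- function(abs595, dilution = 1, volume = 1,
                                   factor = 1.9899) {
  stop_if_not_scalar_number(abs595, "abs595", allow_negative = FALSE)
  stop_if_not_scalar_number(dilution, "dilution")
  stop_if_not_scalar_number(volume, "volume")
  stop_if_not_scalar_number(factor, "factor")
  if (dilution < 1) stop("'dilution' must be at least 1", call. = FALSE)
  if (volume <= 0) stop("'volume' must be positive", call. = FALSE)
  abs595 * factor * dilution / volume
}

#' Total phenolic content from a Folin-Ciocalteu reading
#'
#' Maps an absorbance through a linear gallic-acid calibration curve
#' (`conc = (abs - intercept) / slope`, mg gallic acid per mL) and scales
#' by dilution, extract volume and sample mass to mg GAE per 100 g of
#' material. The calibration slope and intercept are assay-specific and
#' must be supplied.
#'
#' @param absorbance measured absorbance (must not fall below the
#'   intercept, which would imply a negative concentration).
#' @param slope calibration slope, absorbance per (mg GA/mL) (> 0).
#' @param intercept calibration intercept, absorbance units.
#' @param extract_volume extract volume, mL.
#' @param sample_mass extracted sample mass, g (> 0).
#' @param dilution dilution factor (>= 1).
#' @return total phenolic content, mg GAE/100 g.
#' @export
tpc_gae <- function(absorbance, slope, intercept = 0, extract_volume = 10,
                    sample_mass = 1, dilution = 1) {
  stop_if_not_scalar_number(absorbance, "absorbance")
  stop_if_not_scalar_number(slope, "slope")
  stop_if_not_scalar_number(intercept, "intercept")
  stop_if_not_scalar_number(extract_volume, "extract_volume", allow_negative = FALSE)
  stop_if_not_scalar_number(sample_mass, "sample_mass")
  stop_if_not_scalar_number(dilution, "dilution")
  if (slope <= 0) stop("'slope' must be positive", call. = FALSE)
  if (sample_mass <= 0) stop("'sample_mass' must be positive", call. = FALSE)
  if (dilution < 1) stop("'dilution' must be at least 1", call. = FALSE)
  if (absorbance < intercept) {
    stop("absorbance below the calibration intercept: negative concentration",
         call. = FALSE)
  }
  conc <- (absorbance - intercept) / slope
  conc * dilution * extract_volume / sample_mass * 100
}

#' Amino-acid panel of an acid-hydrolysis assay
#'
#' The fixed 16-analyte panel quantified after 6 M HCl hydrolysis:
#' tryptophan is destroyed and cysteine is not recovered, so neither is
#' part of the panel.
#'
#' @format Character vectors of 3-letter codes.
#' @name amino_acid_panel
NULL

#' @rdname amino_acid_panel
#' @export
ESSENTIAL_AA <- c("Thr", "Val", "Met", "Ile", "Leu", "Phe", "Lys", "His")

#' @rdname amino_acid_panel
#' @export
NONESSENTIAL_AA <- c("Asp", "Ser", "Glu", "Gly", "Ala", "Tyr", "Arg", "Pro")

#' Construct an amino-acid profile
#'
#' @param values named numeric vector, g of amino acid per 100 g protein;
#'   must contain exactly the 16 analytes in [ESSENTIAL_AA] and
#'   [NONESSENTIAL_AA], all non-negative.
#' @param label sample label.
#' @return object of class `aa_profile`.
#' @export
aa_profile <- function(values, label = "") {
  panel <- c(ESSENTIAL_AA, NONESSENTIAL_AA)
  missing <- setdiff(panel, names(values))
  if (length(missing)) {
    stop("missing analyte(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(values), panel)
  if (length(extra)) {
    stop("unknown analyte(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  v <- as.numeric(values[panel])
  names(v) <- panel
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("amino-acid values must be finite and non-negative", call. = FALSE)
  }
  structure(list(values = v, label = label), class = "aa_profile")
}

#' Summarize an amino-acid profile against WHO requirements
#'
#' Computes the essential (EAA), non-essential (NEAA) and total (TAA)
#' amino-acid sums, the EAA/NEAA and EAA/TAA percentage ratios, and
#' pass/fail flags of each essential amino acid against a threshold table
#' (g/100 g protein). The default threshold table carries only the lysine
#' adult requirement of 4.5 g/100 g; a fuller WHO table can be supplied as
#' a named vector.
#'
#' Ratio percentages are reported exactly; printed tables in this field
#' round them to whole percent (half away from zero), which
#' [round_half_up()] reproduces.
#'
#' @param profile an [aa_profile()].
#' @param who_thresholds named numeric vector of minimum EAA contents,
#'   g/100 g protein (default `c(Lys = 4.5)`).
#' @return object of class `aa_summary` with fields `eaa_sum`, `neaa_sum`,
#'   `taa_sum`, `eaa_over_neaa_pct`, `eaa_over_taa_pct`, `who_flags`
#'   (named logical), `label`.
#' @export
aa_summary <- function(profile, who_thresholds = c(Lys = 4.5)) {
  stopifnot(inherits(profile, "aa_profile"))
  v <- profile$values
  eaa <- sum(v[ESSENTIAL_AA])
  neaa <- sum(v[NONESSENTIAL_AA])
  taa <- eaa + neaa
  if (neaa == 0 || taa == 0) {
    stop("zero amino-acid sums: ratios undefined", call. = FALSE)
  }
  unknown <- setdiff(names(who_thresholds), ESSENTIAL_AA)
  if (length(unknown)) {
    stop("threshold(s) for non-essential or unknown analyte(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  flags <- v[names(who_thresholds)] >= who_thresholds
  structure(list(eaa_sum = eaa, neaa_sum = neaa, taa_sum = taa,
                 eaa_over_neaa_pct = 100 * eaa / neaa,
                 eaa_over_taa_pct = 100 * eaa / taa,
                 who_flags = flags, label = profile$label),
            class = "aa_summary")
}

#' @export
print.aa_summary <- function(x, ...) {
  cat(sprintf("Amino-acid summary%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  EAA  %6.2f  NEAA %6.2f  TAA %6.2f  (g/100 g protein)\n",
              x$eaa_sum, x$neaa_sum, x$taa_sum))
  cat(sprintf("  EAA/NEAA %d%%  EAA/TAA %d%%  (rounded to whole percent)\n",
              round_half_up(x$eaa_over_neaa_pct),
              round_half_up(x$eaa_over_taa_pct)))
  if (length(x$who_flags)) {
    cat("  WHO flags:", paste(sprintf("%s:%s", names(x$who_flags),
                                      ifelse(x$who_flags, "pass", "FAIL")),
                              collapse = " "), "\n")
  }
  invisible(x)
}

#' Read amino-acid profiles from a CSV of analyte rows
#'
#' Expects a column `amino_acid` with the 16 panel codes and one numeric
#' column per sample; columns ending in `_sd` are treated as replicate-sd
#' metadata and skipped. The packaged file
#' `system.file("extdata", "rapeseed_isolate_amino_acids.csv", package =
#' "dephenolize")` holds literature profiles of five rapeseed protein
#' isolates (dephenolized, enzyme-assisted, ultrasound-assisted, combined,
#' and optimized pretreatments).
#'
#' @param path CSV path.
#' @return named list of [aa_profile()] objects, one per sample column.
#' @export
read_aa_profiles <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (!"amino_acid" %in% names(d)) {
    stop("CSV must have an 'amino_acid' column", call. = FALSE)
  }
  samples <- setdiff(names(d), "amino_acid")
  samples <- samples[!grepl("_sd$", samples)]
  out <- lapply(samples, function(s) {
    aa_profile(stats::setNames(d[[s]], d$amino_acid), label = s)
  })
  stats::setNames(out, samples)
}

#' TCA-soluble protein gain after in vitro digestion
#'
#' The digestibility signal is the increase in trichloroacetic-acid-soluble
#' protein between an undigested control and the enzyme-treated sample. A
#' negative gain (less soluble protein after digestion) is physically
#' suspect and is flagged with a warning.
#'
#' @param control_mg_ml TCA-soluble protein in the control, mg/mL.
#' @param digested_mg_ml TCA-soluble protein after digestion, mg/mL.
#' @return gain in mg/mL (may be negative).
#' @export
digestibility_gain <- function(control_mg_ml, digested_mg_ml) {
  stop_if_not_scalar_number(control_mg_ml, "control_mg_ml", allow_negative = FALSE)
  stop_if_not_scalar_number(digested_mg_ml, "digested_mg_ml", allow_negative = FALSE)
  gain <- digested_mg_ml - control_mg_ml
  if (gain < 0) {
    warning("negative digestibility gain: digested sample has less ",
            "TCA-soluble protein than the control", call. = FALSE)
  }
  gain
}
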