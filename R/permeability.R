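#' Control-corrected rate-constant ratios
#'
#' Relative water-transport activity of a sample series after subtracting
#' the empty-liposome control:
#' \eqn{ratio_i = (K_i - K_{empty})/(K_{ref} - K_{empty})}.
#' The reference entry has ratio exactly 1. Samples whose rate does not
#' exceed the control have no defined activity ratio; they are returned as
#' `NA` with a warning (flagged non-positive activity).
#'
#' @param K_samples named or unnamed vector of sample rate constants \[1/s\]
#' @param K_empty empty-liposome control rate constant \[1/s\]
#' @param reference index (or name) of the reference sample
#' @return Numeric vector of ratios, same length/names as `K_samples`.
#' @examples
#' corrected_rate_ratios(c(153.0, 102.4, 59.2), 33.3, reference = 3)
#' @export
corrected_rate_ratios <- function(K_samples, K_empty, reference = 1) {
  if (is.character(reference)) reference <- match(reference, names(K_samples))
  if (is.na(reference) || reference < 1 || reference > length(K_samples))
    stop("invalid reference sample", call. = FALSE)
  denom <- K_samples[[reference]] - K_empty
  if (denom <= 0)
    stop("reference rate does not exceed the control; ratios undefined",
         call. = FALSE)
  num <- K_samples - K_empty
  out <- num / denom
  out[[reference]] <- 1  # exact by construction
  if (any(num <= 0)) {
    warning("sample rate(s) not above the control flagged as NA ",
            "(non-positive activity)", call. = FALSE)
    out[num <= 0] <- NA_real_
  }
  out
}

#' Osmotic water permeability from the shrinkage rate constant
#'
#' Default formula (Grzelakowski-style):
#' \deqn{P_f = \frac{K}{(S/V_0)\, V_w\, \Delta_{osm}}}
#' with surface-to-volume ratio \eqn{S/V_0 = 3/r} for a sphere of radius
#' `vesicle_diameter / 2`. The exact published variant of this relation is
#' instrument- and convention-dependent, so the formula slot is pluggable:
#' supply `formula` to replace the default computation.
#'
#' @param K rate constant \[1/s\] (raw or control-corrected)
#' @param vesicle_diameter vesicle hydrodynamic diameter \[nm\]
#'   (post-extrusion Z-average)
#' @param delta_osm osmotic gradient \[osmol/L\]. Default 0.5: mixing 1:1
#'   with 0.5 M NaCl gives 0.25 M added salt, van 't Hoff factor 2.
#' @param V_w partial molar volume of water \[cm^3/mol\] (default 18)
#' @param formula optional replacement `function(K, vesicle_diameter,
#'   delta_osm, V_w)` returning P_f in um/s
#' @return P_f \[um/s\]. Zero when `K` is zero.
#' @examples
#' osmotic_permeability(100, vesicle_diameter = 124.7)
#' @export
osmotic_permeability <- function(K, vesicle_diameter, delta_osm = 0.5,
                                 V_w = 18, formula = NULL) {
  if (any(K < 0)) stop("K must be non-negative", call. = FALSE)
  if (vesicle_diameter <= 0 || delta_osm <= 0 || V_w <= 0)
    stop("diameter, osmotic gradient and V_w must be positive",
         call. = FALSE)
  if (!is.null(formula))
    return(formula(K, vesicle_diameter, delta_osm, V_w))
  r_cm <- vesicle_diameter / 2 * 1e-7            # nm -> cm
  osm_cm3 <- delta_osm * 1e-3                    # osmol/L -> mol/cm^3
  p_cm_s <- K * r_cm / (3 * V_w * osm_cm3)
  p_cm_s * 1e4                                   # cm/s -> um/s
}

#' Water channels per vesicle from the reconstitution stoichiometry
#'
#' Counts lipids on both leaflets of a spherical vesicle
#' (`2 * 4 pi r^2 / area_per_lipid`), converts to protein tetramers through
#' the molar lipid-to-protein ratio (LPR) of the reconstitution mix, and
#' multiplies by four monomeric pores per tetramer (aquaporins are
#' homotetramers of independently conducting channels).
#'
#' @param lipid_conc lipid concentration \[mg/ml\]
#' @param protein_conc protein concentration \[mg/ml\]; zero protein gives
#'   zero channels (flagged by a warning)
#' @param lipid_MW lipid molar mass \[g/mol\] (default 776, soy PC)
#' @param tetramer_MW tetramer molar mass \[g/mol\] (default 97000)
#' @param vesicle_diameter vesicle diameter \[nm\]
#' @param area_per_lipid area per lipid headgroup \[nm^2\] (default 0.7)
#' @param lpr optional molar lipid-per-tetramer ratio; overrides the
#'   concentration-based computation when given
#' @return Channel count (possibly fractional) with attributes `lipids`,
#'   `tetramers` and `lpr`.
#' @examples
#' channels_per_vesicle(7.5, 0.05, vesicle_diameter = 124.7)
#' @export
channels_per_vesicle <- function(lipid_conc, protein_conc, lipid_MW = 776,
                                 tetramer_MW = 97000, vesicle_diameter,
                                 area_per_lipid = 0.7, lpr = NULL) {
  if (vesicle_diameter <= 0 || area_per_lipid <= 0)
    stop("vesicle_diameter and area_per_lipid must be positive",
         call. = FALSE)
  r <- vesicle_diameter / 2                      # nm
  lipids <- 2 * 4 * pi * r^2 / area_per_lipid    # both leaflets
  if (is.null(lpr)) {
    if (lipid_conc <= 0 || lipid_MW <= 0 || tetramer_MW <= 0)
      stop("concentrations and molar masses must be positive", call. = FALSE)
    if (protein_conc < 0) stop("negative protein concentration", call. = FALSE)
    if (protein_conc == 0) {
      warning("zero protein concentration: infinite LPR, zero channels",
              call. = FALSE)
      lpr <- Inf
    } else {
      lpr <- (lipid_conc / lipid_MW) / (protein_conc / tetramer_MW)
    }
  }
  tetramers <- lipids / lpr
  structure(4 * tetramers, lipids = lipids, tetramers = tetramers, lpr = lpr)
}

#' Single-channel water permeability
#'
#' Divides the control-corrected membrane permeability over the channels in
#' one vesicle: \eqn{p_f = P_f \cdot 4\pi r^2 / N}, converted to cm^3/s.
#'
#' @param P_f_corrected osmotic permeability of the protein contribution
#'   (control-corrected) \[um/s\]
#' @param vesicle_diameter vesicle diameter \[nm\]
#' @param channels channels per vesicle (>= 1 for a defined per-channel
#'   quantity; zero is an error)
#' @return p_f \[cm^3/s\].
#' @examples
#' n <- channels_per_vesicle(7.5, 0.05, vesicle_diameter = 124.7)
#' single_channel_permeability(21.55 - 6.39, 124.7, n)
#' @export
single_channel_permeability <- function(P_f_corrected, vesicle_diameter,
                                        channels) {
  if (channels <= 0)
    stop("channels must be positive: per-channel permeability undefined",
         call. = FALSE)
  if (vesicle_diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (any(P_f_corrected < 0))
    stop("corrected P_f must be non-negative", call. = FALSE)
  r_cm <- vesicle_diameter / 2 * 1e-7
  area_cm2 <- 4 * pi * r_cm^2
  (P_f_corrected * 1e-4) * area_cm2 / as.numeric(channels)
}

#' Full permeability record for one sample
#'
#' Convenience chain from the fitted rate constant to the per-channel
#' permeability: corrects for the empty-liposome control, converts to
#' membrane permeability P_f, counts channels and derives p_f.
#'
#' @param K sample rate constant \[1/s\]
#' @param K_empty control rate constant \[1/s\]
#' @param vesicle_diameter vesicle diameter \[nm\]
#' @param delta_osm osmotic gradient \[osmol/L\]
#' @param V_w partial molar water volume \[cm^3/mol\]
#' @param lipid_conc,protein_conc concentrations \[mg/ml\]
#' @param lipid_MW,tetramer_MW molar masses \[g/mol\]
#' @param area_per_lipid \[nm^2\]
#' @param lpr optional molar lipid-per-tetramer ratio override
#' @param formula optional P_f formula plug-in, see
#'   [osmotic_permeability()]
#' @param label sample identifier
#' @return Object of class `permeability_record`: list with `K`, `K_empty`,
#'   `K_corrected`, `P_f` (raw), `P_f_corrected`, `channels`, `p_f` and the
#'   inputs.
#' @export
permeability_record <- function(K, K_empty, vesicle_diameter,
                                delta_osm = 0.5, V_w = 18,
                                lipid_conc = 7.5, protein_conc,
                                lipid_MW = 776, tetramer_MW = 97000,
                                area_per_lipid = 0.7, lpr = NULL,
                                formula = NULL, label = "sample") {
  K_corr <- max(K - K_empty, 0)
  P_f <- osmotic_permeability(K, vesicle_diameter, delta_osm, V_w, formula)
  P_f_corr <- osmotic_permeability(K_corr, vesicle_diameter, delta_osm, V_w,
                                   formula)
  channels <- channels_per_vesicle(lipid_conc, protein_conc, lipid_MW,
                                   tetramer_MW, vesicle_diameter,
                                   area_per_lipid, lpr)
  p_f <- if (channels > 0)
    single_channel_permeability(P_f_corr, vesicle_diameter, channels)
  else NA_real_
  structure(list(label = label, K = K, K_empty = K_empty,
                 K_corrected = K_corr, vesicle_diameter = vesicle_diameter,
                 delta_osm = delta_osm, V_w = V_w, P_f = P_f,
                 P_f_corrected = P_f_corr,
                 channels = as.numeric(channels), p_f = p_f),
            class = "permeability_record")
}

#' @export
print.permeability_record <- function(x, ...) {
  cat(sprintf("Permeability record '%s':\n", x$label))
  cat(sprintf("  K = %.4g 1/s (control %.4g, corrected %.4g)\n",
              x$K, x$K_empty, x$K_corrected))
  cat(sprintf("  P_f = %.4g um/s (corrected %.4g)\n", x$P_f,
              x$P_f_corrected))
  cat(sprintf("  %.3g channels/vesicle -> p_f = %.3g cm^3/s\n",
              x$channels, x$p_f))
  invisible(x)
}
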