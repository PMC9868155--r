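#' Reference morphometry of the four Friedman tongue position (FTP) subjects
#'
#' Published morphometric characteristics of the velopharyngeal +
#' oropharyngeal region of interest (hard palate to epiglottis tip) for four
#' subjects graded FTP I-IV, each imaged mouth-closed (MC) and mouth-open
#' (MO). These values parameterize the synthetic airway templates: the
#' number of 0.5 mm cross-sectional planes, the dividing plane at the
#' soft-palate tip, and the velopharyngeal minimum-area plane (plane_Amin)
#' with its area.
#'
#' Segment length is reported here as `(n_planes - 1) * 0.5` mm; the
#' original report's printed lengths differ from this product by up to
#' 0.3 mm for some subjects and are not reproduced.
#'
#' @return A data.frame with one row per template (`FTP1_MC` ... `FTP4_MO`)
#'   and columns `template`, `n_planes`, `dividing_index`,
#'   `amin_index` (velopharyngeal plane_Amin plane number),
#'   `amin_area_cm2`, `oro_amin_index`, `oro_amin_area_cm2`.
#' @seealso [airway_spec()] which turns a row into a synthetic geometry spec.
#' @export
ftp_reference_morphometry <- function() {
  data.frame(
    template = c("FTP1_MC", "FTP1_MO", "FTP2_MC", "FTP2_MO",
                 "FTP3_MC", "FTP3_MO", "FTP4_MC", "FTP4_MO"),
    n_planes = c(96L, 134L, 95L, 114L, 91L, 101L, 91L, 103L),
    dividing_index = c(58L, 70L, 54L, 68L, 68L, 68L, 51L, 53L),
    amin_index = c(44L, 54L, 14L, 54L, 47L, 49L, 38L, 41L),
    amin_area_cm2 = c(0.8288, 2.226, 0.6883, 0.6862,
                      0.6074, 0.6035, 1.4440, 0.5443),
    oro_amin_index = c(59L, 102L, 61L, 77L, 69L, 69L, 52L, 54L),
    oro_amin_area_cm2 = c(2.037, 1.153, 1.177, 0.8473,
                          1.649, 1.533, 2.085, 0.6441),
    stringsAsFactors = FALSE
  )
}

#' Reported subsegmental resistance at the velopharyngeal plane_Amin
#'
#' The published resistance of the subsegment just above the velopharyngeal
#' minimum-area plane for the three mouth-open subjects whose plane_Amin
#' lies in the printed comparison (FTP II, III, IV). Values are reproduced
#' in the units of the original report ("Pa"); the square-law resistance
#' formula is dimensionally Pa s^2 m^-6, and the ratio of two values is
#' unit-free either way.
#'
#' @return data.frame with columns `template`, `subseg_index`,
#'   `amin_area_cm2`, `resistance`.
#' @seealso [subsegment_resistance()]
#' @export
ftp_reference_resistance <- function() {
  data.frame(
    template = c("FTP2_MO", "FTP3_MO", "FTP4_MO"),
    subseg_index = c(53L, 48L, 40L),
    amin_area_cm2 = c(0.6862, 0.6035, 0.5443),
    resistance = c(0.8271, 0.7624, 1.27),
    stringsAsFactors = FALSE
  )
}

# Template parameters that are NOT in the reference table: constriction
# plateau length (from the reported level-2 plane ranges), inlet area at the
# hard palate and downstream expansion maximum (realistic adult pharynx
# values; the reference table prints only plane_Amin areas).
template_shape_params <- function() {
  data.frame(
    template = c("FTP1_MC", "FTP1_MO", "FTP2_MC", "FTP2_MO",
                 "FTP3_MC", "FTP3_MO", "FTP4_MC", "FTP4_MO"),
    plateau_mm = c(0, 0, 20, 12.5, 10.5, 9.5, 0, 6),
    inlet_area_mm2 = c(250, 280, 200, 250, 220, 220, 200, 250),
    expansion_area_mm2 = c(300, 300, 280, 280, 260, 260, 220, 180),
    stringsAsFactors = FALSE
  )
}
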