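#' Specify a synthetic hourglass airway geometry
#'
#' Builds the parameter set for the parametric hourglass lumen generator.
#' Named templates reproduce the morphometry (plane counts, dividing plane,
#' velopharyngeal plane_Amin location and area) of the eight reference
#' subjects ([ftp_reference_morphometry()]); `template = "custom"` takes all
#' parameters explicitly.
#'
#' The lumen tapers monotonically from `inlet_area_mm2` at the top (plane I,
#' hard-palate level) down to the global minimum `amin_area_mm2` at the
#' requested relative position, optionally holds a near-constant constricted
#' plateau of length `constriction_plateau_mm` just downstream of the
#' minimum (area rises by at most 0.4% across the plateau, so the minimum
#' stays unique), then expands smoothly to `expansion_area_mm2` at the
#' bottom (plane IV, epiglottis tip).
#'
#' @param template one of `"FTP1_MC"`, `"FTP1_MO"`, `"FTP2_MC"`, `"FTP2_MO"`,
#'   `"FTP3_MC"`, `"FTP3_MO"`, `"FTP4_MC"`, `"FTP4_MO"`, `"custom"`.
#' @param length_mm axial length of the segment (plane I to plane IV), mm.
#' @param amin_area_mm2 area of the minimum cross-section, mm^2.
#' @param amin_relative_position position of the minimum along the segment,
#'   strictly inside (0, 1); 0 = plane I, 1 = plane IV.
#' @param constriction_plateau_mm length of the near-constant constricted
#'   segment downstream of the minimum, mm (>= 0).
#' @param expansion_area_mm2 downstream maximum area, mm^2.
#' @param inlet_area_mm2 area at plane I, mm^2.
#' @param dividing_relative_position position of the soft-palate-tip
#'   dividing plane (velopharynx/oropharynx interface) along the segment.
#' @param cross_section `"circle"` or `"ellipse"`.
#' @param aspect ellipse aspect ratio (anteroposterior/lateral); ignored for
#'   circles.
#' @param n_theta angular mesh resolution (vertices per ring), >= 16.
#' @param noise_amplitude relative area noise amplitude (0 = smooth).
#' @param spacing_mm axial grid spacing, mm (0.5 by default, matching the
#'   plane stack convention).
#' @param seed integer seed controlling noise and downstream mesh/field
#'   perturbations.
#' @return An object of class `airway_spec` (a named list).
#' @examples
#' spec <- airway_spec("FTP4_MO")
#' prof <- make_area_profile(spec)
#' min(prof$area_mm2)  # 54.43 mm^2 = 0.5443 cm^2
#' @export
airway_spec <- function(template = "custom",
                        length_mm = 50,
                        amin_area_mm2 = 100,
                        amin_relative_position = 0.5,
                        constriction_plateau_mm = 0,
                        expansion_area_mm2 = 200,
                        inlet_area_mm2 = 250,
                        dividing_relative_position = 0.55,
                        cross_section = c("circle", "ellipse"),
                        aspect = 1,
                        n_theta = 64,
                        noise_amplitude = 0,
                        spacing_mm = 0.5,
                        seed = 1L) {
  cross_section <- match.arg(cross_section)
  templates <- ftp_reference_morphometry()
  if (!identical(template, "custom")) {
    row <- templates[templates$template == template, ]
    if (nrow(row) != 1L) {
      stop("unknown template '", template, "'", call. = FALSE)
    }
    shp <- template_shape_params()
    shp <- shp[shp$template == template, ]
    length_mm <- (row$n_planes - 1L) * spacing_mm
    amin_area_mm2 <- row$amin_area_cm2 * 100
    amin_relative_position <- (row$amin_index - 1L) / (row$n_planes - 1L)
    dividing_relative_position <- (row$dividing_index - 1L) / (row$n_planes - 1L)
    constriction_plateau_mm <- shp$plateau_mm
    inlet_area_mm2 <- shp$inlet_area_mm2
    expansion_area_mm2 <- shp$expansion_area_mm2
  }
  stopifnot_scalar(length_mm, "length_mm", positive = TRUE)
  stopifnot_scalar(amin_area_mm2, "amin_area_mm2", positive = TRUE)
  stopifnot_scalar(expansion_area_mm2, "expansion_area_mm2", positive = TRUE)
  stopifnot_scalar(inlet_area_mm2, "inlet_area_mm2", positive = TRUE)
  stopifnot_scalar(constriction_plateau_mm, "constriction_plateau_mm",
                   nonneg = TRUE)
  stopifnot_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  if (amin_area_mm2 >= expansion_area_mm2) {
    stop("'amin_area_mm2' must be smaller than 'expansion_area_mm2'",
         call. = FALSE)
  }
  if (amin_area_mm2 >= inlet_area_mm2) {
    stop("'amin_area_mm2' must be smaller than 'inlet_area_mm2'",
         call. = FALSE)
  }
  if (amin_relative_position <= 0 || amin_relative_position >= 1) {
    stop("'amin_relative_position' must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (n_theta < 16) stop("'n_theta' must be >= 16", call. = FALSE)
  if (aspect <= 0) stop("'aspect' must be > 0", call. = FALSE)
  structure(
    list(template = template,
         length_mm = length_mm,
         amin_area_mm2 = amin_area_mm2,
         amin_relative_position = amin_relative_position,
         constriction_plateau_mm = constriction_plateau_mm,
         expansion_area_mm2 = expansion_area_mm2,
         inlet_area_mm2 = inlet_area_mm2,
         dividing_relative_position = dividing_relative_position,
         cross_section = cross_section,
         aspect = if (cross_section == "circle") 1 else aspect,
         n_theta = as.integer(n_theta),
         noise_amplitude = noise_amplitude,
         spacing_mm = spacing_mm,
         seed = as.integer(seed)),
    class = "airway_spec"
  )
}

#' Generate the axial area function A(z) of a synthetic airway
#'
#' Evaluates the hourglass area profile of an [airway_spec()] on a regular
#' axial grid. Planes are perpendicular to the z axis; z *decreases*
#' downstream (plane index increases downstream), with plane I at
#' `z = length_mm` and plane IV at `z = 0`.
#'
#' The profile has a unique global minimum equal to `amin_area_mm2` exactly
#' at the grid index nearest the requested relative position, a monotone
#' cosine-smooth taper above it, a plateau (area within 0.4% of the
#' minimum) of the requested length just downstream, and a smooth expansion to
#' `expansion_area_mm2` below. With `noise_amplitude > 0`, multiplicative
#' noise is added everywhere except the minimum plane, clamped so the
#' minimum stays global and unique.
#'
#' @param spec an [airway_spec()].
#' @return An object of class `area_profile`: a list with `z_mm` (strictly
#'   decreasing), `area_mm2`, `spacing_mm`, and `landmarks` (named indices
#'   `top`, `dividing`, `bottom`, `amin`).
#' @export
make_area_profile <- function(spec) {
  stopifnot(inherits(spec, "airway_spec"))
  h <- spec$spacing_mm
  n <- as.integer(round(spec$length_mm / h)) + 1L
  if (n < 5L) stop("segment too short for the requested spacing", call. = FALSE)
  t_mm <- (seq_len(n) - 1L) * h          # distance downstream of plane I
  L <- t_mm[n]
  i_amin <- 1L + as.integer(round(spec$amin_relative_position * (n - 1L)))
  i_amin <- max(2L, min(n - 1L, i_amin))
  t0 <- t_mm[i_amin]
  P <- spec$constriction_plateau_mm
  if (t0 + P >= L) {
    stop("constriction plateau extends past the end of the segment",
         call. = FALSE)
  }
  te <- t0 + P
  a_min <- spec$amin_area_mm2
  edge <- if (P > 0) a_min * 1.004 else a_min

  area <- numeric(n)
  up <- t_mm < t0
  area[up] <- a_min +
    (spec$inlet_area_mm2 - a_min) * smoothstep((t0 - t_mm[up]) / t0)
  mid <- t_mm >= t0 & t_mm <= te
  if (P > 0) {
    area[mid] <- a_min * (1 + 0.004 * ((t_mm[mid] - t0) / P)^2)
  } else {
    area[mid] <- a_min
  }
  dn <- t_mm > te
  area[dn] <- edge +
    (spec$expansion_area_mm2 - edge) * smoothstep((t_mm[dn] - te) / (L - te))

  if (spec$noise_amplitude > 0) {
    eta <- with_seed(spec$seed, stats::rnorm(n))
    eta <- pmin(pmax(eta, -2), 2)
    area <- area * (1 + spec$noise_amplitude * eta)
    # keep the configured minimum unique and exact
    area[i_amin] <- a_min
    idx <- setdiff(seq_len(n), i_amin)
    area[idx] <- pmax(area[idx], a_min * (1 + 1e-9))
  }

  i_div <- 1L + as.integer(round(spec$dividing_relative_position * (n - 1L)))
  i_div <- max(2L, min(n - 1L, i_div))
  structure(
    list(z_mm = L - t_mm,
         area_mm2 = area,
         spacing_mm = h,
         landmarks = list(top = 1L, dividing = i_div, bottom = n,
                          amin = i_amin)),
    class = "area_profile"
  )
}

#' @export
print.area_profile <- function(x, ...) {
  n <- length(x$z_mm)
  cat("Axial area profile:", n, "planes,",
      sprintf("%.1f mm at %.2f mm spacing\n",
              (n - 1L) * x$spacing_mm, x$spacing_mm))
  cat(sprintf("  area range %.2f - %.2f mm^2; minimum at plane %d\n",
              min(x$area_mm2), max(x$area_mm2), x$landmarks$amin))
  cat("  landmarks: top = plane 1, dividing = plane",
      x$landmarks$dividing, ", bottom = plane", x$landmarks$bottom, "\n")
  invisible(x)
}
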