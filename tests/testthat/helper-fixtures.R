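# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk.

# Constant-area circular profile (a straight tube). Degenerate for
# plane_Amin search by design.
cylinder_profile <- function(r_mm = 5, length_mm = 50, spacing_mm = 0.5) {
  n <- as.integer(round(length_mm / spacing_mm)) + 1L
  structure(
    list(z_mm = length_mm - (seq_len(n) - 1L) * spacing_mm,
         area_mm2 = rep(pi * r_mm^2, n),
         spacing_mm = spacing_mm,
         landmarks = list(top = 1L, dividing = n %/% 2L, bottom = n,
                          amin = n %/% 2L)),
    class = "area_profile"
  )
}

# Minimal spec carrying just what make_surface_mesh() needs.
mesh_spec <- function(n_theta = 64L, cross_section = "circle", aspect = 1) {
  structure(list(cross_section = cross_section,
                 aspect = if (cross_section == "circle") 1 else aspect,
                 n_theta = as.integer(n_theta)),
            class = "airway_spec")
}

cylinder_mesh <- function(r_mm = 5, length_mm = 50, n_theta = 64L,
                          spacing_mm = 0.5) {
  make_surface_mesh(cylinder_profile(r_mm, length_mm, spacing_mm),
                    mesh_spec(n_theta))
}

# An hourglass spec with explicit parameters (custom template).
hourglass_spec <- function(length_mm = 50, amin = 100, rel = 0.5,
                           plateau = 0, expansion = 200, inlet = 250,
                           n_theta = 64L, seed = 1L, ...) {
  airway_spec("custom", length_mm = length_mm, amin_area_mm2 = amin,
              amin_relative_position = rel,
              constriction_plateau_mm = plateau,
              expansion_area_mm2 = expansion, inlet_area_mm2 = inlet,
              n_theta = n_theta, seed = seed, ...)
}

all_templates <- ftp_reference_morphometry()$template
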