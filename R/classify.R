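# Three-level jet/separation segmentation of the plane stack and
# recirculation (reversed near-wall flow) detection.

#' Area-weighted reversed-flow fraction of a plane
#'
#' Fraction of the plane's area whose axial velocity opposes the bulk flow
#' direction -- the footprint of the recirculation region.
#'
#' @param velocity n x 3 matrix of sample velocities, m/s.
#' @param area_weight sample area weights.
#' @param flow_direction unit 3-vector of the bulk flow direction.
#' @return Fraction in `[0, 1]`.
#' @export
reverse_flow_fraction <- function(velocity, area_weight,
                                  flow_direction = c(0, 0, -1)) {
  velocity <- matrix(velocity, ncol = 3L)
  if (nrow(velocity) == 0L || sum(area_weight) <= 0) {
    stop("plane has no samples", call. = FALSE)
  }
  nvec <- flow_direction / sqrt(sum(flow_direction^2))
  rev <- as.numeric(velocity %*% nvec) < 0
  sum(area_weight[rev]) / sum(area_weight)
}

#' Per-plane reversed-flow fractions of a sampled field
#'
#' @param field a [make_flow_field()]-style `flow_field_samples` object.
#' @return Numeric vector, one fraction per plane (stack order).
#' @export
reverse_flow_fractions <- function(field) {
  idx <- sort(unique(field$planes$plane_index))
  vapply(idx, function(i) {
    s <- field$planes[field$planes$plane_index == i, ]
    reverse_flow_fraction(cbind(s$ux_ms, s$uy_ms, s$uz_ms),
                          s$area_weight_mm2, field$flow_direction)
  }, numeric(1L))
}

#' Classify the plane stack into jet-formation / pre-separation /
#' full-separation levels
#'
#' Level 1 (jet formation) spans plane I down to plane_Amin inclusive:
#' the converging lumen accumulates jet kinetic energy. Level 2 (pre full
#' separation) continues downstream while the lumen stays nearly
#' constricted (`A/A_amin <= theta_exp`) *and* the reversed-flow footprint
#' stays small (`reverse fraction < theta_rec`): the constant constricted
#' segment with at most transient, regional recirculation. Level 3 (full
#' flow separation) is the remainder: the rapidly expanded lumen with an
#' established recirculation region. Levels are contiguous and ordered;
#' level 2 may be empty.
#'
#' The thresholds are declared model parameters (the three-level taxonomy
#' is qualitative in origin); defaults `theta_exp = 1.5`,
#' `theta_rec = 0.10`.
#'
#' @param sections a `plane_sections` data.frame (areas used for the
#'   expansion test).
#' @param amin_index plane index of plane_Amin.
#' @param reverse_fractions per-plane reversed-flow fractions
#'   ([reverse_flow_fractions()]); `NULL` treats all planes as
#'   recirculation-free.
#' @param theta_exp luminal expansion threshold (area ratio to plane_Amin).
#' @param theta_rec reversed-flow fraction threshold.
#' @return List of class `level_segmentation`: `labels` (integer 1/2/3 per
#'   plane), `level2_start`, `level3_start` (plane indices, `NA` when the
#'   level is empty), and `reverse_fractions`.
#' @export
classify_levels <- function(sections, amin_index, reverse_fractions = NULL,
                            theta_exp = 1.5, theta_rec = 0.10) {
  n <- nrow(sections)
  if (!amin_index %in% sections$index) {
    stop("'amin_index' is not a plane of the stack", call. = FALSE)
  }
  if (is.null(reverse_fractions)) reverse_fractions <- rep(0, n)
  if (length(reverse_fractions) != n) {
    stop("'reverse_fractions' must have one value per plane", call. = FALSE)
  }
  a_amin <- sections$area_mm2[sections$index == amin_index]
  labels <- integer(n)
  pos_amin <- which(sections$index == amin_index)
  labels[seq_len(pos_amin)] <- 1L
  if (pos_amin < n) {
    down <- (pos_amin + 1L):n
    ok2 <- sections$area_mm2[down] / a_amin <= theta_exp &
      reverse_fractions[down] < theta_rec
    # level 2 is the contiguous run immediately after plane_Amin
    first_bad <- match(FALSE, ok2)
    n2 <- if (is.na(first_bad)) length(down) else first_bad - 1L
    if (n2 > 0L) labels[down[seq_len(n2)]] <- 2L
    if (n2 < length(down)) labels[down[(n2 + 1L):length(down)]] <- 3L
  }
  structure(
    list(labels = labels,
         level2_start = if (any(labels == 2L)) {
           sections$index[match(2L, labels)]
         } else {
           NA_integer_
         },
         level3_start = if (any(labels == 3L)) {
           sections$index[match(3L, labels)]
         } else {
           NA_integer_
         },
         reverse_fractions = reverse_fractions,
         theta_exp = theta_exp, theta_rec = theta_rec),
    class = "level_segmentation"
  )
}

#' @export
print.level_segmentation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 1:3))
  cat("Level segmentation: jet formation", tab[[1L]],
      "planes; pre-separation", tab[[2L]],
      "planes; full separation", tab[[3L]], "planes\n")
  cat("  level 2 starts at plane", x$level2_start,
      "; level 3 starts at plane", x$level3_start, "\n")
  invisible(x)
}
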