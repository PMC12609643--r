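#' DADA index from iris and pupil radii
#'
#' The DADA index (pupil index value) is the ratio of the annular iris surface
#' to the pupil surface, `(IRr^2 - Pr^2) / Pr^2` with `IRr` the iris radius
#' and `Pr` the pupil radius. It falls towards 0 as the pupil dilates to fill
#' the iris (parasympathetic failure) and rises with miosis (sympathetic
#' failure). Because it is a ratio of areas it is scale invariant: both radii
#' may be supplied in any common unit.
#'
#' @param iris_radius iris radius (same unit as `pupil_radius`); must be
#'   `>= pupil_radius`
#' @param pupil_radius pupil radius, strictly positive
#' @return dimensionless index, `>= 0`; vectorised over both arguments
#' @seealso [implied_iris_radius()] for the inverse
#' @export
#' @examples
#' dada_index(2, 1)          # 3: iris annulus three times the pupil area
#' dada_index(5375.6, 2950)  # about 2.32, a healthy control eye
dada_index <- function(iris_radius, pupil_radius) {
  if (!length(iris_radius) || !length(pupil_radius)) {
    stop_domain("iris_radius and pupil_radius must be non-empty")
  }
  if (any(!is.finite(pupil_radius)) || any(!is.finite(iris_radius))) {
    stop_domain("radii must be finite")
  }
  if (any(pupil_radius <= 0)) stop_domain("pupil_radius must be > 0")
  if (any(iris_radius < pupil_radius)) {
    stop_domain("iris_radius must be >= pupil_radius")
  }
  (iris_radius^2 - pupil_radius^2) / pupil_radius^2
}

#' Iris radius implied by a DADA index and pupil radius
#'
#' Inverts the index formula: `IRr = Pr * sqrt(dada + 1)`.
#'
#' @param dada DADA index, `>= 0`
#' @param pupil_radius pupil radius, strictly positive
#' @return iris radius in the unit of `pupil_radius`
#' @export
#' @examples
#' implied_iris_radius(3, 1)    # 2
#' implied_iris_radius(0, 5)    # 5: pupil fills the iris
implied_iris_radius <- function(dada, pupil_radius) {
  if (any(!is.finite(dada)) || any(!is.finite(pupil_radius))) {
    stop_domain("inputs must be finite")
  }
  if (any(dada < 0)) stop_domain("dada must be >= 0")
  if (any(pupil_radius <= 0)) stop_domain("pupil_radius must be > 0")
  pupil_radius * sqrt(dada + 1)
}

#' Qualitative interpretation of a DADA-index change
#'
#' A fall of the index relative to baseline reflects mydriasis from failing
#' parasympathetic (Edinger-Westphal / cranial) drive; a rise reflects miosis
#' from failing sympathetic (cervicothoracic spinal) drive. Changes within
#' `tolerance_frac` of baseline are indeterminate.
#'
#' @param baseline_dada,current_dada DADA index values, `>= 0`
#' @param tolerance_frac relative dead-band around baseline (default 0.05)
#' @return one of `"cranial_parasympathetic_failure"`,
#'   `"spinal_sympathetic_failure"`, `"indeterminate"`; vectorised
#' @export
#' @examples
#' interpret_dada_change(2.32, 1.06)  # index halved: cranial failure
interpret_dada_change <- function(baseline_dada, current_dada,
                                  tolerance_frac = 0.05) {
  if (any(baseline_dada < 0) || any(current_dada < 0)) {
    stop_domain("DADA index values must be >= 0")
  }
  if (any(tolerance_frac < 0)) stop_domain("tolerance_frac must be >= 0")
  n <- max(length(baseline_dada), length(current_dada))
  b <- rep_len(baseline_dada, n)
  cur <- rep_len(current_dada, n)
  rel <- ifelse(b > 0, (cur - b) / b,
                ifelse(cur > 0, Inf, 0))
  out <- rep("indeterminate", n)
  out[rel < -tolerance_frac] <- "cranial_parasympathetic_failure"
  out[rel > tolerance_frac] <- "spinal_sympathetic_failure"
  out
}
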