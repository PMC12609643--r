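new_classification <- function(criterion, ids, calls, threshold) {
  calls <- as.character(calls)
  stopifnot(length(ids) == length(calls))
  structure(
    list(criterion = criterion,
         threshold = threshold,
         per_subject = data.frame(id = ids, call = calls,
                                  stringsAsFactors = FALSE),
         n_deceased = sum(calls == "deceased"),
         n_viable = sum(calls == "viable")),
    class = "pupil_classification")
}

#' @export
print.pupil_classification <- function(x, ...) {
  cat(sprintf("Classification by %s (threshold %g): %d deceased, %d viable\n",
              x$criterion, x$threshold, x$n_deceased, x$n_viable))
  invisible(x)
}

#' Classify subjects as deceased by the fixed-and-dilated pupil criterion
#'
#' The bedside criterion: a subject is called deceased when the pupil diameter
#' is at least `diameter_threshold_um`. The default 8000 um sits strictly
#' between the sham maximum (6850 um) and the study minimum (8780 um) of the
#' default group parameters, so on default synthetic cohorts every study
#' subject is called deceased and every control/sham subject viable. Pupil
#' reactivity itself is not modelled.
#'
#' @param cohort a `pupil_cohort`
#' @param diameter_threshold_um pupil-diameter cut-off in micrometres
#' @return a `pupil_classification`: criterion, per-subject calls, and
#'   deceased/viable counts
#' @export
classify_fixed_dilated <- function(cohort, diameter_threshold_um = 8000) {
  if (!is.numeric(diameter_threshold_um) || diameter_threshold_um <= 0) {
    stop_domain("diameter_threshold_um must be > 0")
  }
  diam <- 2 * cohort$pupil_radius
  calls <- ifelse(diam >= diameter_threshold_um, "deceased", "viable")
  new_classification("pupil_diameter", cohort$id, calls,
                     diameter_threshold_um)
}

# weighted pool-adjacent-violators for a non-DEcreasing fit
pava_increasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  # blocks as stacks of (value, weight, size)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; sz[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) /
        (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = sz[seq_len(k)])
}

#' Calibrate the monotone DADA-to-degeneration map
#'
#' Fits a non-increasing map from DADA index to degeneration percentage by
#' weighted pool-adjacent-violators (isotonic regression on the dada-sorted
#' training pairs; duplicated dada values are pre-pooled by their weighted
#' mean). The paper-level reading is that lower index values (wider pupils)
#' correspond to heavier Edinger-Westphal degeneration; the fitted map turns
#' the histological ">80% degenerated" death criterion into an index-based
#' classifier via [classify_dada()].
#'
#' @param dada numeric vector of DADA index values (length >= 2, not all equal)
#' @param degen_pct matching degeneration percentages in `[0, 100]`
#' @param threshold_pct death threshold on the predicted percentage
#'   (default 80, strict inequality at classification time)
#' @return a `dada_calibration`: `knots` (`data.frame` of strictly increasing
#'   `dada` and non-increasing fitted `degen_pct`) and `threshold_pct`
#' @seealso [predict.dada_calibration()], [classify_dada()]
#' @export
#' @examples
#' cal <- calibrate_dada_map(c(0.6, 1.6), c(95, 60))
#' predict(cal, 1.1)  # 77.5, the linear midpoint
calibrate_dada_map <- function(dada, degen_pct, threshold_pct = 80) {
  if (length(dada) != length(degen_pct)) stop_domain("length mismatch")
  keep <- !is.na(dada) & !is.na(degen_pct)
  dada <- dada[keep]; degen_pct <- degen_pct[keep]
  if (length(dada) < 2) stop_domain("need at least 2 training pairs")
  if (diff(range(dada)) == 0) stop_domain("dada values must not all be equal")
  if (any(degen_pct < 0 | degen_pct > 100)) {
    stop_domain("degen_pct must lie in [0, 100]")
  }
  if (threshold_pct < 0 || threshold_pct >= 100) {
    stop_domain("threshold_pct must lie in [0, 100)")
  }
  ord <- order(dada)
  x <- dada[ord]; y <- degen_pct[ord]
  # pool exact duplicates in x first
  ux <- unique(x)
  uy <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
  uw <- vapply(ux, function(v) sum(x == v), numeric(1))
  # non-increasing fit = negated increasing fit
  fit <- -pava_increasing(-uy, uw)
  structure(list(knots = data.frame(dada = ux, degen_pct = fit),
                 threshold_pct = threshold_pct),
            class = "dada_calibration")
}

#' Predict degeneration percentage from a calibrated map
#'
#' Piecewise-linear interpolation between calibration knots, held constant
#' beyond the training range and clamped to `[0, 100]`.
#'
#' @param object a `dada_calibration`
#' @param dada DADA index values to predict at
#' @param ... unused
#' @return predicted degeneration percentages
#' @export
predict.dada_calibration <- function(object, dada, ...) {
  k <- object$knots
  if (nrow(k) == 1) return(rep(clamp(k$degen_pct, 0, 100), length(dada)))
  clamp(stats::approx(k$dada, k$degen_pct, xout = dada, rule = 2,
                      ties = "ordered")$y, 0, 100)
}

#' @export
print.dada_calibration <- function(x, ...) {
  cat(sprintf("DADA calibration: %d knots, death threshold > %g%% degeneration\n",
              nrow(x$knots), x$threshold_pct))
  print(x$knots, digits = 4)
  invisible(x)
}

#' Classify subjects as deceased by the DADA-index criterion
#'
#' A subject is called deceased when the degeneration percentage predicted
#' from its DADA index strictly exceeds the calibration's `threshold_pct`
#' (a prediction of exactly 80 is viable). With the default generator
#' (`n_over80 = 8`) and a calibration trained on the same cohort's study-group
#' pairs, this reproduces the 8-of-12 deceased / 4 viable contrast against the
#' 12-of-12 call of [classify_fixed_dilated()].
#'
#' @param cohort a `pupil_cohort` (must carry `dada_index`)
#' @param calibration a `dada_calibration` from [calibrate_dada_map()]
#' @return a `pupil_classification`
#' @export
classify_dada <- function(cohort, calibration) {
  if (!inherits(calibration, "dada_calibration")) {
    stop_domain("calibration must be a dada_calibration")
  }
  if (nrow(cohort) == 0) {
    return(new_classification("dada_index", character(0), character(0),
                              calibration$threshold_pct))
  }
  if (is.null(cohort$dada_index) || any(is.na(cohort$dada_index))) {
    stop_domain("cohort must have complete dada_index values")
  }
  pred <- predict(calibration, cohort$dada_index)
  calls <- ifelse(pred > calibration$threshold_pct, "deceased", "viable")
  new_classification("dada_index", cohort$id, calls,
                     calibration$threshold_pct)
}

#' Serialise / restore a DADA calibration as JSON
#'
#' @param calibration a `dada_calibration`
#' @param path optional file; when `NULL` the JSON string is returned
#' @return `calibration_to_json`: JSON string or `path`;
#'   `calibration_from_json`: a `dada_calibration`
#' @export
calibration_to_json <- function(calibration, path = NULL) {
  obj <- list(schema = "dada_calibration/1",
              threshold_pct = calibration$threshold_pct,
              knots = calibration$knots)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname calibration_to_json
#' @param json JSON string or path to a JSON file
#' @export
calibration_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(knots = data.frame(dada = obj$knots$dada,
                                    degen_pct = obj$knots$degen_pct),
                 threshold_pct = obj$threshold_pct),
            class = "dada_calibration")
}
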