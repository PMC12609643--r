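#' Default generator parameters for the three experimental groups
#'
#' One row per group (control, sham, study) carrying the published descriptive
#' statistics of the rabbit subarachnoid-haemorrhage experiment the generator
#' emulates: group size, and mean/SD/min/max for pupil diameter (um), DADA
#' index (dimensionless) and degenerated Edinger-Westphal neuron density
#' (n/mm^3). These defaults are also shipped as a YAML file at
#' `system.file("extdata", "group_params_default.yaml", package = "pupilratio")`.
#'
#' @return a `data.frame` with one row per group and columns
#'   `group`, `n`, and `<variable>_{mean,sd,min,max}` for
#'   `pupil_diameter`, `dada`, `degen`.
#' @export
#' @examples
#' default_group_params()
default_group_params <- function() {
  p <- data.frame(
    group = c("control", "sham", "study"),
    n     = c(5L, 5L, 12L),
    pupil_diameter_mean = c(5900.00, 6310.00, 9989.50),
    pupil_diameter_sd   = c(546.32, 533.35, 747.12),
    pupil_diameter_min  = c(5200.00, 5452.00, 8780.00),
    pupil_diameter_max  = c(6600.00, 6850.00, 11138.00),
    dada_mean = c(2.32, 1.95, 1.06),
    dada_sd   = c(0.43, 0.37, 0.31),
    dada_min  = c(1.78, 1.47, 0.58),
    dada_max  = c(2.90, 2.41, 1.65),
    degen_mean = c(3.00, 12.00, 18.00),
    degen_sd   = c(0.95, 2.92, 4.00),
    degen_min  = c(1.80, 8.20, 11.00),
    degen_max  = c(4.20, 15.80, 25.00),
    stringsAsFactors = FALSE
  )
  validate_group_params(p)
  p
}

GROUPS <- c("control", "sham", "study")
VARIABLES <- c("pupil_diameter", "dada", "degen")

validate_group_params <- function(params) {
  if (!is.data.frame(params)) {
    stop_config("group parameters must be a data.frame")
  }
  missing_groups <- setdiff(GROUPS, params$group)
  if (length(missing_groups)) {
    stop_config(paste0("missing group parameters for: ",
                       paste(missing_groups, collapse = ", ")))
  }
  if (anyDuplicated(params$group)) {
    stop_config("duplicated group rows in parameters")
  }
  for (v in VARIABLES) {
    cols <- paste0(v, c("_mean", "_sd", "_min", "_max"))
    missing_cols <- setdiff(cols, names(params))
    if (length(missing_cols)) {
      stop_config(paste0("missing parameter columns: ",
                         paste(missing_cols, collapse = ", ")))
    }
    m <- params[[cols[1]]]; s <- params[[cols[2]]]
    lo <- params[[cols[3]]]; hi <- params[[cols[4]]]
    if (any(s <= 0)) stop_config(paste0(v, "_sd must be > 0"))
    if (any(lo > m | m > hi)) {
      stop_config(paste0(v, ": need min <= mean <= max in every group"))
    }
  }
  if (any(params$n < 1)) stop_config("group sizes must be positive")
  invisible(params)
}

#' Read generator parameters from a YAML or JSON file
#'
#' The file holds one mapping per group with keys mirroring the columns of
#' [default_group_params()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` parameter file
#' @return validated parameter `data.frame`
#' @export
read_group_params <- function(path) {
  if (!file.exists(path)) stop_config(paste0("parameter file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(raw)) {
    p <- raw
  } else {
    p <- do.call(rbind, lapply(raw, function(g) as.data.frame(g, stringsAsFactors = FALSE)))
    rownames(p) <- NULL
  }
  p$n <- as.integer(p$n)
  validate_group_params(p)
  p
}

#' Analytic group means implied by the generator
#'
#' Computes, for each group and variable, the expected value of the generated
#' quantity under the latent-severity model: the closed-form truncated-normal
#' mean for degeneration density, and (for pupil diameter and DADA index) the
#' affine image of the normalised degeneration integrated over its truncated
#' normal law, including the closed-form effect of clamping the Gaussian
#' measurement noise back into the group range. These are the
#' truncation-corrected calibration targets the generator is tested against.
#'
#' @param params group parameters, see [default_group_params()]
#' @param noise_frac noise standard deviation as a fraction of each group's
#'   variable range (default 0.01)
#' @return `data.frame` with columns `group`, `pupil_diameter`, `dada`, `degen`
#' @export
expected_group_means <- function(params = default_group_params(),
                                 noise_frac = 0.01) {
  validate_group_params(params)
  out <- data.frame(group = params$group,
                    pupil_diameter = NA_real_,
                    dada = NA_real_,
                    degen = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(params))) {
    g <- params[i, ]
    out$degen[i] <- truncnorm_mean(g$degen_mean, g$degen_sd,
                                   g$degen_min, g$degen_max)
    drange <- g$degen_max - g$degen_min
    prange <- g$pupil_diameter_max - g$pupil_diameter_min
    arange <- g$dada_max - g$dada_min
    out$pupil_diameter[i] <- integrate_over_truncnorm(function(d) {
      centre <- g$pupil_diameter_min + (d - g$degen_min) / drange * prange
      vapply(centre, clamped_noise_mean, numeric(1),
             s = noise_frac * prange,
             lo = g$pupil_diameter_min, hi = g$pupil_diameter_max)
    }, g$degen_mean, g$degen_sd, g$degen_min, g$degen_max)
    out$dada[i] <- integrate_over_truncnorm(function(d) {
      centre <- g$dada_max - (d - g$degen_min) / drange * arange
      vapply(centre, clamped_noise_mean, numeric(1),
             s = noise_frac * arange, lo = g$dada_min, hi = g$dada_max)
    }, g$degen_mean, g$degen_sd, g$degen_min, g$degen_max)
  }
  out
}
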