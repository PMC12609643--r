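REPORT_SCHEMA <- "pupilratio_report/1"

PIPELINE_VARS <- c(pupil_diameter = "pupil diameter (um)",
                   dada_index = "DADA index",
                   degen_density = "degenerated neuron density (n/mm^3)")

variable_values <- function(cohort, variable) {
  switch(variable,
         pupil_diameter = 2 * cohort$pupil_radius,
         dada_index = cohort$dada_index,
         degen_density = cohort$degen_density,
         stop_config(paste0("unknown variable: ", variable)))
}

#' Descriptive summary of one sample
#'
#' Mean, SD (`n - 1` denominator, `NA` for a single value), median (mid-point
#' convention for even n), min and max.
#'
#' @param values non-empty numeric sample
#' @return one-row `data.frame` with columns `n, mean, sd, median, min, max`
#' @export
#' @examples
#' summarize_group(1:5)  # mean 3, sd sqrt(2.5)
summarize_group <- function(values) {
  check_sample(values, "values")
  data.frame(n = length(values),
             mean = mean(values),
             sd = if (length(values) > 1) stats::sd(values) else NA_real_,
             median = stats::median(values),
             min = min(values),
             max = max(values))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("pupilratio_pipeline_error", class(e))))
  })
}

PAIRWISE <- list(c("control", "sham"), c("control", "study"), c("sham", "study"))

#' Run the full analysis pipeline
#'
#' Orchestrates, deterministically for a given configuration: cohort
#' generation (or loading), validation, per-group descriptive summaries of the
#' three variables (pupil diameter, DADA index, degenerated neuron density), a
#' Kruskal-Wallis test per variable, Bonferroni-corrected pairwise
#' Mann-Whitney U post-hoc tests (run only when the Kruskal-Wallis p-value is
#' below `alpha`, unless `force_pairwise`), Spearman correlations among the
#' three variables within the study group, and the two deceased/viable
#' classifications (fixed-dilated pupil-diameter threshold versus the
#' calibrated DADA-index criterion, with the calibration trained on the
#' cohort's own study-group index/percentage pairs).
#'
#' @param cohort an existing `pupil_cohort`, a path to a cohort CSV, or `NULL`
#'   to generate one
#' @param params,noise_frac,n_over80,seed generator configuration used when
#'   `cohort` is `NULL`; see [generate_cohort()]
#' @param alpha significance level gating the post-hoc tests (default 0.05)
#' @param diameter_threshold_um pupil-diameter death threshold (default 8000)
#' @param dada_threshold_pct degeneration-percentage death threshold
#'   (default 80)
#' @param force_pairwise run pairwise tests even under a non-significant
#'   Kruskal-Wallis result
#' @param correlations_all_subjects correlate across the whole cohort instead
#'   of the study group only (off by default)
#' @return a `pupil_report` list: `schema`, `provenance`, `group_summaries`,
#'   `kruskal_wallis`, `pairwise`, `correlations`, `classifications`
#' @export
#' @examples
#' rep <- run_pipeline(seed = 7)
#' rep$classifications$dada_index$n_deceased   # 8 at defaults
run_pipeline <- function(cohort = NULL,
                         params = default_group_params(),
                         noise_frac = 0.01,
                         n_over80 = 8L,
                         seed = 1L,
                         alpha = 0.05,
                         diameter_threshold_um = 8000,
                         dada_threshold_pct = 80,
                         force_pairwise = FALSE,
                         correlations_all_subjects = FALSE) {
  cohort <- stage("cohort", {
    if (is.null(cohort)) {
      generate_cohort(params = params, noise_frac = noise_frac,
                      n_over80 = n_over80, seed = seed)
    } else if (is.character(cohort)) {
      read_cohort_csv(cohort)
    } else {
      cohort
    }
  })
  stage("validate", validate_cohort(cohort, dada_tol = 1e-6))

  summaries <- stage("summarise", {
    out <- do.call(rbind, lapply(names(PIPELINE_VARS), function(v) {
      do.call(rbind, lapply(GROUPS, function(g) {
        s <- summarize_group(variable_values(cohort[cohort$group == g, ], v))
        cbind(data.frame(variable = v, group = g, stringsAsFactors = FALSE), s)
      }))
    }))
    rownames(out) <- NULL
    out
  })

  kw <- stage("kruskal_wallis", {
    res <- lapply(names(PIPELINE_VARS), function(v) {
      kruskal_wallis(lapply(GROUPS, function(g) {
        variable_values(cohort[cohort$group == g, ], v)
      }), comparison = v)
    })
    names(res) <- names(PIPELINE_VARS)
    res
  })

  pairwise <- stage("pairwise_mwu", {
    res <- lapply(names(PIPELINE_VARS), function(v) {
      run_posthoc <- force_pairwise || kw[[v]]$p_raw < alpha
      cells <- lapply(PAIRWISE, function(pr) {
        label <- paste(pr, collapse = " vs ")
        if (!run_posthoc) {
          return(list(comparison = label, computed = FALSE,
                      statistic = NA_real_, p_raw = NA_real_,
                      p_corrected = NA_real_, method = NA_character_,
                      sided = "two"))
        }
        tst <- mann_whitney_u(
          variable_values(cohort[cohort$group == pr[1], ], v),
          variable_values(cohort[cohort$group == pr[2], ], v),
          sided = "two", comparison = label)
        list(comparison = label, computed = TRUE,
             statistic = unname(tst$statistic), p_raw = tst$p_raw,
             p_corrected = NA_real_, method = tst$method, sided = tst$sided)
      })
      if (run_posthoc) {
        corrected <- bonferroni(vapply(cells, `[[`, numeric(1), "p_raw"),
                                m = length(cells))
        for (i in seq_along(cells)) cells[[i]]$p_corrected <- corrected[i]
      }
      names(cells) <- vapply(cells, `[[`, character(1), "comparison")
      cells
    })
    names(res) <- names(PIPELINE_VARS)
    res
  })

  correlations <- stage("spearman", {
    sub <- if (correlations_all_subjects) cohort else cohort[cohort$group == "study", ]
    pairs <- list(c("dada_index", "pupil_diameter"),
                  c("dada_index", "degen_density"),
                  c("pupil_diameter", "degen_density"))
    res <- lapply(pairs, function(pr) {
      tst <- spearman_rho(variable_values(sub, pr[1]),
                          variable_values(sub, pr[2]),
                          sided = "two",
                          comparison = paste(pr, collapse = " vs "))
      list(pair = paste(pr, collapse = " vs "),
           rho = unname(tst$statistic), p = tst$p_raw,
           n = tst$n, method = tst$method, sided = tst$sided)
    })
    names(res) <- vapply(res, `[[`, character(1), "pair")
    res
  })

  classifications <- stage("classify", {
    study <- cohort[cohort$group == "study", ]
    cal <- calibrate_dada_map(study$dada_index, study$degen_pct,
                              threshold_pct = dada_threshold_pct)
    list(pupil_diameter = classify_fixed_dilated(cohort, diameter_threshold_um),
         dada_index = classify_dada(cohort, cal),
         calibration = cal)
  })

  structure(list(
    schema = REPORT_SCHEMA,
    provenance = list(
      package = "pupilratio",
      version = as.character(utils::packageVersion("pupilratio")),
      seed = attr(cohort, "seed") %||% NA_integer_,
      noise_frac = noise_frac, n_over80 = as.integer(n_over80),
      alpha = alpha,
      diameter_threshold_um = diameter_threshold_um,
      dada_threshold_pct = dada_threshold_pct),
    n_subjects = nrow(cohort),
    group_summaries = summaries,
    kruskal_wallis = kw,
    pairwise = pairwise,
    correlations = correlations,
    classifications = classifications),
    class = "pupil_report")
}

report_to_plain <- function(report) {
  plain_test <- function(t) list(statistic = unname(t$statistic),
                                 df = t$df, n = unname(t$n),
                                 p_raw = t$p_raw, sided = t$sided,
                                 method = t$method, comparison = t$comparison)
  plain_cls <- function(cl) list(criterion = cl$criterion,
                                 threshold = cl$threshold,
                                 n_deceased = cl$n_deceased,
                                 n_viable = cl$n_viable,
                                 per_subject = cl$per_subject)
  list(schema = report$schema,
       provenance = report$provenance,
       n_subjects = report$n_subjects,
       group_summaries = report$group_summaries,
       kruskal_wallis = lapply(report$kruskal_wallis, plain_test),
       pairwise = report$pairwise,
       correlations = report$correlations,
       classifications = list(
         pupil_diameter = plain_cls(report$classifications$pupil_diameter),
         dada_index = plain_cls(report$classifications$dada_index),
         calibration = list(
           knots = report$classifications$calibration$knots,
           threshold_pct = report$classifications$calibration$threshold_pct)))
}

fmt_p <- function(p) {
  ifelse(is.na(p), "--", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

star <- function(p, alpha = 0.05) ifelse(!is.na(p) & p < alpha, " *", "")

render_markdown <- function(report) {
  lines <- c("# Pupillometry analysis report", "",
             sprintf("Subjects: %d; seed: %s", report$n_subjects,
                     report$provenance$seed), "",
             "## Descriptive statistics and pairwise comparisons", "",
             "| Variable | Statistic | Control | Sham | Study | p (control vs sham) | p (control vs study) | p (sham vs study) |",
             "|---|---|---|---|---|---|---|---|")
  gs <- report$group_summaries
  for (v in names(PIPELINE_VARS)) {
    sv <- gs[gs$variable == v, ]
    by_g <- function(g) sv[sv$group == g, ]
    pw <- report$pairwise[[v]]
    ps <- vapply(pw, function(c) c$p_corrected, numeric(1))
    mean_row <- sprintf("| %s | Mean ± SD | %s | %s | %s |  |  |  |",
                        PIPELINE_VARS[[v]],
                        paste0(signif(by_g("control")$mean, 6), " ± ", signif(by_g("control")$sd, 4)),
                        paste0(signif(by_g("sham")$mean, 6), " ± ", signif(by_g("sham")$sd, 4)),
                        paste0(signif(by_g("study")$mean, 6), " ± ", signif(by_g("study")$sd, 4)))
    med <- function(g) sprintf("%s (%s-%s)", signif(by_g(g)$median, 6),
                               signif(by_g(g)$min, 6), signif(by_g(g)$max, 6))
    med_row <- sprintf("|  | Median (Min-Max) | %s | %s | %s | %s%s | %s%s | %s%s |",
                       med("control"), med("sham"), med("study"),
                       fmt_p(ps[1]), star(ps[1]),
                       fmt_p(ps[2]), star(ps[2]),
                       fmt_p(ps[3]), star(ps[3]))
    lines <- c(lines, mean_row, med_row)
  }
  lines <- c(lines, "",
             "p: Bonferroni-corrected two-sided Mann-Whitney U (post hoc after Kruskal-Wallis); *: significant at 0.05; --: not computed (Kruskal-Wallis non-significant).",
             "", "## Correlations (study group)", "",
             "| Pair | rho | p | N |", "|---|---|---|---|")
  for (cr in report$correlations) {
    lines <- c(lines, sprintf("| %s | %.3f | %s | %d |",
                              cr$pair, cr$rho, fmt_p(cr$p), cr$n))
  }
  cls <- report$classifications
  lines <- c(lines, "", "## Classification (deceased vs viable)", "",
             sprintf("- Pupil-diameter criterion (>= %g um): %d deceased, %d viable",
                     cls$pupil_diameter$threshold,
                     cls$pupil_diameter$n_deceased, cls$pupil_diameter$n_viable),
             sprintf("- DADA-index criterion (predicted degeneration > %g%%): %d deceased, %d viable",
                     cls$dada_index$threshold,
                     cls$dada_index$n_deceased, cls$dada_index$n_viable))
  paste(lines, collapse = "\n")
}

render_csv <- function(report) {
  rows <- do.call(rbind, lapply(names(report$pairwise), function(v) {
    do.call(rbind, lapply(report$pairwise[[v]], function(cell) {
      data.frame(variable = v, comparison = cell$comparison,
                 computed = cell$computed,
                 U = cell$statistic, p_raw = cell$p_raw,
                 p_corrected = cell$p_corrected,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(rows, con, row.names = FALSE, na = "")
  close(con)
  paste(out, collapse = "\n")
}

#' Render an analysis report
#'
#' `"json"` produces a schema-versioned, deterministic (timestamp-free) JSON
#' document; `"csv"` the 3-variable x 3-comparison pairwise-test grid;
#' `"markdown"` a human-readable report mirroring the layout of the published
#' descriptive-statistics and correlation tables.
#'
#' @param report a `pupil_report` from [run_pipeline()]
#' @param format `"json"`, `"csv"` or `"markdown"`
#' @param path optional output file; when given, the text is written there
#' @return the rendered text, invisibly when `path` is given
#' @export
render_report <- function(report, format = c("json", "csv", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  txt <- switch(format,
    json = as.character(jsonlite::toJSON(report_to_plain(report),
                                         auto_unbox = TRUE, digits = NA,
                                         na = "null", dataframe = "columns")),
    csv = render_csv(report),
    markdown = render_markdown(report))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Reload a JSON report
#'
#' @param json path to a JSON report written by [render_report()] (or the
#'   JSON text itself)
#' @return the report as a plain nested list (same content as
#'   `report_to_plain`); numeric grids restored as data.frames
#' @export
read_report_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  if (is.null(obj$schema) || obj$schema != REPORT_SCHEMA) {
    stop_config("not a pupilratio report JSON (schema mismatch)")
  }
  obj$group_summaries <- as.data.frame(obj$group_summaries)
  obj
}

#' @export
print.pupil_report <- function(x, ...) {
  cat(render_markdown(x), "\n")
  invisible(x)
}
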