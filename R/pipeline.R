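# Study-level orchestration: parameter extraction over a full image set
# and the report tables of the longitudinal analysis.
#
# Conventions applied uniformly: the four site measurements of one
# breast/time point are averaged into a single per-patient value before
# any statistic is computed (subjects are the repeated unit), and the
# dose pairing for the dose-response correlations uses the patient mean
# skin dose (a site-level pairing mode is available).

#' Extract the twelve parameters from every image
#'
#' Applies [extract_parameters()] to each image and returns tidy records,
#' one row per image x parameter (so a complete patient contributes
#' 12 x 4 sites x 2 breasts x 4 time points = 384 values). The design
#' must be complete: every patient x breast x site x time point cell must
#' be present exactly once.
#'
#' @param images List of [skin_image()] objects with full metadata.
#' @param roi Optional [circular_roi()] shared by all images; default is
#'   each image's own [default_roi()].
#' @return Tibble with columns `patient_id`, `breast`, `site`,
#'   `time_point`, `parameter`, `value`.
#' @export
extract_all <- function(images, roi = NULL) {
  meta <- dplyr::bind_rows(lapply(images, function(img) {
    tibble::tibble(patient_id = img$patient_id, breast = img$breast,
                   site = img$site, time_point = img$time_point)
  }))
  .check_completeness(meta)
  vals <- lapply(images, function(img) {
    extract_parameters(img, roi = if (is.null(roi)) default_roi(img) else roi)
  })
  records <- meta[rep(seq_len(nrow(meta)), each = 12L), ]
  records$parameter <- factor(rep(color_parameter_names(), length(images)),
                              levels = color_parameter_names())
  records$value <- as.numeric(t(do.call(rbind, vals)))
  tibble::as_tibble(records)
}

.check_completeness <- function(meta) {
  full <- expand.grid(patient_id = unique(meta$patient_id),
                      breast = .breast_levels, site = .site_levels,
                      time_point = .time_levels, stringsAsFactors = FALSE)
  key <- function(d) paste(d$patient_id, d$breast, d$site, d$time_point)
  missing <- setdiff(key(full), key(meta))
  if (length(missing) > 0L)
    stop("incomplete image set; missing (patient breast site time): ",
         paste(utils::head(missing, 5L), collapse = "; "),
         if (length(missing) > 5L) sprintf(" ... and %d more", length(missing) - 5L))
  dup <- key(meta)[duplicated(key(meta))]
  if (length(dup) > 0L)
    stop("duplicated image cell(s): ", paste(unique(dup), collapse = "; "))
  invisible(TRUE)
}

#' Average the four sites into one value per patient/breast/time
#'
#' @param records Tidy records from [extract_all()].
#' @return Tibble `patient_id`, `breast`, `time_point`, `parameter`,
#'   `value` (site mean).
#' @export
site_average <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, patient_id, breast, time_point, parameter),
    value = mean(value), .groups = "drop")
}

#' Cohort mean and SD of each parameter over time (Table 3 analogue)
#'
#' Mean and n-1 standard deviation, over patients, of the site-averaged
#' parameter values, for each parameter x breast x time point.
#'
#' @param records Tidy records from [extract_all()].
#' @return Tibble 12 parameters x 2 breasts x 4 time points.
#' @export
summarize_table3 <- function(records) {
  per_patient <- site_average(records)
  if (length(unique(per_patient$patient_id)) < 2L)
    stop("at least 2 patients are required for an SD")
  dplyr::summarise(
    dplyr::group_by(per_patient, parameter, breast, time_point),
    mean = mean(value), sd = stats::sd(value), n = dplyr::n(),
    .groups = "drop")
}

#' Paired irradiated-vs-unirradiated tests per time point (Table 4 analogue)
#'
#' Wilcoxon signed-rank test between the two breasts' site-averaged
#' values, per parameter and time point, flagged at the Bonferroni
#' adjusted level.
#'
#' @param records Tidy records from [extract_all()].
#' @param alpha_adjusted Significance level (default 0.05/3).
#' @return Tibble 12 x 4 with `statistic`, `p`, `significant`.
#' @export
compare_breasts <- function(records, alpha_adjusted = bonferroni_alpha()) {
  per_patient <- site_average(records)
  wide <- tidyr::pivot_wider(per_patient, names_from = breast,
                             values_from = value)
  dplyr::reframe(
    dplyr::group_by(wide, parameter, time_point),
    {
      res <- wilcoxon_signed_rank(irradiated, unirradiated,
                                  alpha_adjusted = alpha_adjusted)
      tibble::tibble(statistic = res$statistic, p = res$p,
                     n_effective = res$n_effective,
                     significant = res$significant)
    })
}

#' Repeated-measures ANOVA per parameter (S1-table analogue)
#'
#' Two-way within-subject ANOVA (group = breast, time = 4 points) on the
#' site-averaged values of each parameter, with conditional
#' Greenhouse-Geisser correction (see [rm_anova()]).
#'
#' @param records Tidy records from [extract_all()].
#' @return Tibble: 12 parameters x 3 effects.
#' @export
rm_anova_report <- function(records) {
  per_patient <- site_average(records)
  dplyr::bind_rows(lapply(split(per_patient, per_patient$parameter),
    function(d) {
      arr <- .records_to_array(d)
      out <- rm_anova(arr)
      out$parameter <- d$parameter[1L]
      out[, c("parameter", setdiff(names(out), "parameter"))]
    }))
}

# subjects x breast(2) x time(4) array for one parameter
.records_to_array <- function(d) {
  subj <- sort(unique(d$patient_id))
  arr <- array(NA_real_, c(length(subj), 2L, 4L),
               dimnames = list(subj, .breast_levels, .time_levels))
  arr[cbind(match(d$patient_id, subj), match(d$breast, .breast_levels),
            match(d$time_point, .time_levels))] <- d$value
  arr
}

#' Dose-response correlations (Table 5 analogue)
#'
#' Spearman correlation, over patients, between the skin dose and each
#' parameter's irradiated-breast value at the post-baseline time points.
#' Cells with p >= `mask_alpha` are masked in the display columns
#' (`rho_shown`), mirroring reports that print only significant
#' correlations; the unmasked `rho`/`p` are always returned.
#'
#' @param records Tidy records from [extract_all()].
#' @param doses A [dose_table()] sharing `patient_id` with the records.
#' @param times Time points to correlate (default the three post-baseline
#'   points).
#' @param mask_alpha Display threshold (default 0.05).
#' @param pairing `"patient"` pairs the patient mean dose with the
#'   site-averaged value; `"site"` pairs each site's dose with that
#'   site's value.
#' @return Tibble 12 parameters x length(times).
#' @export
correlate_dose <- function(records, doses,
                           times = c("RT_7days", "RT_14days", "RT_after"),
                           mask_alpha = 0.05,
                           pairing = c("patient", "site")) {
  pairing <- match.arg(pairing)
  irr <- dplyr::filter(records, breast == "irradiated",
                       time_point %in% times)
  if (!setequal(unique(irr$patient_id), doses$patient_id))
    stop("records and dose table cover different patients")
  if (pairing == "patient") {
    vals <- site_average(irr)
    vals$dose <- doses$mean[match(vals$patient_id, doses$patient_id)]
  } else {
    vals <- irr
    dose_long <- tidyr::pivot_longer(doses[, c("patient_id", .site_levels)],
                                     -patient_id, names_to = "site",
                                     values_to = "dose")
    vals <- dplyr::left_join(vals, dose_long, by = c("patient_id", "site"))
  }
  out <- dplyr::reframe(
    dplyr::group_by(vals, parameter, time_point),
    {
      res <- spearman_corr(dose, value)
      tibble::tibble(rho = res$rho, p = res$p, n = res$n)
    })
  out$significant <- out$p < mask_alpha
  out$rho_shown <- ifelse(out$significant, out$rho, NA_real_)
  out
}

#' Early-vs-final correlations (Table 6 analogue)
#'
#' Spearman correlation, over patients, of each parameter's
#' irradiated-breast value at RT_7days (and RT_14days) with its value at
#' RT_after, quantifying how well early measurements predict the final
#' severity.
#'
#' @param records Tidy records from [extract_all()].
#' @param early Early time points (default RT_7days and RT_14days).
#' @return Tibble 12 parameters x 2 early time points.
#' @export
correlate_early_late <- function(records,
                                 early = c("RT_7days", "RT_14days")) {
  per_patient <- site_average(
    dplyr::filter(records, breast == "irradiated"))
  wide <- tidyr::pivot_wider(per_patient, names_from = time_point,
                             values_from = value)
  dplyr::bind_rows(lapply(early, function(tp) {
    sub <- wide[, c("parameter", tp, "RT_after")]
    names(sub)[2L] <- "early_value"
    dplyr::reframe(
      dplyr::group_by(sub, parameter),
      {
        res <- spearman_corr(early_value, RT_after)
        tibble::tibble(early = tp, rho = res$rho, p = res$p, n = res$n)
      })
  }))
}

#' Correlation of parameters with RTOG grades
#'
#' Spearman correlation of the site-averaged irradiated-breast values with
#' the physician-assessed RTOG grade at the matching time point. On a
#' grade-constant cohort (all patients the same grade) the correlation is
#' undefined and the result is empty with a message.
#'
#' @param records Tidy records from [extract_all()].
#' @param rtog Tibble `patient_id`, `time_point`, `grade`.
#' @return Tibble per parameter x graded time point (possibly 0 rows).
#' @export
correlate_rtog <- function(records, rtog) {
  per_patient <- site_average(
    dplyr::filter(records, breast == "irradiated",
                  time_point %in% unique(rtog$time_point)))
  joined <- dplyr::inner_join(per_patient, rtog,
                              by = c("patient_id", "time_point"))
  ok <- dplyr::group_by(joined, parameter, time_point)
  out <- dplyr::reframe(ok, {
    if (stats::sd(grade) == 0) {
      tibble::tibble(rho = NA_real_, p = NA_real_, n = length(grade))
    } else {
      res <- spearman_corr(grade, value)
      tibble::tibble(rho = res$rho, p = res$p, n = res$n)
    }
  })
  if (all(is.na(out$rho)))
    message("RTOG grades have zero variance; correlations are undefined")
  out
}

#' Run the full study analysis
#'
#' Either simulates a cohort (`simulate = TRUE`) or analyzes an existing
#' image directory laid out as `patient/breast/site/timepoint.png` with a
#' `doses.csv`. Writes `table3.csv`, `table4.csv`, `table5.csv`,
#' `table6.csv`, `anova.csv` and a `report.json` (seed, shapes, masking
#' thresholds) into `outdir`, and returns the tables invisibly.
#'
#' @param input Cohort directory (ignored when `simulate = TRUE`).
#' @param outdir Output directory.
#' @param simulate Generate a synthetic cohort instead of reading images.
#' @param n_patients,seed,params Passed to [generate_cohort()] when
#'   simulating.
#' @param mask_alpha,alpha_adjusted Significance thresholds for the
#'   Table-5 masking and the paired tests.
#' @return List of the five tables plus the extracted records, invisibly.
#' @export
run_study <- function(input = NULL, outdir, simulate = is.null(input),
                      n_patients = 20, seed = 1,
                      params = erythema_params(),
                      mask_alpha = 0.05,
                      alpha_adjusted = bonferroni_alpha()) {
  if (simulate) {
    cohort <- generate_cohort(n_patients, params = params, seed = seed)
    images <- cohort$images
    doses <- cohort$dose_table
  } else {
    cohort <- read_cohort(input)
    images <- cohort$images
    doses <- cohort$dose_table
  }
  records <- extract_all(images)
  tables <- list(
    table3 = summarize_table3(records),
    table4 = compare_breasts(records, alpha_adjusted = alpha_adjusted),
    anova = rm_anova_report(records),
    table5 = correlate_dose(records, doses, mask_alpha = mask_alpha),
    table6 = correlate_early_late(records))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(as.data.frame(tables[[nm]]),
                     file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
  jsonlite::write_json(
    list(seed = if (simulate) seed else NA, simulate = simulate,
         n_patients = length(unique(records$patient_id)),
         n_images = length(images), mask_alpha = mask_alpha,
         alpha_adjusted = alpha_adjusted,
         package_version = as.character(utils::packageVersion("dermachroma")),
         shapes = lapply(tables, dim)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(tables, list(records = records)))
}
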