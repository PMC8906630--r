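# Seeded synthetic erythema cohort.
#
# Emulates the longitudinal study design: per patient, 2 breasts x 4 sites
# x 4 time points of close-up skin images, one OSLD-style dose table, and
# RTOG grade labels. Erythema is modelled additively in CIE a* (redness),
# with coupled fractions on b* and L*, scaled by the site skin dose and a
# monotone fractional time profile; the unirradiated breast gets only a
# small zero-mean drift. Pixel-level texture is i.i.d. Gaussian channel
# noise. All randomness derives from one integer seed expanded into
# per-patient and per-image substreams, so any subset of the cohort is
# reproducible in isolation.

#' Parameters of the synthetic erythema model
#'
#' Defaults are fixed to emulate the study conditions: baseline skin tone
#' centred at Lab (72, -1.2, 20.2) (the Lab of the cohort's mean baseline
#' skin colour), a dose slope such that the mean a* rises from about -1 at
#' baseline to about +6 after a ~235 cGy skin dose course, the fractional
#' time profile of that rise at the four time points, and the observed
#' 186.7--284.0 cGy skin-dose range.
#'
#' @param baseline_L_range,baseline_a_range,baseline_b_range Uniform
#'   sampling intervals for the per-patient baseline L*, a*, b*.
#' @param dose_slope_a Increase of a* per cGy of site skin dose at the
#'   final time point (erythema strength); 0 turns the dose effect off.
#' @param frac_b,frac_L Fractions of the a* shift applied to b* and L*
#'   (`frac_L` is negative: erythematous skin darkens).
#' @param time_profile Fractional effect at (RT_before, RT_7days,
#'   RT_14days, RT_after); must start at 0 and increase strictly.
#' @param control_drift SD (Lab units) of the zero-mean perturbation added
#'   to each unirradiated-breast measurement.
#' @param pixel_noise_sd SD of the Gaussian per-channel pixel noise on the
#'   0--255 scale.
#' @param dose_interval Site skin-dose range in cGy.
#' @param image_size `c(W, H)` in pixels. The default 128 x 128 keeps the
#'   cohort fast to render; the acquisition device's native 1624 x 1212 is
#'   available by setting it here.
#' @param rtog_threshold a* shift above which a patient is labelled RTOG
#'   grade 1 (below: grade 0); the synthetic cohort never exceeds grade 1.
#' @return List of class `erythema_params`.
#' @export
erythema_params <- function(baseline_L_range = c(71.6, 72.4),
                            baseline_a_range = c(-1.6, -0.8),
                            baseline_b_range = c(19.6, 20.8),
                            dose_slope_a = 0.031,
                            frac_b = 0.38,
                            frac_L = -0.11,
                            time_profile = c(0, 0.36, 0.72, 1),
                            control_drift = 0.3,
                            pixel_noise_sd = 6,
                            dose_interval = c(186.7, 284.0),
                            image_size = c(128, 128),
                            rtog_threshold = 2) {
  stopifnot(length(time_profile) == 4L)
  if (time_profile[1L] != 0 || any(diff(time_profile) <= 0))
    stop("`time_profile` must start at 0 and increase strictly")
  if (dose_slope_a < 0) stop("`dose_slope_a` must be >= 0")
  if (pixel_noise_sd < 0) stop("`pixel_noise_sd` must be >= 0")
  if (diff(dose_interval) < 0) stop("`dose_interval` must be non-decreasing")
  structure(list(
    baseline_L_range = baseline_L_range,
    baseline_a_range = baseline_a_range,
    baseline_b_range = baseline_b_range,
    dose_slope_a = dose_slope_a, frac_b = frac_b, frac_L = frac_L,
    time_profile = time_profile, control_drift = control_drift,
    pixel_noise_sd = pixel_noise_sd, dose_interval = dose_interval,
    image_size = image_size, rtog_threshold = rtog_threshold),
    class = "erythema_params")
}

# Deterministic 32-bit substream seed from the master seed and a label.
.substream_seed <- function(seed, label) {
  bytes <- as.integer(charToRaw(label))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-site sampling quantile windows within the dose interval, biasing the
# inner site low and the upper/lower (tangential entrance/exit) sites high.
.site_dose_windows <- list(upper = c(0.35, 1), lower = c(0.35, 1),
                           inner = c(0, 0.55), outer = c(0.1, 0.8))

#' Sample a synthetic per-patient, per-site dose table
#'
#' Each patient draws a shared dose level (measured dose tables show rows
#' that run high or low across all four sites together); each site then
#' jitters that level and maps it into a site-specific quantile window of
#' `dose_interval`, biased so the inner site tends lowest and the upper
#' and lower sites highest, mimicking tangential-field skin dosimetry.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; a fixed seed reproduces the table exactly.
#' @param dose_interval Overall dose range in cGy.
#' @param site_jitter Half-width of the uniform site-level perturbation of
#'   the patient dose quantile.
#' @return A [dose_table()].
#' @export
sample_doses <- function(n_patients, seed = 1,
                         dose_interval = erythema_params()$dose_interval,
                         site_jitter = 0.25) {
  stopifnot(n_patients >= 1)
  lo <- dose_interval[1L]; width <- diff(dose_interval)
  .with_seed(.substream_seed(seed, "doses"), {
    q_patient <- stats::runif(n_patients)
    cols <- lapply(.site_dose_windows, function(w) {
      q <- pmin(1, pmax(0, q_patient + stats::runif(n_patients, -site_jitter,
                                                    site_jitter)))
      lo + width * (w[1L] + (w[2L] - w[1L]) * q)
    })
    dose_table(tibble::tibble(patient_id = as.character(seq_len(n_patients)),
                              upper = cols$upper, lower = cols$lower,
                              inner = cols$inner, outer = cols$outer))
  })
}

#' Render one synthetic skin image
#'
#' Builds a uniform base colour in L*a*b* from the patient baseline; for
#' the irradiated breast adds the dose- and time-dependent erythema shift
#' `dose_slope_a * dose * time_profile[time_point]` to a* (with the
#' configured fractions on b* and L*), for the unirradiated breast adds a
#' small zero-mean drift; converts to RGB through the inverse L*a*b* path,
#' then adds i.i.d. Gaussian pixel noise and clips to \[0, 255\]. Base
#' colours falling outside the sRGB gamut are clipped with a warning.
#'
#' @param baseline_lab Patient baseline `c(L, a, b)`.
#' @param dose Site skin dose in cGy (ignored for the unirradiated breast).
#' @param time_point One of the four longitudinal time points.
#' @param breast `"irradiated"` or `"unirradiated"`.
#' @param params An [erythema_params()] object.
#' @param seed Substream seed for this image's noise and drift.
#' @param patient_id,site Metadata carried on the image.
#' @param quantize Round channels to 8-bit integers (as a real device
#'   would). Off by default so noise-free renders are exactly invertible.
#' @return A [skin_image()].
#' @export
render_skin_image <- function(baseline_lab, dose, time_point,
                              breast = "irradiated",
                              params = erythema_params(), seed = 1,
                              patient_id = NA_character_,
                              site = NA_character_, quantize = FALSE) {
  breast <- match.arg(breast, .breast_levels)
  time_point <- match.arg(time_point, .time_levels)
  ti <- match(time_point, .time_levels)
  .with_seed(seed, {
    lab <- baseline_lab
    if (breast == "irradiated") {
      shift_a <- params$dose_slope_a * dose * params$time_profile[ti]
      lab <- lab + shift_a * c(params$frac_L, 1, params$frac_b)
    } else if (params$control_drift > 0) {
      lab <- lab + stats::rnorm(3, 0, params$control_drift)
    }
    base_rgb <- lab_to_rgb(lab, warn_clip = TRUE) * 255
    w <- params$image_size[1L]; h <- params$image_size[2L]
    px <- array(rep(base_rgb, each = h * w), c(h, w, 3L))
    if (params$pixel_noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, params$pixel_noise_sd)
    px[px < 0] <- 0
    px[px > 255] <- 255
    if (quantize) px <- round(px)
    skin_image(px, patient_id = patient_id, breast = breast, site = site,
               time_point = time_point)
  })
}

#' Generate a full synthetic longitudinal cohort
#'
#' Per patient: a baseline skin tone, four site doses, and 32 images
#' (2 breasts x 4 sites x 4 time points). RTOG grades at RT_14days and
#' RT_after are derived by thresholding the patient's a* shift at that
#' time point and never exceed grade 1, matching a cohort with only mild
#' erythema.
#'
#' @param n_patients Number of patients (default 20).
#' @param params An [erythema_params()] object.
#' @param seed Master integer seed.
#' @return List of class `synthetic_cohort` with elements `images` (list
#'   of [skin_image()]), `dose_table`, `rtog` (tibble), `truth` (tibble of
#'   per-patient generating values), `params`, `seed`.
#' @export
generate_cohort <- function(n_patients = 20, params = erythema_params(),
                            seed = 1) {
  stopifnot(n_patients >= 1)
  doses <- sample_doses(n_patients, seed = seed,
                        dose_interval = params$dose_interval)
  truth <- .with_seed(.substream_seed(seed, "baselines"), {
    tibble::tibble(
      patient_id = as.character(seq_len(n_patients)),
      baseline_L = stats::runif(n_patients, params$baseline_L_range[1L],
                                params$baseline_L_range[2L]),
      baseline_a = stats::runif(n_patients, params$baseline_a_range[1L],
                                params$baseline_a_range[2L]),
      baseline_b = stats::runif(n_patients, params$baseline_b_range[1L],
                                params$baseline_b_range[2L]))
  })
  images <- vector("list", n_patients * 32L)
  idx <- 0L
  for (i in seq_len(n_patients)) {
    pid <- truth$patient_id[i]
    base <- c(truth$baseline_L[i], truth$baseline_a[i], truth$baseline_b[i])
    for (breast in .breast_levels) {
      for (site in .site_levels) {
        dose <- doses[[site]][i]
        for (tp in .time_levels) {
          idx <- idx + 1L
          images[[idx]] <- render_skin_image(
            base, dose, tp, breast = breast, params = params,
            seed = .substream_seed(seed, paste(pid, breast, site, tp, sep = "/")),
            patient_id = pid, site = site)
        }
      }
    }
  }
  shift_after <- params$dose_slope_a * doses$mean
  rtog <- tibble::tibble(
    patient_id = rep(truth$patient_id, 2L),
    time_point = rep(c("RT_14days", "RT_after"), each = n_patients),
    grade = as.integer(c(
      shift_after * params$time_profile[3L] > params$rtog_threshold,
      shift_after > params$rtog_threshold)))
  structure(list(images = images, dose_table = doses, rtog = rtog,
                 truth = truth, params = params, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d images (%d x %d px), seed %d\n",
              nrow(x$dose_table), length(x$images),
              x$params$image_size[1L], x$params$image_size[2L], x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Lays out `patient/breast/site/timepoint.png` image files (8-bit
#' quantized) next to `doses.csv`, `rtog.csv` and `params.json`, the
#' layout the analysis entry points consume.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in cohort$images) {
    sub <- file.path(dir, img$patient_id, img$breast, img$site)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    write_skin_image(img, file.path(sub, paste0(img$time_point, ".png")))
  }
  write_dose_table(cohort$dose_table, file.path(dir, "doses.csv"))
  utils::write.csv(as.data.frame(cohort$rtog), file.path(dir, "rtog.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(cohort$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort image directory
#'
#' Inverse of [write_cohort()]: reads every
#' `patient/breast/site/timepoint.png` under `dir` plus `doses.csv` (and
#' `rtog.csv` if present).
#'
#' @param dir Directory produced by [write_cohort()] or laid out the same
#'   way.
#' @return List with `images` and `dose_table` (and `rtog` when present).
#' @export
read_cohort <- function(dir) {
  paths <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0L) stop("no .png images found under ", dir)
  images <- lapply(paths, read_skin_image, from_path = TRUE)
  out <- list(images = images,
              dose_table = read_dose_table(file.path(dir, "doses.csv")))
  rtog_path <- file.path(dir, "rtog.csv")
  if (file.exists(rtog_path))
    out$rtog <- tibble::as_tibble(
      utils::read.csv(rtog_path, colClasses = c(patient_id = "character")))
  out
}
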