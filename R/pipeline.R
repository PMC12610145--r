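# End-to-end experiment: phantom cohort -> Poisson-Gaussian noise -> filter
# arms -> U-Net per arm -> metrics -> Hough severity classification -> ANOVA
# across arms. Every arm sees byte-identical noisy inputs (paired design) and
# everything is reproducible from one master seed.

#' Configure an end-to-end experiment
#'
#' Defaults describe a desk-scale paired experiment: a 12-patient cohort
#' (severity mix 3/4/5) of 64 px phantom slices, Gaussian noise sd
#' `rho = 0.05` plus a Poisson term calibrated so a vessel ROI lands at
#' about 13 dB SNR, the four-filter bank against a no-filter arm, and a desk
#' U-Net per arm.
#'
#' @param n_patients,severity_mix,slices_per_patient,image_size,pixel_spacing_mm
#'   cohort parameters, see [generate_cohort()].
#' @param rho Gaussian noise sd.
#' @param target_snr_db SNR target used to calibrate the Poisson coefficient
#'   against the vessel plateau intensity (the homogeneous aortic tissue the
#'   SNR ROI sits in); ignored when `gamma` is given.
#' @param gamma optional explicit Poisson coefficient.
#' @param arms subset of `c("noisy", "average", "median", "wiener", "mmwf")`.
#' @param filter_window odd filter window.
#' @param unet a [unet_config()]; its `input_size` must match `image_size`.
#' @param epochs training epochs per arm (defaults to the U-Net config's).
#' @param fractions patient-wise train/validation/test fractions.
#' @param train_mode `"per_arm"` trains one network per filter arm (the
#'   reference design); `"shared"` trains once on the noisy arm and reuses
#'   the weights for every arm (cheap mode for smoke tests).
#' @param include_oracle also classify from the ground-truth masks (skipping
#'   the U-Net) as a perfect-segmentation reference arm?
#' @param classify run the Hough severity-classification stage? Turning it off
#'   predicts only the held-out test slices and skips diameters, for runs that
#'   only need the segmentation metrics.
#' @param threshold binarization threshold.
#' @param seed master seed.
#' @return object of class `"experiment_config"`.
#' @export
experiment_config <- function(n_patients = 12, severity_mix = c(3, 4, 5),
                              slices_per_patient = c(10, 10), image_size = 64,
                              pixel_spacing_mm = 1.75, rho = 0.05,
                              target_snr_db = 13, gamma = NULL,
                              arms = c("noisy", "average", "median", "wiener", "mmwf"),
                              filter_window = 3,
                              unet = unet_config("desk", input_size = image_size),
                              epochs = NULL, fractions = c(0.6, 0.2, 0.2),
                              train_mode = c("per_arm", "shared"),
                              include_oracle = FALSE, classify = TRUE,
                              threshold = 0.5, seed = 1) {
  arms <- match.arg(arms, several.ok = TRUE)
  train_mode <- match.arg(train_mode)
  if (unet$input_size != image_size)
    abort("experiment_config: unet input_size must equal image_size")
  structure(as.list(environment()), class = "experiment_config")
}

filter_arm_images <- function(noisy, arm, window, sigma_n2) {
  if (arm == "noisy") return(noisy)
  spec <- filter_spec(arm, window = window,
    noise_variance = if (arm %in% c("wiener", "mmwf")) sigma_n2 else "estimate"
  )
  lapply(noisy, apply_filter, spec = spec)
}

#' Run a configured experiment
#'
#' Stages: generate the phantom cohort; add one shared Poisson-Gaussian noise
#' realization; build each filter arm from those identical noisy slices;
#' train a U-Net per arm (patient-wise split), predict probability maps,
#' binarize; score per-slice MCC/DSC/JC/MSD on the held-out test slices; run
#' a one-way ANOVA across arms per metric; measure per-patient diameters with
#' the Hough transform on every predicted mask and grade severity for the
#' whole cohort.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress?
#' @return object of class `"aaa_experiment"`: list with `metrics` (per-slice
#'   tibble), `anova` (per-metric tibble), `classification` (per-arm tibble),
#'   `confusion` / `class_metrics` (per-arm lists), `history` (per-arm
#'   training histories), `snr_db`, `noise` (gamma/rho), `cohort`, `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- config

  say("[cohort] generating %d patients", cfg$n_patients)
  cohort <- generate_cohort(
    n_patients = cfg$n_patients, severity_mix = cfg$severity_mix,
    slices_per_patient = cfg$slices_per_patient, master_seed = cfg$seed,
    image_size = cfg$image_size, pixel_spacing_mm = cfg$pixel_spacing_mm
  )
  cohort <- split_by_patient(cohort, cfg$fractions, seed = cfg$seed)
  slices <- lapply(seq_len(nrow(cohort)), function(i) generate_patient_slices(cohort, i))
  names(slices) <- cohort$patient_id
  clean <- unlist(lapply(slices, function(s) lapply(s, `[[`, "image")), recursive = FALSE)
  masks <- unlist(lapply(slices, function(s) lapply(s, `[[`, "mask")), recursive = FALSE)
  meta <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    tibble::tibble(
      patient_id = cohort$patient_id[i], slice_index = seq_len(cohort$n_slices[i]) - 1L,
      subset = cohort$subset[i]
    )
  })

  vessel_level <- cohort$vessel_level[1]
  gamma <- cfg$gamma %||% calibrate_gamma(vessel_level, cfg$rho, cfg$target_snr_db)
  say("[noise] rho = %.3f, gamma = %.4f", cfg$rho, gamma)
  noisy <- lapply(seq_along(clean), function(i) {
    add_poisson_gaussian(clean[[i]], noise_params(gamma, cfg$rho, derive_seed(cfg$seed, 4L, i)))
  })
  # measured SNR in a homogeneous tissue field at the plateau intensity
  snr_db <- {
    flat <- image2d(matrix(vessel_level, 64, 64))
    nf <- add_poisson_gaussian(flat, noise_params(gamma, cfg$rho, derive_seed(cfg$seed, 6L)))
    measure_snr_db(nf, roi_spec(1, 1, 64, 64))
  }

  # one uniform noise-variance estimate shared across all slices and arms
  sigma_n2 <- mean(vapply(
    noisy[seq_len(min(10, length(noisy)))], estimate_noise_variance, 0,
    window = cfg$filter_window
  ))

  arm_results <- list()
  histories <- list()
  shared_model <- NULL
  for (arm in cfg$arms) {
    say("[arm %s] filtering", arm)
    inputs <- filter_arm_images(noisy, arm, cfg$filter_window, sigma_n2)
    tr <- which(meta$subset == "train")
    va <- which(meta$subset == "validation")
    if (cfg$train_mode == "per_arm" || is.null(shared_model)) {
      say("[arm %s] training U-Net (%d train / %d val slices)", arm, length(tr), length(va))
      cfg_arm <- cfg$unet
      cfg_arm$seed <- derive_seed(cfg$seed, 5L, match(arm, cfg$arms))
      model <- build_unet(cfg_arm)
      model <- unet_train(model, inputs[tr], masks[tr], inputs[va], masks[va],
        epochs = cfg$epochs
      )
      if (cfg$train_mode == "shared") shared_model <- model
    } else {
      model <- shared_model
    }
    histories[[arm]] <- model$history
    te <- which(meta$subset == "test")
    scope <- if (cfg$classify) seq_len(nrow(meta)) else te
    preds <- predict(model, inputs[scope])
    bins <- lapply(preds, binarize, threshold = cfg$threshold)
    names(bins) <- as.character(scope)
    mt <- evaluate_masks(bins[as.character(te)], masks[te],
      id = paste0(meta$patient_id[te], "_", meta$slice_index[te]))
    mt$arm <- arm
    cls <- NULL
    if (cfg$classify) {
      by_patient <- split(bins, meta$patient_id[scope])[cohort$patient_id]
      cls <- classify_cohort(cohort, by_patient, threshold = cfg$threshold)
    }
    arm_results[[arm]] <- list(metrics = mt, classification = cls)
  }

  if (cfg$include_oracle) {
    by_patient <- split(masks, meta$patient_id)[cohort$patient_id]
    arm_results[["oracle"]] <- list(
      metrics = NULL,
      classification = classify_cohort(cohort, by_patient)
    )
  }

  metrics <- dplyr::bind_rows(lapply(arm_results, `[[`, "metrics"))
  anova_tbl <- if (length(cfg$arms) >= 2) {
    purrr::map_dfr(c("mcc", "dsc", "jc", "msd"), function(m) {
      d <- metrics[is.finite(metrics[[m]]), ]
      a <- one_way_anova(d, value = m, group = "arm")
      tibble::tibble(
        metric = m, statistic = a$statistic,
        df_between = a$df[1], df_within = a$df[2], p.value = a$p.value
      )
    })
  } else NULL

  classification <- confusion <- cmetrics <- NULL
  if (cfg$classify) {
    classification <- purrr::map_dfr(names(arm_results), function(a) {
      cl <- arm_results[[a]]$classification
      cl$arm <- a
      cl
    })
    confusion <- lapply(arm_results, function(r) {
      severity_confusion(r$classification$pred_class, r$classification$true_class)
    })
    cmetrics <- lapply(confusion, class_metrics)
  }

  structure(list(
    metrics = metrics, anova = anova_tbl, classification = classification,
    confusion = confusion, class_metrics = cmetrics, history = histories,
    snr_db = snr_db, noise = c(gamma = gamma, rho = cfg$rho),
    sigma_n2 = sigma_n2, cohort = cohort, config = cfg
  ), class = "aaa_experiment")
}

#' @export
print.aaa_experiment <- function(x, ...) {
  cat(sprintf(
    "<aaa_experiment: %d patients, arms %s, measured SNR %.1f dB>\n",
    nrow(x$cohort), paste(unique(x$metrics$arm), collapse = "/"), x$snr_db
  ))
  print(glance(x))
  invisible(x)
}

#' @method tidy aaa_experiment
#' @export
tidy.aaa_experiment <- function(x, ...) x$metrics

#' @method glance aaa_experiment
#' @export
glance.aaa_experiment <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_slices = dplyr::n(),
      mcc = mean(.data$mcc), dsc = mean(.data$dsc), jc = mean(.data$jc),
      msd = mean(.data$msd, na.rm = TRUE),
      .groups = "drop"
    )
}
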