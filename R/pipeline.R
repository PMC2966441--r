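# End-to-end study orchestration: simulate -> preprocess -> decode ->
# inference -> behavioral analysis -> report.

# FNV-1a hash of the serialized config, for provenance stamps in filenames
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h a safe double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Study configuration
#'
#' Bundles every parameter of a simulated multi-subject study. Regions of
#' interest are simulated as independent cortical sheets whose coupling
#' between spatial-frequency preference and ocular dominance — and whose
#' monocular gain — decrease from V1 to V3, mirroring the qualitative
#' hierarchy in which eye-of-origin information is strongest in the primary
#' visual cortex.
#'
#' @param n_subjects Number of simulated subjects (default 8).
#' @param rois Named list; each entry is a list with `coupling_rho` and
#'   `eye_selectivity` for that region's sheet and response model.
#' @param design An [experiment_design()].
#' @param model A [response_model()]; per-ROI `eye_selectivity` overrides
#'   its value.
#' @param sampling A [voxel_sampling()].
#' @param behavioral A [behavioral_design()].
#' @param n_voxels_cutoff Voxel-selection cutoff for decoding (100).
#' @param n_permutations Permutations for inference per decoding entry;
#'   0 skips permutation testing.
#' @param family_size Bonferroni family (default: number of ROIs).
#' @param lag_volumes Hemodynamic lag for sample extraction (1).
#' @param seed Master seed.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_subjects = 8,
                         rois = list(
                           V1 = list(coupling_rho = 0.8, eye_selectivity = 0.8),
                           V2 = list(coupling_rho = 0.5, eye_selectivity = 0.5),
                           V3 = list(coupling_rho = 0.1, eye_selectivity = 0.1)),
                         design = experiment_design(),
                         model = response_model(),
                         sampling = voxel_sampling(),
                         behavioral = behavioral_design(),
                         n_voxels_cutoff = 100,
                         n_permutations = 0,
                         family_size = length(rois),
                         lag_volumes = 1,
                         seed = 1) {
  structure(list(n_subjects = as.integer(n_subjects), rois = rois,
                 design = design, model = model, sampling = sampling,
                 behavioral = behavioral,
                 n_voxels_cutoff = as.integer(n_voxels_cutoff),
                 n_permutations = as.integer(n_permutations),
                 family_size = as.integer(family_size),
                 lag_volumes = as.integer(lag_volumes),
                 seed = as.integer(seed)),
            class = "study_config")
}

# In-scanner behavioral responses: one judgement per stimulation block, with
# the same generative signal-detection parameters as outside the scanner.
behavior_for_blocks <- function(eye, sf, bdesign, seed, subject) {
  with_seed(seed, {
    signal <- eye == bdesign$dominant_eye
    dpr <- bdesign$dprime[sf]
    crit <- bdesign$criterion[sf]
    ev <- stats::rnorm(length(eye), mean = ifelse(signal, dpr / 2, -dpr / 2))
    other <- if (bdesign$dominant_eye == "L") "R" else "L"
    resp <- ifelse(ev > crit, bdesign$dominant_eye, other)
    behavioral_session(
      data.frame(trial = seq_along(eye), stimulus_eye = eye, sf = sf,
                 response_eye = resp, stringsAsFactors = FALSE),
      dominant_eye = bdesign$dominant_eye, subject = subject)
  })
}

#' Run a full simulated study
#'
#' For each subject and ROI: generates a cortical sheet, simulates the
#' block-design runs, preprocesses them into pattern samples, and decodes
#' the stimulus eye-of-origin at each spatial frequency with both the
#' multivoxel pattern-correlation classifier and the univariate mean-signal
#' classifier (optionally with permutation inference). Each subject also
#' receives a simulated behavioral session outside the scanner and one
#' judgement per stimulation block inside the scanner, analyzed with
#' [accuracy_by_sf()] and [sdt_analysis()]. Group-level t tests against
#' chance and the correlation between in- and out-of-scanner accuracy are
#' computed with the package's analytic tests.
#'
#' @param config A [study_config()].
#' @param verbose Print per-subject progress.
#' @return An object of class `"study_report"`: `decoding` and `behavior`
#'   data frames, `group_tests` list, config and its hash.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dec_rows <- list()
  beh_rows <- list()
  sfs <- c("low", "high")
  for (s in seq_len(config$n_subjects)) {
    if (verbose) message("subject ", s)
    sseed <- derive_seed(config$seed, s)
    for (ri in seq_along(config$rois)) {
      roi <- names(config$rois)[ri]
      rp <- config$rois[[ri]]
      sheet <- cortical_sheet(coupling_rho = rp$coupling_rho,
                              seed = derive_seed(sseed, 10 + ri))
      model <- config$model
      model$eye_selectivity <- rp$eye_selectivity
      ds <- simulate_experiment(config$design, sheet, model, config$sampling,
                                seed = derive_seed(sseed, 20 + ri))
      samples <- preprocess_dataset(ds, config$lag_volumes)
      for (sf in sfs) {
        problem <- paste(c("L", "R"), sf, sep = "_")
        for (cls in c("pattern_correlation", "univariate_difference")) {
          cfg <- decoding_config(problem, config$n_voxels_cutoff, cls)
          res <- loro_cv(samples, cfg)
          p <- NA_real_; cp <- NA_real_
          if (config$n_permutations > 0) {
            pt <- permutation_test(samples, cfg, config$n_permutations,
                                   seed = derive_seed(sseed, 30 + ri),
                                   family_size = config$family_size)
            p <- pt$p_value; cp <- pt$corrected_p
          }
          dec_rows[[length(dec_rows) + 1L]] <- data.frame(
            subject = s, roi = roi, sf = sf, classifier = cls,
            accuracy = res$accuracy, p_value = p, corrected_p = cp,
            stringsAsFactors = FALSE)
        }
      }
      if (ri == 1L) {
        # behavioral sessions are per subject, not per ROI
        out_sess <- simulate_behavior(config$behavioral,
                                      seed = derive_seed(sseed, 40),
                                      subject = paste0("s", s))
        blocks <- do.call(rbind, lapply(ds$runs, function(r) {
          parse_condition(r$condition_order)
        }))
        in_sess <- behavior_for_blocks(blocks$eye, blocks$sf,
                                       config$behavioral,
                                       seed = derive_seed(sseed, 41),
                                       subject = paste0("s", s))
        acc_out <- accuracy_by_sf(out_sess)
        acc_in <- accuracy_by_sf(in_sess)
        for (sf in sfs) {
          sdt <- sdt_analysis(out_sess, sf)
          beh_rows[[length(beh_rows) + 1L]] <- data.frame(
            subject = s, sf = sf,
            accuracy_out = acc_out[[sf]], accuracy_in = acc_in[[sf]],
            dprime = sdt$dprime, criterion = sdt$criterion,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  decoding <- do.call(rbind, dec_rows)
  behavior <- do.call(rbind, beh_rows)

  group <- list()
  for (roi in names(config$rois)) for (sf in sfs) {
    for (cls in c("pattern_correlation", "univariate_difference")) {
      acc <- decoding$accuracy[decoding$roi == roi & decoding$sf == sf &
                                 decoding$classifier == cls]
      key <- sprintf("decoding_vs_chance.%s.%s.%s", roi, sf, cls)
      group[[key]] <- tryCatch(one_sample_t(acc, 0.5), error = function(e) NULL)
    }
  }
  for (sf in sfs) {
    acc <- behavior$accuracy_out[behavior$sf == sf]
    group[[paste0("behavior_vs_chance.", sf)]] <-
      tryCatch(one_sample_t(acc, 0.5), error = function(e) NULL)
  }
  wide <- function(col) {
    cbind(behavior[behavior$sf == "low", col],
          behavior[behavior$sf == "high", col])
  }
  acc2 <- wide("accuracy_out")
  group$behavior_high_vs_low <- tryCatch(paired_t(acc2[, 2], acc2[, 1]),
                                         error = function(e) NULL)
  dp2 <- wide("dprime")
  group$dprime_low_vs_high <- tryCatch(paired_t(dp2[, 1], dp2[, 2]),
                                       error = function(e) NULL)
  cr2 <- wide("criterion")
  group$criterion_low_vs_high <- tryCatch(paired_t(cr2[, 1], cr2[, 2]),
                                          error = function(e) NULL)
  group$in_out_scanner_correlation <- tryCatch(
    pearson_test(behavior$accuracy_out, behavior$accuracy_in),
    error = function(e) NULL)

  structure(list(decoding = decoding, behavior = behavior,
                 group_tests = group, config = config,
                 hash = config_hash(unclass(config))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report [%s]: %d subjects, %d ROIs\n", x$hash,
              x$config$n_subjects, length(x$config$rois)))
  agg <- stats::aggregate(accuracy ~ roi + sf + classifier, x$decoding, mean)
  cat("\nMean decoding accuracy:\n")
  print(agg, row.names = FALSE)
  cat("\nBehavior (mean over subjects):\n")
  print(stats::aggregate(cbind(accuracy_out, dprime, criterion) ~ sf,
                         x$behavior, mean), row.names = FALSE)
  invisible(x)
}

#' Serialize a study report
#'
#' Writes the full report as JSON and the decoding table as CSV, both
#' stamped with the config hash.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, sprintf("study_report_%s.json", report$hash))
  cpath <- file.path(dir, sprintf("decoding_summary_%s.csv", report$hash))
  tests <- lapply(report$group_tests, function(t) {
    if (is.null(t)) return(NULL)
    list(method = t$method, statistic = t$statistic, df = t$df,
         p_two_tailed = t$p_two_tailed, estimate = as.list(t$estimate))
  })
  jsonlite::write_json(list(
    hash = report$hash, seed = report$config$seed,
    decoding = report$decoding, behavior = report$behavior,
    group_tests = tests
  ), jpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$decoding, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}

#' Write a self-contained fixture bundle to disk
#'
#' Generates a small simulated dataset (NIfTI runs, ROI mask, events tables,
#' a behavioral TSV and a ground-truth JSON) for smoke-testing the pipeline
#' from files. `"tiny"` uses 3 runs on a 36-voxel sheet and completes in
#' seconds; `"default"` reproduces the full 12-run protocol.
#'
#' @param dir Output directory.
#' @param size `"tiny"` or `"default"`.
#' @param seed Master seed.
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(dir, size = c("tiny", "default"), seed = 1) {
  size <- match.arg(size)
  if (size == "tiny") {
    design <- experiment_design(n_runs = 3)
    sheet <- cortical_sheet(size_mm = 9.6, mm_per_px = 0.15,
                            seed = derive_seed(seed, 1))
    bdes <- behavioral_design(n_trials = 48)
  } else {
    design <- experiment_design()
    sheet <- cortical_sheet(seed = derive_seed(seed, 1))
    bdes <- behavioral_design()
  }
  ds <- simulate_experiment(design, sheet, response_model(),
                            voxel_sampling(), seed = derive_seed(seed, 2))
  paths <- write_dataset(ds, dir, prefix = size)
  sess <- simulate_behavior(bdes, seed = derive_seed(seed, 3))
  bpath <- file.path(dir, paste0(size, "_behavior.tsv"))
  write_behavioral_tsv(sess, bpath)
  invisible(c(paths, bpath))
}
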