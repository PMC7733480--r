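#' Configuration of the end-to-end pipeline
#'
#' Bundles the phantom cohort, preprocessing, three network-variant blocks,
#' fusion and evaluation settings under one master seed. The three variant
#' blocks differ only in the dimensions that distinguish them: input
#' channels (Vess: 3) and segment size (LDim: 45 at full fidelity). Every
#' other network setting is shared.
#'
#' @param base_spec A [phantom_spec()] with at least one vessel segment
#'   (its aneurysm list is replaced per generated case).
#' @param n_train,n_test Cohort sizes for the cross-validation training set
#'   and the held-out test set.
#' @param volume_range Aneurysm volume range in mm^3.
#' @param k Cross-validation folds (5 at full fidelity; >= 2 for smoke runs).
#' @param target_mm Isotropic grid spacing after standardization.
#' @param scale_ranges Vesselness scale ranges (voxels) for the Vess variant.
#' @param network Shared [network_config()] settings, as a list of
#'   overrides (e.g. `list(epochs = 2, widths = rep(4, 8))`).
#' @param ldim_segment Segment size of the LDim variant (45 at full
#'   fidelity; may be reduced for smoke runs, but must stay larger than the
#'   shared segment size).
#' @param bins Volume thresholds (mm^3) for the binned evaluation.
#' @param ensemble_method `"staple"` or `"majority"`.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(base_spec, n_train = 10L, n_test = 5L,
                            volume_range = c(20, 500), k = 5L,
                            target_mm = 0.5,
                            scale_ranges = list(c(0.5, 5), c(5, 15)),
                            network = list(), ldim_segment = 45L,
                            bins = c(30, 50, 100),
                            ensemble_method = "staple", seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (n_train < k) stop("n_train must be >= k")
  structure(list(base_spec = base_spec, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), volume_range = volume_range,
                 k = as.integer(k), target_mm = target_mm,
                 scale_ranges = scale_ranges, network = network,
                 ldim_segment = as.integer(ldim_segment), bins = bins,
                 ensemble_method = ensemble_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

variant_network_config <- function(config, variant) {
  args <- config$network
  args$seed <- if (is.null(args$seed)) config$seed else args$seed
  if (variant == "Vess") args$channels_in <- 3L
  if (variant == "LDim") args$segment_size <- config$ldim_segment
  do.call(network_config, args)
}

prep_case <- function(case, variant, config) {
  stack <- build_stack(case$image, variant, target_mm = config$target_mm,
                       scale_ranges = config$scale_ranges)
  labels <- resample_isotropic(case$aneurysm_mask, config$target_mm,
                               mode = "label")
  # the resampled grid of the mask matches the stack grid by construction
  list(stack = stack, labels = labels)
}

#' Run the full synthetic pipeline
#'
#' Generates training and test phantom cohorts, preprocesses each case for
#' the three input variants, trains each variant with k-fold
#' cross-validation, applies every fold sub-model to the test cases and
#' fuses the fold outputs with STAPLE, combines the three variant outputs
#' into the ensemble prediction, and evaluates all four models with
#' volume-binned detection/segmentation metrics.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (NIfTI masks, fold
#'   manifest JSON, metrics CSV/JSON).
#' @param verbose Print stage progress.
#' @return List with `reports` (named list of data.frames per model:
#'   Orig, Vess, LDim, Ens), `detections`, `folds`, `test_truth` and
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  variants <- c("Orig", "Vess", "LDim")

  say("generating %d training and %d test phantoms", config$n_train,
      config$n_test)
  train_cases <- make_cohort(config$n_train, config$base_spec,
                             config$volume_range, seed = config$seed)
  test_cases <- make_cohort(config$n_test, config$base_spec,
                            config$volume_range, seed = config$seed + 1L)

  folds <- make_folds(seq_len(config$n_train), seed = config$seed,
                      k = config$k)

  prepped <- list()
  for (v in variants) {
    say("preprocessing for variant %s", v)
    prepped[[v]] <- list(
      train = lapply(train_cases, prep_case, variant = v, config = config),
      test = lapply(test_cases, prep_case, variant = v, config = config))
  }

  variant_masks <- list()  # variant -> list over test cases
  for (v in variants) {
    ncf <- variant_network_config(config, v)
    fold_preds <- vector("list", config$k)
    for (f in seq_len(config$k)) {
      train_ids <- which(folds$assignments != f)
      say("training %s fold %d/%d on %d cases", v, f, config$k,
          length(train_ids))
      ncf_f <- ncf
      ncf_f$seed <- ncf$seed + f
      model <- train_fold(prepped[[v]]$train[train_ids], ncf_f)
      fold_preds[[f]] <- lapply(prepped[[v]]$test, function(case)
        binarize(predict_volume(model, case$stack), 0.5))
    }
    say("fusing %d fold outputs for %s", config$k, v)
    variant_masks[[v]] <- lapply(seq_len(config$n_test), function(i)
      fuse_folds(lapply(fold_preds, `[[`, i)))
  }

  say("combining variants into the ensemble")
  ens_masks <- lapply(seq_len(config$n_test), function(i)
    ensemble_combine(lapply(variants, function(v) variant_masks[[v]][[i]]),
                     method = config$ensemble_method))

  refs <- lapply(prepped[[1]]$test, `[[`, "labels")
  all_masks <- c(variant_masks, list(Ens = ens_masks))
  detections <- lapply(all_masks, function(masks)
    lapply(seq_len(config$n_test), function(i)
      match_detections(masks[[i]], refs[[i]])))
  reports <- lapply(detections, volume_binned_report, bins = config$bins)

  out <- list(reports = reports, detections = detections, folds = folds,
              test_truth = lapply(test_cases, `[[`, "aneurysm_truth"),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(folds$assignments),
                         file.path(out_dir, "folds.json"), auto_unbox = TRUE)
    for (i in seq_len(config$n_test)) {
      cdir <- file.path(out_dir, sprintf("test_case_%02d", i))
      dir.create(cdir, showWarnings = FALSE)
      for (v in names(all_masks))
        write_volume(all_masks[[v]][[i]],
                     file.path(cdir, sprintf("mask_%s.nii.gz", v)))
      write_volume(refs[[i]], file.path(cdir, "reference.nii.gz"))
    }
    for (v in names(reports))
      utils::write.csv(reports[[v]],
                       file.path(out_dir, sprintf("report_%s.csv", v)),
                       row.names = FALSE)
    jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (v in names(x$reports)) {
    cat(sprintf("-- %s --\n", v))
    print(x$reports[[v]], row.names = FALSE)
  }
  invisible(x)
}
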