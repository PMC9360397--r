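# Pipeline orchestration: simulate -> extract -> calibrate -> validate ->
# report, driven by a single configuration object, with explicit seeding,
# logging and a content-hash manifest.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. All randomness is
#' funnelled through the named seed fields; two runs with the same config
#' produce byte-identical tables.
#'
#' @param n_animals Animals in the simulated design.
#' @param fractions Haemolysed fractions.
#' @param seed Master seed (design, signals, splits and folds derive from
#'   it).
#' @param params A [forward_params()] object (or a named list of overrides
#'   for it, as produced by a YAML config file).
#' @param methods Methods to run, subset of `c("uv", "red", "pls", "ann")`.
#' @param split_fraction Calibration share for the univariate 70/30 split.
#' @param cv_k Folds of the nested cross-validation (multivariate methods).
#' @param n_lf Fixed PLS factor count, or `NULL` to select by inner CV.
#' @param max_epochs Epoch cap of the network.
#' @param n_replicates Replicates per precision level.
#' @param precision_levels Hb levels (g/L) of the precision study.
#' @param render_images How many samples to render as PNG patches (the
#'   image-extraction stage is exercised on these).
#' @param image_size Patch side in pixels.
#' @param pixel_noise_sd Per-pixel noise of rendered patches (also dithers
#'   the 8-bit quantization).
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_animals = 10,
                            fractions = haemolysis_fractions(),
                            seed = 42L,
                            params = forward_params(),
                            methods = c("uv", "red", "pls", "ann"),
                            split_fraction = 0.7,
                            cv_k = 10,
                            n_lf = NULL,
                            max_epochs = 500L,
                            n_replicates = 10,
                            precision_levels = c(0.5, 2.5, 10),
                            render_images = 2,
                            image_size = 32,
                            pixel_noise_sd = 1,
                            out_dir = "haemoquant-out") {
  if (is.list(params) && !inherits(params, "forward_params"))
    params <- do.call(forward_params, params)
  methods <- match.arg(methods, c("uv", "red", "pls", "ann"),
                       several.ok = TRUE)
  structure(list(n_animals = n_animals, fractions = fractions,
                 seed = as.integer(seed), params = params,
                 methods = methods, split_fraction = split_fraction,
                 cv_k = cv_k, n_lf = n_lf,
                 max_epochs = as.integer(max_epochs),
                 n_replicates = n_replicates,
                 precision_levels = precision_levels,
                 render_images = render_images, image_size = image_size,
                 pixel_noise_sd = pixel_noise_sd, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Plain-text key/value configuration; unknown keys are rejected, missing
#' keys take their defaults, and `params:` holds [forward_params()]
#' overrides.
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals$params <- unclass(vals$params)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# Simulated within-run measurement of specimens at a fixed Hb level:
# signals carry replicate (instrument) noise only, as in a precision study
# where one operator re-measures prepared specimens.
simulate_measurements <- function(hb, params) {
  n <- length(hb)
  a540 <- absorbance_forward(hb, params) +
    stats::rnorm(n, 0, params$abs_replicate_sd)
  rgb <- rgb_forward(hb, params, red_noise_sd = params$red_replicate_sd,
                     g_noise_sd = params$g_replicate_sd,
                     b_noise_sd = params$b_replicate_sd)
  data.frame(hb_ref = hb, absorbance540 = pmax(a540, 0),
             r_mean = rgb[, "r"], g_mean = rgb[, "g"], b_mean = rgb[, "b"],
             intensity = weighted_intensity(rgb[, "r"], rgb[, "g"],
                                            rgb[, "b"]))
}

pred_cols <- c("r_mean", "g_mean", "b_mean", "intensity")

#' Run the full analysis pipeline
#'
#' Simulates the study design, writes the sample table, renders and
#' re-extracts a few cuvette patches, calibrates every requested method,
#' validates it (stratified split for the univariate methods, animal-wise
#' nested cross-validation for the multivariate ones), computes the
#' figures of merit from freshly simulated replicate and blank specimens,
#' and writes every artifact plus a manifest of MD5 content hashes and a
#' log recording every seed and file.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (defaults to the config's).
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths), `comparisons` and `merits` (per-method report objects).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  artifacts <- character(0)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    writeLines(line, log_con)
    message(line)
  }
  note_artifact <- function(p) { artifacts <<- c(artifacts, p); p }
  params <- config$params

  logmsg("master seed %d", config$seed)
  design <- generate_design(config$n_animals, config$fractions,
                            seed = config$seed)
  samples <- simulate_samples(design, params, seed = config$seed + 1L)
  tab_path <- note_artifact(file.path(out_dir, "samples.csv"))
  write_sample_table(samples, tab_path)
  logmsg("wrote %s (%d samples, design seed %d, signal seed %d)",
         tab_path, nrow(samples), config$seed, config$seed + 1L)

  if (config$render_images > 0) {
    idx <- seq_len(min(config$render_images, nrow(samples)))
    for (i in idx) {
      p <- note_artifact(file.path(out_dir, sprintf("patch_%02d.png", i)))
      render_patch(c(samples$r_mean[i], samples$g_mean[i],
                     samples$b_mean[i]),
                   size = config$image_size,
                   pixel_noise_sd = config$pixel_noise_sd,
                   seed = config$seed + 100L + i, path = p)
    }
    ext <- extract_images(file.path(out_dir, sprintf("patch_%02d.png", idx)))
    ext_path <- note_artifact(file.path(out_dir, "extracted.csv"))
    utils::write.csv(ext, ext_path, row.names = FALSE)
    logmsg("rendered %d patches; extraction max |dR| = %.3f", length(idx),
           max(abs(ext$r_mean - samples$r_mean[idx])))
  }

  comparisons <- list()
  merits <- list()

  uni_signal <- function(method, df) {
    if (method == "uv") df$absorbance540 else redbance(df$r_mean)
  }
  for (method in intersect(config$methods, c("uv", "red"))) {
    plan <- split_calibration(samples, config$split_fraction,
                              seed = config$seed + 2L)
    cal <- samples[samples$sample_id %in% plan$calibration_ids, ]
    val <- samples[samples$sample_id %in% plan$validation_ids, ]
    fit <- ols_fit(cal$hb_ref, uni_signal(method, cal))
    fit_path <- note_artifact(file.path(out_dir,
                                        sprintf("fit_%s.csv", method)))
    write_linear_fit(fit, fit_path)
    lin <- anova_linearity(fit)
    pred_val <- predict_hb(fit, uni_signal(method, val))
    comparisons[[method]] <- comparison_report(pred_val, val$hb_ref, method)
    logmsg("%s: line (%.4f, %.4f), r %.4f, ANOVA p %.3g; split %d/%d (seed %d)",
           method, fit$intercept, fit$slope, fit$r, lin$p,
           nrow(cal), nrow(val), config$seed + 2L)
    predict_fun <- function(meas) {
      sig <- if (method == "uv") meas$absorbance540 else redbance(meas$r_mean)
      predict_hb(fit, sig)
    }
    merits[[method]] <- merit_from_simulation(method, predict_fun, params,
                                              config, pred_val, val$hb_ref)
  }

  make_X <- function(df) as.matrix(df[, pred_cols])
  for (method in intersect(config$methods, c("pls", "ann"))) {
    if (method == "pls") {
      fit_fn <- function(train) {
        nl <- config$n_lf
        if (is.null(nl))
          nl <- as.integer(select_n_lf(make_X(train), train$hb_ref,
                                       seed = config$seed + 3L))
        pls_fit(make_X(train), train$hb_ref, nl)
      }
      predict_fn <- function(model, test) pls_predict(model, make_X(test))
    } else {
      spec <- ann_spec(max_epochs = config$max_epochs,
                       seed = config$seed + 4L)
      fit_fn <- function(train)
        ann_train(ann_init(spec), make_X(train), train$hb_ref)
      predict_fn <- function(model, test) ann_predict(model, make_X(test))
    }
    cv <- nested_cv(samples, fit_fn, predict_fn, k = config$cv_k,
                    seed = config$seed + 5L)
    comparisons[[method]] <- comparison_report(cv$predictions,
                                               cv$references, method)
    logmsg("%s: nested %d-fold CV, pooled RMSE %.3f g/L", method,
           config$cv_k, sqrt(mean((cv$predictions - cv$references)^2)))
    final_model <- fit_fn(samples)
    if (method == "pls") {
      logmsg("pls: %d latent factor(s), X-var %s%%, Y-var %s%%",
             final_model$n_lf,
             paste(sprintf("%.1f", final_model$explained_x_variance),
                   collapse = "/"),
             paste(sprintf("%.1f", final_model$explained_y_variance),
                   collapse = "/"))
      note_artifact(write_pls_model(final_model,
                                    file.path(out_dir, "model_pls.json")))
    } else {
      note_artifact(write_ann_model(final_model,
                                    file.path(out_dir, "model_ann.json")))
    }
    predict_fun <- function(meas) predict_fn(final_model, meas)
    merits[[method]] <- merit_from_simulation(method, predict_fun, params,
                                              config, cv$predictions,
                                              cv$references)
  }

  for (method in names(comparisons)) {
    p <- note_artifact(file.path(out_dir,
                                 sprintf("comparison_%s.csv", method)))
    write_comparison_report(comparisons[[method]], p)
  }
  if (length(merits)) {
    merit_path <- note_artifact(file.path(out_dir, "merit.csv"))
    utils::write.csv(merit_table(merits), merit_path, row.names = FALSE)
    logmsg("wrote %s", merit_path)
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  logmsg("manifest: %d artifacts", nrow(manifest))
  invisible(list(status = 0L, artifacts = c(artifacts, manifest_path),
                 comparisons = comparisons, merits = merits))
}

# Figures of merit from freshly simulated specimens: n replicates at each
# precision level and ten blanks, measured with within-run noise only.
merit_from_simulation <- function(method, predict_fun, params, config,
                                  validation_predicted,
                                  validation_reference) {
  set.seed(config$seed + 6L)
  reps <- lapply(config$precision_levels, function(level) {
    meas <- simulate_measurements(rep(level, config$n_replicates), params)
    predict_fun(meas)
  })
  names(reps) <- as.character(config$precision_levels)
  blank_hb <- pmax(0, stats::rnorm(10, 0, params$baseline_free_hb_sd))
  blanks <- predict_fun(simulate_measurements(blank_hb, params))
  merit_report(method, replicate_predictions = reps,
               blank_predictions = blanks,
               validation_predicted = validation_predicted,
               validation_reference = validation_reference,
               linearity_high = max(config$precision_levels))
}

#' Serialize / deserialize a PLS model as JSON
#'
#' @param model A [pls_fit()] result.
#' @param path JSON file path.
#' @return `write_pls_model` returns `path` invisibly; `read_pls_model`
#'   the restored model.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- unclass(model)
  obj$x_weights <- list(dim = dim(model$x_weights),
                        values = as.vector(model$x_weights))
  obj$x_loadings <- list(dim = dim(model$x_loadings),
                         values = as.vector(model$x_loadings))
  obj$scores <- list(dim = dim(model$scores),
                     values = as.vector(model$scores))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  un <- function(x) unlist(x)
  mat <- function(m) matrix(un(m$values), un(m$dim)[1], un(m$dim)[2])
  structure(list(
    n_lf = un(o$n_lf), n_lf_requested = un(o$n_lf_requested),
    x_weights = mat(o$x_weights), x_loadings = mat(o$x_loadings),
    y_loadings = un(o$y_loadings), scores = mat(o$scores),
    x_mean = un(o$x_mean), x_sd = un(o$x_sd),
    y_mean = un(o$y_mean), y_sd = un(o$y_sd),
    coefficients = un(o$coefficients), intercept = un(o$intercept),
    explained_x_variance = un(o$explained_x_variance),
    explained_y_variance = un(o$explained_y_variance),
    n_predictors = un(o$n_predictors)
  ), class = "pls_model")
}
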