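#' Run configuration
#'
#' A fully serializable description of an experiment run; a run can be
#' reproduced from its stored configuration alone.
#'
#' @param experiment `"dictionary"` or `"ct"`.
#' @param preset `"desk"` (reduced, minutes on one CPU) or `"full"`
#'   (full-scale problem dimensions).
#' @param seed integer master seed for data generation and training.
#' @param train_model train the model before evaluation (`dictionary` trains
#'   the sparsifying transform; `ct` optionally trains the learned prox).
#' @param policy a [label_policy()].
#' @param n_test number of evaluation instances (`NULL` for the preset
#'   default).
#' @param out_dir optional directory for the JSON report, per-inference
#'   certificates and solver traces.
#' @param ... overrides stored verbatim in the config (solver / training
#'   settings understood by [run_experiment()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(experiment = c("dictionary", "ct"), preset = "desk",
                       seed = 1L, train_model = TRUE, policy = label_policy(),
                       n_test = NULL, out_dir = NULL, ...) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, preset = preset, seed = seed,
                 train_model = train_model, policy = policy, n_test = n_test,
                 out_dir = out_dir, extra = list(...)),
            class = "run_config")
}

#' Read / write run configurations (JSON or YAML)
#'
#' @param path file ending in `.json`, `.yml` or `.yaml`.
#' @return a [run_config()] (`read_run_config`) or `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pol <- do.call(label_policy, as.list(raw$policy))
  cfg <- run_config(experiment = raw$experiment, preset = raw$preset,
                    seed = raw$seed, train_model = isTRUE(raw$train_model),
                    policy = pol, n_test = raw$n_test, out_dir = raw$out_dir)
  cfg$extra <- if (is.null(raw$extra)) list() else as.list(raw$extra)
  cfg
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  payload <- unclass(config)
  payload$policy <- unclass(payload$policy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# fail rate = mean of per-inference fail indicators for one property
.fail_rates <- function(cert_list) {
  props <- cert_list[[1]]$name
  sapply(props, function(p) {
    mean(vapply(cert_list, function(ct) ct$label[ct$name == p] == "fail", logical(1)))
  })
}

#' IDM certificate properties
#'
#' Sparsity of the code `K x` (both the l1 norm used for labelling in the
#' dictionary experiment and a tolerance-l0 count) and relative measurement
#' error.  Records need fields `code`, `x`, `A`, `d`.
#'
#' @param zero_tol tolerance of the l0 count.
#' @return list of [property_spec()]s.
#' @export
idm_properties <- function(zero_tol = 1e-3) {
  list(
    property_spec("sparsity_l1", function(r) sum(abs(r$code)),
                  "l1 norm of the sparsified inference Kx"),
    property_spec("sparsity_l0", function(r) property_sparsity(r$code, zero_tol),
                  "tolerance-l0 of the sparsified inference"),
    property_spec("fidelity", function(r) property_rel_error(r$A, r$x, r$d),
                  "relative measurement error |Ax-d|/|d|"))
}

#' CT certificate properties
#'
#' Box-constraint distance, relative measurement error, and the data-driven
#' regularization residual `||x - prox(x)||`.  Records need fields `x`, `A`,
#' `d`, and a `prox`.
#'
#' @return list of [property_spec()]s.
#' @export
ct_properties <- function() {
  list(
    property_spec("box_constraint", function(r) property_box_distance(r$x, 0, 1),
                  "Euclidean distance to [0,1]^n"),
    property_spec("fidelity", function(r) property_rel_error(r$A, r$x, r$d),
                  "relative measurement error |Ax-d|/|d|"),
    property_spec("data_regularization", function(r) learned_prox_residual(r$x, r$prox),
                  "proximal residual of the learned regularizer"))
}

.dictionary_run <- function(config) {
  ex <- config$extra
  dims <- if (identical(config$preset, "full"))
    list(n = 250L, r = 50L, m = 100L, k = 5L, n_train = 2000L, n_test = 200L)
  else
    list(n = 60L, r = 12L, m = 24L, k = 3L, n_train = 500L, n_test = 100L)
  n_test <- if (is.null(config$n_test)) dims$n_test else config$n_test
  train_ds <- generate_dictionary_dataset(dims$n, dims$r, dims$m, dims$k,
                                          dims$n_train, seed = config$seed)
  test_ds <- generate_dictionary_dataset(dims$n, dims$r, dims$m, dims$k,
                                         n_test, seed = config$seed + 1L)
  # the hidden transform and measurement matrix define the population:
  # share them between splits
  test_ds$M <- train_ds$M; test_ds$A <- train_ds$A
  test_ds$X <- test_ds$M %*% test_ds$S
  test_ds$D <- test_ds$A %*% test_ds$X

  model <- implicit_model("idm", idm_init_weights(dims$n, seed = config$seed),
                          train_ds$A)
  history <- NULL
  if (isTRUE(config$train_model)) {
    cfg <- train_config(
      epochs = if (is.null(ex$epochs)) 120L else ex$epochs,
      batch_size = 50L,
      lr = if (is.null(ex$lr)) 3e-3 else ex$lr,
      fp_tol = 1e-6,
      fp_max_iter = if (is.null(ex$fp_max_iter)) 300L else ex$fp_max_iter,
      seed = config$seed)
    tr <- train(model, train_ds, cfg)
    model <- tr$model; history <- tr$history
  }
  records_of <- function(D) {
    many <- idm_infer_many(model$weights, model$A, D)
    lapply(seq_len(ncol(D)), function(i)
      list(x = many$X[, i], code = many$C[, i], A = model$A, d = D[, i]))
  }
  # calibration on model inferences over (a subsample of) the training data
  n_cal <- min(if (is.null(ex$n_cal)) 120L else ex$n_cal, train_ds$count)
  cal_idx <- with_seed(config$seed + 2L, sample.int(train_ds$count, n_cal))
  cal_records <- records_of(train_ds$D[, cal_idx, drop = FALSE])
  props <- idm_properties()
  tables <- lapply(props, calibrate, records = cal_records,
                   source = "training-inferences")
  names(tables) <- vapply(props, `[[`, "", "name")

  test_records <- records_of(test_ds$D[, seq_len(n_test), drop = FALSE])
  certs <- lapply(test_records, certify, properties = props, tables = tables,
                  policy = config$policy)
  rel_err <- vapply(seq_len(n_test), function(i) {
    l2norm(test_records[[i]]$x - test_ds$X[, i]) / max(1e-12, l2norm(test_ds$X[, i]))
  }, numeric(1))
  code_l0 <- vapply(test_records, function(r) property_sparsity(r$code, 1e-3),
                    numeric(1))
  list(experiment = "dictionary", preset = config$preset, seed = config$seed,
       trained = isTRUE(config$train_model),
       metrics = list(mean_rel_error = mean(rel_err),
                      frac_rel_error_below_0.1 = mean(rel_err < 0.1),
                      mean_code_l0 = mean(code_l0)),
       fail_rates = as.list(.fail_rates(certs)),
       history = history, certificates = certs, rel_err = rel_err,
       model = model, test = test_ds)
}

.ct_run <- function(config) {
  ex <- config$extra
  geom <- ct_preset_geometry(config$preset)
  n_test <- if (is.null(config$n_test)) 50L else config$n_test
  n_cal <- if (is.null(ex$n_cal)) 100L else ex$n_cal
  radon <- build_radon_map(geom)
  cal_ds <- generate_ct_dataset(geom, n_cal, seed = config$seed, radon = radon)
  test_ds <- generate_ct_dataset(geom, n_test, seed = config$seed + 1L, radon = radon)

  prox <- learned_prox(geom$image_side^2, image_side = geom$image_side,
                       seed = config$seed)
  weights <- ct_weights(prox)
  model <- implicit_model("ct", weights, radon,
                          tol = if (is.null(ex$tol)) 1e-7 else ex$tol,
                          max_iter = if (is.null(ex$max_iter)) 1500L else ex$max_iter)
  history <- NULL
  if (isTRUE(config$train_model)) {
    cfg <- train_config(epochs = if (is.null(ex$epochs)) 2L else ex$epochs,
                        lr = if (is.null(ex$lr)) 1e-3 else ex$lr,
                        fp_tol = 1e-5, fp_max_iter = 300L, seed = config$seed)
    n_tr <- min(if (is.null(ex$n_train)) 10L else ex$n_train, cal_ds$count)
    sub <- cal_ds
    sub$phantoms <- cal_ds$phantoms[seq_len(n_tr)]
    sub$sino_noisy <- cal_ds$sino_noisy[, seq_len(n_tr), drop = FALSE]
    sub$sino_clean <- cal_ds$sino_clean[, seq_len(n_tr), drop = FALSE]
    sub$count <- n_tr
    tr <- train(model, sub, cfg)
    model <- tr$model; history <- tr$history
  }
  # ground-truth calibration: phantoms are known on the training side, and the
  # constraint certificates then encode "at least as consistent as the truth"
  gt_records <- lapply(seq_len(cal_ds$count), function(i) {
    list(x = as.vector(t(cal_ds$phantoms[[i]])), A = radon,
         d = cal_ds$sino_noisy[, i], prox = model$weights$prox)
  })
  props <- ct_properties()
  tables <- lapply(props, calibrate, records = gt_records, source = "ground-truths")
  names(tables) <- vapply(props, `[[`, "", "name")

  side <- geom$image_side
  test_records <- vector("list", n_test)
  psnr_model <- numeric(n_test); ssim_model <- numeric(n_test)
  psnr_bp <- numeric(n_test)
  for (i in seq_len(n_test)) {
    d <- test_ds$sino_noisy[, i]
    res <- infer(model, d)
    test_records[[i]] <- list(x = res$x, A = radon, d = d,
                              prox = model$weights$prox, state = res$state)
    est <- matrix(res$x, side, side, byrow = TRUE)
    ph <- test_ds$phantoms[[i]]
    psnr_model[i] <- psnr(ph, est)
    ssim_model[i] <- ssim(ph, est)
    bp <- map_adjoint(radon, d)
    bp <- bp / max(bp, 1e-12)
    psnr_bp[i] <- psnr(ph, matrix(project_box(bp, 0, 1), side, side, byrow = TRUE))
  }
  certs <- lapply(test_records, certify, properties = props, tables = tables,
                  policy = config$policy)
  list(experiment = "ct", preset = config$preset, seed = config$seed,
       trained = isTRUE(config$train_model),
       metrics = list(mean_psnr = mean(psnr_model), mean_ssim = mean(ssim_model),
                      mean_psnr_backprojection = mean(psnr_bp)),
       fail_rates = as.list(.fail_rates(certs)),
       history = history, certificates = certs, model = model, test = test_ds)
}

#' Run a full experiment: generate, (optionally) train, infer, certify,
#' evaluate
#'
#' Executes the pipeline for the configured experiment and returns a report:
#' evaluation metrics, certificate fail rates per property (the mean of
#' per-inference fail indicators), the training history, and all per-inference
#' certificates.  When `config$out_dir` is set, a JSON report embedding the
#' configuration and seeds — everything needed to regenerate the run — is
#' written alongside per-inference certificate files.
#'
#' @param config a [run_config()].
#' @return the report, invisibly of class `l2o_report`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- switch(config$experiment,
                   dictionary = .dictionary_run(config),
                   ct = .ct_run(config))
  report$config <- config
  class(report) <- "l2o_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(experiment = report$experiment, preset = report$preset,
                    seed = report$seed, trained = report$trained,
                    metrics = report$metrics, fail_rates = report$fail_rates,
                    config = unclass(config)[c("experiment", "preset", "seed",
                                               "train_model", "n_test")],
                    policy = unclass(config$policy))
    jsonlite::write_json(payload, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (i in seq_along(report$certificates))
      write_certificates(report$certificates[[i]], config$policy,
                         file.path(config$out_dir, sprintf("certificates_%03d.json", i)))
  }
  invisible(report)
}

#' @export
print.l2o_report <- function(x, ...) {
  cat(sprintf("<l2o_report: %s experiment, preset %s, seed %d, %s>\n",
              x$experiment, x$preset, x$seed,
              if (x$trained) "trained" else "untrained"))
  for (nm in names(x$metrics)) cat(sprintf("  %-28s %.4f\n", nm, x$metrics[[nm]]))
  cat("  certificate fail rates:\n")
  for (nm in names(x$fail_rates))
    cat(sprintf("    %-26s %.2f%%\n", nm, 100 * x$fail_rates[[nm]]))
  invisible(x)
}
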