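#' Split a data set into model-building and external validation parts
#'
#' Random disjoint split; the build part gets `round(n * fraction)` molecules
#' and the external part the rest. Reproducible given `seed`.
#'
#' @param molecules a [molecule_set()].
#' @param fraction proportion used for model building (default 0.75; the
#'   remaining 25% is touched only for external validation).
#' @param seed integer RNG seed.
#' @return A list with `build` and `external` molecule sets and the index
#'   vectors `build_idx` and `external_idx`.
#' @export
split_external <- function(molecules, fraction = 0.75, seed = 1) {
  n <- length(molecules)
  if (n < 4) stop("need at least 4 molecules to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  build_idx <- sort(sample.int(n, round(n * fraction)))
  external_idx <- setdiff(seq_len(n), build_idx)
  list(build = molecules[build_idx], external = molecules[external_idx],
       build_idx = build_idx, external_idx = external_idx, seed = seed)
}

#' Generate repeated k-fold cross-validation indices
#'
#' Within each repeat the test folds partition the build set, so every sample
#' appears in exactly `repeats` test folds. By default folds are stratified
#' by activity quartile (via `caret::createMultiFolds`, the convention of the
#' original workflow); set `stratify = FALSE` for plain random partitions.
#'
#' @param y numeric activity vector of the build set.
#' @param k number of folds.
#' @param repeats number of repeats.
#' @param seed integer RNG seed.
#' @param stratify stratify folds by activity quartile.
#' @return A list of `k * repeats` elements, each with `train` and `test`
#'   index vectors.
#' @export
repeated_kfold <- function(y, k = 10, repeats = 10, seed = 1, stratify = TRUE) {
  n <- length(y)
  if (k > n) stop("k cannot exceed the number of samples")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (stratify && requireNamespace("caret", quietly = TRUE)) {
    tr <- caret::createMultiFolds(y, k = k, times = repeats)
    folds <- lapply(tr, function(idx)
      list(train = sort(idx), test = sort(setdiff(seq_len(n), idx))))
    names(folds) <- names(tr)
  } else {
    folds <- list()
    for (r in seq_len(repeats)) {
      lab <- sample(rep(seq_len(k), length.out = n))
      for (f in seq_len(k)) {
        folds[[sprintf("Fold%02d.Rep%02d", f, r)]] <-
          list(train = which(lab != f), test = which(lab == f))
      }
    }
  }
  attr(folds, "seed") <- seed
  folds
}

#' Mean absolute error and its spread
#'
#' Returns the mean of the absolute errors and the sample standard deviation
#' of the absolute errors (the "MAE +/- SD" reporting convention).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return A list with `mae` and `sd` (`sd` is `NA` for a single error).
#' @export
mae_sd <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  ae <- abs(y_true - y_pred)
  list(mae = mean(ae), sd = if (length(ae) > 1) stats::sd(ae) else NA_real_)
}

#' Run the full external validation scheme
#'
#' Reproduces the standard QSAR validation protocol: a random 75/25 split
#' into model-building and external sets; the optimal threshold `t*`
#' determined once on the build set only; `k x repeats` cross-validation
#' folds on the build set, each yielding one modSAR model trained at that
#' `t*`; selection of the model with the smallest internal test MAE; and
#' evaluation of the selected model on the untouched external set, with MAE
#' and SD reported separately for molecules inside and outside the
#' applicability domain.
#'
#' @param molecules a curated [molecule_set()] with fingerprints and
#'   descriptors.
#' @param fraction build-set proportion.
#' @param k,repeats cross-validation layout (defaults give 100 models).
#' @param seed integer RNG seed driving the split and the folds.
#' @param lambda L1 regularisation weight.
#' @param grid threshold scan grid.
#' @param control an [oplra_control()].
#' @param stratify stratify folds by activity quartile.
#' @param verbose print fold progress.
#' @return An object of class `modsar_validation`: `folds` (per-fold train
#'   and test MAE), `selected` (index of the minimum-test-MAE fold),
#'   `model` (the selected model), `t_star`, `external` (per-molecule
#'   predictions), `external_mae` (overall / in-AD / out-of-AD `mae_sd`),
#'   and the seeds and indices needed to replay the run.
#' @export
run_validation <- function(molecules, fraction = 0.75, k = 10, repeats = 10,
                           seed = 1, lambda = 0.005,
                           grid = seq(0, 0.99, by = 0.01),
                           control = oplra_control(), stratify = TRUE,
                           verbose = FALSE) {
  sp <- split_external(molecules, fraction = fraction, seed = seed)
  build <- sp$build
  scan <- threshold_scan(build, grid = grid)
  t_star <- scan$t_star
  folds <- repeated_kfold(build$activity, k = k, repeats = repeats,
                          seed = seed, stratify = stratify)
  res <- data.frame(fold = names(folds), train_mae = NA_real_,
                    test_mae = NA_real_, stringsAsFactors = FALSE)
  models <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    tr <- folds[[i]]$train; te <- folds[[i]]$test
    m <- modsar(build[tr], lambda = lambda, t_alpha = t_star,
                seed = seed, control = control)
    p <- predict(m, build[te])
    res$train_mae[i] <- mean(abs(m$residuals))
    res$test_mae[i] <- mae_sd(build$activity[te], p$pred_pic50)$mae
    models[[i]] <- m
    if (verbose) message(sprintf("fold %s: test MAE %.4f", names(folds)[i],
                                 res$test_mae[i]))
  }
  selected <- which.min(res$test_mae)
  model <- models[[selected]]
  ext_pred <- predict(model, sp$external)
  ext_true <- sp$external$activity
  in_ad <- ext_pred$in_ad
  external_mae <- list(
    overall = mae_sd(ext_true, ext_pred$pred_pic50),
    in_ad = if (any(in_ad)) mae_sd(ext_true[in_ad], ext_pred$pred_pic50[in_ad]) else NULL,
    out_ad = if (any(!in_ad)) mae_sd(ext_true[!in_ad], ext_pred$pred_pic50[!in_ad]) else NULL)
  structure(list(folds = res, selected = selected, model = model,
                 t_star = t_star, scan = scan,
                 external = cbind(ext_pred, obs_pic50 = unname(ext_true)),
                 external_mae = external_mae,
                 seed = seed, build_idx = sp$build_idx,
                 external_idx = sp$external_idx, k = k, repeats = repeats,
                 stratify = stratify),
            class = "modsar_validation")
}

#' @export
print.modsar_validation <- function(x, ...) {
  cat("modSAR validation:", nrow(x$folds), "folds, t* =", x$t_star, "\n")
  cat("  selected fold:", x$folds$fold[x$selected],
      " internal test MAE =", round(x$folds$test_mae[x$selected], 4), "\n")
  fmt <- function(m) if (is.null(m)) "-" else
    sprintf("%.3f +/- %.3f", m$mae, m$sd)
  cat("  external MAE:", fmt(x$external_mae$overall), "\n")
  cat("    within AD: ", fmt(x$external_mae$in_ad),
      " (n =", sum(x$external$in_ad), ")\n")
  cat("    outside AD:", fmt(x$external_mae$out_ad),
      " (n =", sum(!x$external$in_ad), ")\n")
  invisible(x)
}

#' Export a validation report as CSV
#'
#' Writes the per-fold table and a summary with the within/outside-AD
#' external errors.
#'
#' @param report a `modsar_validation`.
#' @param file output path for the per-fold table.
#' @param summary_file optional output path for the summary.
#' @return `file`, invisibly.
#' @export
export_validation <- function(report, file, summary_file = NULL) {
  utils::write.csv(report$folds, file, row.names = FALSE)
  if (!is.null(summary_file)) {
    g <- function(m) if (is.null(m)) c(NA, NA) else c(m$mae, m$sd)
    utils::write.csv(data.frame(
      stratum = c("overall", "in_ad", "out_ad"),
      mae = c(g(report$external_mae$overall)[1], g(report$external_mae$in_ad)[1],
              g(report$external_mae$out_ad)[1]),
      sd = c(g(report$external_mae$overall)[2], g(report$external_mae$in_ad)[2],
             g(report$external_mae$out_ad)[2])), summary_file, row.names = FALSE)
  }
  invisible(file)
}
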