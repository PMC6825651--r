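#' Fit a two-level modular network QSAR model
#'
#' Runs the full training pipeline: descriptor preprocessing (near-zero
#' variance and correlation filters, min-max scaling), fingerprint-based
#' Tanimoto similarity, threshold scan with ACC-peak selection of the optimal
#' threshold `t*` (unless a threshold is supplied), network construction at
#' `t*`, Louvain module detection, and one optimal piecewise linear
#' regression (OPLRAreg) per module. Singleton modules are modelled by the
#' constant equal to their activity.
#'
#' @param molecules a [molecule_set()] with activities, fingerprints (or
#'   SMILES from which to compute them) and descriptors.
#' @param lambda L1 regularisation weight for the per-region equations.
#' @param grid threshold grid for the scan (default 0 to 0.99 by 0.01).
#' @param t_alpha optional fixed similarity threshold; skips the scan.
#' @param seed RNG seed controlling Louvain's node visiting order.
#' @param corr_cutoff descriptor correlation filter cutoff.
#' @param control an [oplra_control()].
#' @param fingerprint_cfg list with `radius` and `n_bits`, used when
#'   fingerprints must be computed from SMILES and recorded for prediction.
#' @return An object of class `modsar` with components `t_star`, `scan`,
#'   `graph`, `partition`, `submodels`, `prep`, `fingerprints`, `activity`,
#'   `fitted`, `residuals`.
#' @seealso [predict.modsar()], [run_validation()], [cliff_profile()]
#' @export
modsar <- function(molecules, lambda = 0.005, grid = seq(0, 0.99, by = 0.01),
                   t_alpha = NULL, seed = 20191018, corr_cutoff = 0.90,
                   control = oplra_control(),
                   fingerprint_cfg = list(radius = 2, n_bits = 1024)) {
  stopifnot(inherits(molecules, "molecule_set"))
  if (length(molecules) < 2) stop("need at least 2 curated molecules")
  fps <- molecules$fingerprints
  if (is.null(fps)) {
    if (is.null(molecules$smiles))
      stop("molecules need fingerprints or SMILES")
    fps <- compute_fingerprints(molecules$smiles, fingerprint_cfg$radius,
                                fingerprint_cfg$n_bits, ids = molecules$ids)
  } else {
    fingerprint_cfg$n_bits <- ncol(fps)
  }
  if (is.null(molecules$descriptors))
    stop("molecules need a descriptor matrix")
  prep <- preprocess_descriptors(molecules$descriptors, corr_cutoff = corr_cutoff)
  X <- prep$values
  y <- molecules$activity

  sim <- tanimoto_matrix(fps)
  scan <- NULL
  if (is.null(t_alpha)) {
    scan <- threshold_scan(NULL, grid = grid, sim = sim)
    t_star <- scan$t_star
  } else t_star <- t_alpha

  graph <- build_graph(NULL, t_star, sim = sim)
  partition <- detect_modules(graph, seed = seed)

  submodels <- list()
  for (mod in sort(unique(partition$membership))) {
    idx <- which(partition$membership == mod)
    submodels[[as.character(mod)]] <-
      if (length(idx) == 1) constant_model(unname(y[idx]))
      else fit_oplra(X[idx, , drop = FALSE], unname(y[idx]),
                     lambda = lambda, control = control)
  }

  fitted <- vapply(seq_along(molecules$ids), function(k) {
    sub <- submodels[[as.character(partition$membership[k])]]
    if (isTRUE(sub$constant)) sub$regions[[1]]$intercept
    else predict_piecewise(sub, X[k, , drop = FALSE])
  }, numeric(1))
  names(fitted) <- molecules$ids

  structure(list(call = match.call(), t_star = t_star, scan = scan,
                 graph = graph, partition = partition, submodels = submodels,
                 prep = prep, fingerprint_cfg = fingerprint_cfg,
                 lambda = lambda, control = control, seed = seed,
                 ids = molecules$ids, activity = y, fingerprints = fps,
                 fitted = fitted, residuals = y - fitted),
            class = "modsar")
}

#' Assign a new molecule to a network module
#'
#' Computes the Tanimoto similarity of the query fingerprint to every
#' training molecule and applies the three assignment cases: (i)
#' `many_neighbours` - one module holds the strict maximum number of
#' above-threshold neighbours; (ii) `multi_module_avg` - the neighbour count
#' is tied across modules and the tie is broken by the largest average
#' similarity over each tied module's above-threshold neighbours (then by
#' the smaller module id); (iii) `nearest_only` - no training similarity
#' reaches the threshold and the module of the single most similar training
#' molecule is used, which places the query outside the applicability
#' domain.
#'
#' @param model a fitted [modsar()] model.
#' @param fp binary fingerprint of the query molecule (same length as the
#'   training fingerprints).
#' @return A list with `module`, `case` and the similarity vector `sims`.
#' @export
assign_module <- function(model, fp) {
  fps <- model$fingerprints
  if (is.null(fps) || nrow(fps) == 0) stop("model has no training fingerprints")
  if (length(fp) != ncol(fps)) stop("fingerprint length mismatch")
  fp <- as.numeric(fp)
  inter <- as.vector(fps %*% fp)
  union <- rowSums(fps) + sum(fp) - inter
  sims <- ifelse(union > 0, inter / union, 0)
  memb <- model$partition$membership
  neigh <- which(sims >= model$t_star)
  if (length(neigh) > 0) {
    counts <- table(memb[neigh])
    tied <- as.integer(names(counts)[counts == max(counts)])
    if (length(tied) == 1)
      return(list(module = tied, case = "many_neighbours", sims = sims))
    avg <- vapply(tied, function(m)
      mean(sims[neigh[memb[neigh] == m]]), numeric(1))
    best <- tied[avg == max(avg)]
    return(list(module = min(best), case = "multi_module_avg", sims = sims))
  }
  nearest <- which.max(sims)
  list(module = unname(memb[nearest]), case = "nearest_only", sims = sims)
}

#' Predict activities of new molecules
#'
#' Each molecule is assigned to a module with [assign_module()]; singleton
#' modules return their stored activity, other modules evaluate their
#' piecewise linear equation on the molecule's descriptors (scaled with the
#' training parameters and clipped to [0, 1]). Molecules with no training
#' neighbour above `t*` are flagged as outside the applicability domain
#' (`in_ad = FALSE`).
#'
#' @param object a fitted [modsar()] model.
#' @param newdata a [molecule_set()] (activities may be `NA`-free dummies at
#'   prediction time) with fingerprints or SMILES, and descriptors when any
#'   target module is non-singleton.
#' @param ... unused.
#' @return A data frame with columns `id`, `pred_pic50`, `module`, `case`,
#'   `in_ad`.
#' @export
predict.modsar <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "molecule_set"))
  fps <- newdata$fingerprints
  if (is.null(fps)) {
    if (is.null(newdata$smiles)) stop("newdata needs fingerprints or SMILES")
    fps <- compute_fingerprints(newdata$smiles, object$fingerprint_cfg$radius,
                                object$fingerprint_cfg$n_bits,
                                ids = newdata$ids)
  }
  Xs <- if (!is.null(newdata$descriptors))
    apply_preprocessing(object$prep, newdata$descriptors) else NULL
  n <- length(newdata$ids)
  pred <- numeric(n); module <- integer(n); case <- character(n)
  for (k in seq_len(n)) {
    a <- assign_module(object, fps[k, ])
    module[k] <- a$module; case[k] <- a$case
    sub <- object$submodels[[as.character(a$module)]]
    pred[k] <- if (isTRUE(sub$constant)) sub$regions[[1]]$intercept
               else {
                 if (is.null(Xs)) stop("newdata needs descriptors")
                 predict_piecewise(sub, Xs[k, , drop = FALSE])
               }
  }
  data.frame(id = newdata$ids, pred_pic50 = pred, module = module,
             case = case, in_ad = case != "nearest_only",
             stringsAsFactors = FALSE)
}

#' @export
print.modsar <- function(x, ...) {
  cat("modSAR model\n")
  cat("  molecules:", length(x$ids), "  t* =", x$t_star,
      "  Q =", round(x$partition$q, 4), "\n")
  cat("  modules:", length(x$partition$main_modules), "main +",
      length(x$partition$singletons), "singletons\n")
  cat("  training MAE:", round(mean(abs(x$residuals)), 4), "\n")
  invisible(x)
}

#' @export
summary.modsar <- function(object, ...) {
  mods <- sort(unique(object$partition$membership))
  tab <- do.call(rbind, lapply(mods, function(m) {
    sub <- object$submodels[[as.character(m)]]
    data.frame(module = m, size = sum(object$partition$membership == m),
               singleton = isTRUE(sub$constant),
               regions = sub$R,
               feature = if (is.na(sub$partition_feature)) "" else sub$partition_feature,
               train_mae = sub$train_mae)
  }))
  out <- list(t_star = object$t_star, q = object$partition$q,
              modules = tab, overall_mae = mean(abs(object$residuals)))
  class(out) <- "summary.modsar"
  out
}

#' @export
print.summary.modsar <- function(x, ...) {
  cat("modSAR model summary\n")
  cat("  t* =", x$t_star, "  Q =", round(x$q, 4),
      "  training MAE =", round(x$overall_mae, 4), "\n\n")
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.modsar <- function(object, ...) object$fitted

#' @export
residuals.modsar <- function(object, ...) object$residuals

#' @export
coef.modsar <- function(object, ...) {
  mods <- sort(unique(object$partition$membership))
  do.call(rbind, lapply(mods, function(m)
    rule_table(object$submodels[[as.character(m)]],
               module = sprintf("m%02d", m))))
}

#' Plot a modSAR model
#'
#' Plots the ACC-vs-threshold scan with the selected `t*` (when a scan was
#' run), or the module-coloured similarity network otherwise.
#'
#' @param x a `modsar` model.
#' @param which `"scan"` or `"network"`.
#' @param ... passed to the underlying plot function.
#' @export
plot.modsar <- function(x, which = c("scan", "network"), ...) {
  which <- match.arg(which)
  if (which == "scan" && !is.null(x$scan)) {
    plot(x$scan$table$t_alpha, x$scan$table$acc, type = "l",
         xlab = "similarity threshold", ylab = "average clustering coefficient",
         ...)
    graphics::abline(v = x$t_star, lty = 2)
    graphics::mtext(sprintf("t* = %.2f", x$t_star), side = 3, adj = 1)
  } else {
    plot(x$graph, vertex.color = x$partition$membership,
         vertex.label = NA, vertex.size = 5, ...)
  }
  invisible(x)
}

#' Export the per-module rule tables as CSV
#'
#' @param model a `modsar` model.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_rules <- function(model, file) {
  utils::write.csv(coef(model), file, row.names = FALSE)
  invisible(file)
}

serialize_oplra <- function(sub) {
  list(constant = isTRUE(sub$constant),
       partition_feature = if (is.na(sub$partition_feature)) NULL else sub$partition_feature,
       breakpoints = as.numeric(sub$breakpoints),
       regions = lapply(sub$regions, function(r)
         list(index = r$index,
              lower = if (is.finite(r$lower)) r$lower else NULL,
              upper = if (is.finite(r$upper)) r$upper else NULL,
              coef_names = names(r$coefficients),
              coef_values = as.numeric(r$coefficients),
              intercept = r$intercept)),
       lambda = sub$lambda, train_mae = sub$train_mae,
       objective = sub$objective, n_samples = sub$n_samples, R = sub$R)
}

deserialize_oplra <- function(s) {
  regions <- lapply(s$regions, function(r) {
    list(index = as.integer(r$index),
         lower = if (is.null(r$lower)) -Inf else as.numeric(r$lower),
         upper = if (is.null(r$upper)) Inf else as.numeric(r$upper),
         coefficients = stats::setNames(as.numeric(unlist(r$coef_values)),
                                        as.character(unlist(r$coef_names))),
         intercept = as.numeric(r$intercept))
  })
  m <- structure(list(
    partition_feature = if (is.null(s$partition_feature)) NA_character_
                        else s$partition_feature,
    breakpoints = as.numeric(unlist(s$breakpoints)),
    regions = regions,
    lambda = if (is.null(s$lambda)) NA_real_ else as.numeric(s$lambda),
    train_mae = as.numeric(s$train_mae), objective = as.numeric(s$objective),
    n_samples = as.integer(s$n_samples), R = as.integer(s$R)),
    class = "oplra")
  if (isTRUE(s$constant)) m$constant <- TRUE
  m
}

#' Save a modSAR model to a JSON file
#'
#' Writes a single self-describing, versioned JSON file holding everything
#' prediction needs: the threshold, preprocessing state, network edges,
#' partition, per-module equations and the training fingerprints (as set-bit
#' indices). Numeric values are stored at full precision so that a reloaded
#' model predicts bit-identically.
#'
#' @param model a `modsar` model.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_modsar <- function(model, file) {
  ends <- igraph::ends(model$graph, igraph::E(model$graph), names = TRUE)
  obj <- list(
    format = "modsar", version = "1.0",
    t_star = model$t_star, lambda = model$lambda, seed = model$seed,
    fingerprint_cfg = model$fingerprint_cfg,
    prep = list(names = model$prep$names,
                min = as.numeric(model$prep$scaling$min),
                max = as.numeric(model$prep$scaling$max),
                params = model$prep$params,
                dropped = model$prep$dropped),
    partition = list(ids = names(model$partition$membership),
                     module = as.integer(model$partition$membership),
                     q = model$partition$q),
    edges = list(from = if (nrow(ends)) ends[, 1] else character(0),
                 to = if (nrow(ends)) ends[, 2] else character(0),
                 tanimoto = if (nrow(ends))
                   as.numeric(igraph::E(model$graph)$tanimoto) else numeric(0)),
    submodels = lapply(model$submodels, serialize_oplra),
    training = list(ids = model$ids, activity = as.numeric(model$activity),
                    n_bits = ncol(model$fingerprints),
                    bits = lapply(seq_len(nrow(model$fingerprints)), function(k)
                      which(model$fingerprints[k, ] == 1L))))
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}

#' Load a modSAR model from a JSON file
#'
#' @param file path written by [write_modsar()].
#' @return A `modsar` model usable with [predict.modsar()].
#' @export
read_modsar <- function(file) {
  s <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (!identical(s$format, "modsar")) stop("not a modSAR model file")
  ids <- as.character(unlist(s$training$ids))
  n_bits <- as.integer(s$training$n_bits)
  fps <- matrix(0L, length(ids), n_bits, dimnames = list(ids, NULL))
  for (k in seq_along(ids)) fps[k, unlist(s$training$bits[[k]])] <- 1L
  memb <- stats::setNames(as.integer(unlist(s$partition$module)),
                          as.character(unlist(s$partition$ids)))
  sizes <- table(memb)
  partition <- structure(list(
    membership = memb, q = as.numeric(s$partition$q),
    main_modules = as.integer(names(sizes)[sizes >= 2]),
    singletons = as.integer(names(sizes)[sizes == 1]),
    sizes = sizes), class = "module_partition")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  efrom <- as.character(unlist(s$edges$from))
  if (length(efrom)) {
    g <- igraph::add_edges(g, rbind(match(efrom, ids),
                                    match(as.character(unlist(s$edges$to)), ids)))
    igraph::E(g)$tanimoto <- as.numeric(unlist(s$edges$tanimoto))
  }
  g <- igraph::set_graph_attr(g, "t_alpha", as.numeric(s$t_star))
  pn <- as.character(unlist(s$prep$names))
  prep <- structure(list(values = NULL, names = pn,
                         scaling = data.frame(name = pn,
                                              min = as.numeric(unlist(s$prep$min)),
                                              max = as.numeric(unlist(s$prep$max))),
                         dropped = as.character(unlist(s$prep$dropped)),
                         params = lapply(s$prep$params, unlist)),
                    class = "descriptor_prep")
  submodels <- lapply(s$submodels, deserialize_oplra)
  activity <- stats::setNames(as.numeric(unlist(s$training$activity)), ids)
  structure(list(call = NULL, t_star = as.numeric(s$t_star), scan = NULL,
                 graph = g, partition = partition, submodels = submodels,
                 prep = prep,
                 fingerprint_cfg = lapply(s$fingerprint_cfg, as.numeric),
                 lambda = as.numeric(s$lambda), control = NULL,
                 seed = s$seed, ids = ids, activity = activity,
                 fingerprints = fps, fitted = NULL, residuals = NULL),
            class = "modsar")
}
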