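# Optimal piecewise linear regression with L1 regularisation (OPLRAreg).
#
# The underlying mixed-integer program chooses one partition descriptor,
# ordered breakpoints B[1] <= ... <= B[R-1], binary sample-to-region
# assignments consistent with those breakpoints, and per-region weights
# minimising the sum of absolute residuals plus lambda * sum |w|. Because
# assignments must respect the ordering of the partition feature, every
# feasible assignment is a contiguous segmentation of the samples sorted by
# that feature (ties may split at a breakpoint). The program is therefore
# solved exactly by dynamic programming over split positions, with each
# segment's L1-regularised least-absolute-deviation fit solved as a linear
# program (Barrodale-Roberts simplex via quantreg; the penalty enters as
# zero-response pseudo-observations lambda * e_j with no intercept).

#' Control parameters for OPLRAreg fitting
#'
#' @param min_region_size smallest number of samples allowed per region.
#' @param small_module modules with fewer samples than this get a
#'   single-region model without breakpoint search.
#' @param epsilon relative training-MAE improvement required to accept an
#'   additional region.
#' @param r_max hard cap on the number of regions.
#' @param delta minimum separation between breakpoints on the [0, 1]
#'   descriptor scale.
#' @param top_k number of candidate partition features retained after the
#'   univariate split-improvement prefilter (`Inf` = consider all).
#' @return A list of class `oplra_control`.
#' @export
oplra_control <- function(min_region_size = 5, small_module = 10,
                          epsilon = 0.03, r_max = 6, delta = 1e-4,
                          top_k = Inf) {
  stopifnot(min_region_size >= 1, r_max >= 1, epsilon >= 0, top_k >= 1)
  structure(list(min_region_size = min_region_size,
                 small_module = small_module, epsilon = epsilon,
                 r_max = r_max, delta = delta, top_k = top_k),
            class = "oplra_control")
}

# Exact LAD + L1 fit: minimise sum |y - (b + Xw)| + lambda * sum |w|.
# Solved as an LP; a floor on the penalty keeps the basis nonsingular when
# lambda = 0 and the segment is short (the objective reported is computed
# with the true lambda from the returned coefficients).
lad_l1_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n == 0) stop("empty segment")
  if (n == 1) {
    coefs <- stats::setNames(numeric(p), colnames(X))
    return(list(intercept = y[1], coefficients = coefs, fitted = y[1],
                mae = 0, objective = 0))
  }
  lam_eff <- max(lambda, 1e-9)
  A <- rbind(cbind(1, X), cbind(0, lam_eff * diag(p)))
  ya <- c(y, rep(0, p))
  fit <- suppressWarnings(quantreg::rq.fit.br(A, ya, tau = 0.5))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  w <- beta[-1]
  w[abs(w) < 1e-8] <- 0
  fitted <- as.vector(X %*% w) + beta[1]
  res <- y - fitted
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(unname(w), colnames(X)),
       fitted = fitted, mae = mean(abs(res)),
       objective = sum(abs(res)) + lambda * sum(abs(w)))
}

# Univariate prefilter score: best residual-sum-of-squares reduction over a
# single split of the samples ordered by the feature. Cheap heuristic used
# only to shortlist candidate partition features.
split_score <- function(x, y, min_region_size) {
  o <- order(x)
  ys <- y[o]
  n <- length(ys)
  if (n < 2 * min_region_size) return(0)
  cs <- cumsum(ys); cs2 <- cumsum(ys^2)
  tot <- cs2[n] - cs[n]^2 / n
  ks <- min_region_size:(n - min_region_size)
  left <- cs2[ks] - cs[ks]^2 / ks
  right <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
  max(tot - (left + right), 0)
}

# Dynamic program over contiguous segments of the sorted samples.
# cost_fn(i, j) returns the exact LAD+L1 objective of segment i..j.
segment_dp <- function(n, R, min_region_size, cost_fn) {
  best <- matrix(Inf, R, n)
  arg <- matrix(NA_integer_, R, n)
  for (j in min_region_size:n) best[1, j] <- cost_fn(1, j)
  if (R > 1) {
    for (r in 2:R) {
      jmin <- r * min_region_size
      if (jmin > n) break
      for (j in jmin:n) {
        is <- ((r - 1) * min_region_size + 1):(j - min_region_size + 1)
        vals <- vapply(is, function(i) best[r - 1, i - 1] + cost_fn(i, j),
                       numeric(1))
        k <- which.min(vals)
        best[r, j] <- vals[k]
        arg[r, j] <- is[k]
      }
    }
  }
  if (!is.finite(best[R, n])) return(NULL)
  starts <- integer(R)
  j <- n
  for (r in R:1) {
    starts[r] <- if (r == 1) 1L else arg[r, j]
    j <- starts[r] - 1L
  }
  list(objective = best[R, n], starts = starts)
}

#' Fit a piecewise linear model with a fixed feature and region count
#'
#' Solves, to optimality, the piecewise regression program for a given
#' partition feature and number of regions `R`: samples are split into `R`
#' ordered regions along the feature, and each region gets an L1-regularised
#' least-absolute-deviation linear equation. The objective is the total sum
#' of absolute residuals plus `lambda` times the sum of absolute
#' coefficients. Breakpoints are placed midway between the boundary samples.
#'
#' @param X numeric descriptor matrix with named columns (scaled to [0, 1]).
#' @param y numeric response (pIC50).
#' @param feature name of the partition descriptor (ignored when `R = 1`).
#' @param R number of regions (>= 1).
#' @param lambda L1 regularisation weight.
#' @param control an [oplra_control()].
#' @param cache optional environment memoising segment fits across calls
#'   with the same feature ordering.
#' @return An object of class `oplra` (see [fit_oplra()]).
#' @export
fit_fixed <- function(X, y, feature = NULL, R = 1, lambda = 0.005,
                      control = oplra_control(), cache = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (R < 1) stop("R must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  if (R == 1) {
    # a single region has no breakpoints, so the per-region size floor
    # does not bind
    f <- lad_l1_fit(X, y, lambda)
    return(new_oplra(NA_character_, numeric(0), list(f), lambda,
                     f$mae, f$objective, n))
  }
  if (n < R * control$min_region_size)
    stop("sizing error: ", n, " samples cannot fill ", R, " regions of size >= ",
         control$min_region_size)
  if (is.null(feature) || !feature %in% colnames(X))
    stop("unknown partition feature: ", feature)
  o <- order(X[, feature])
  xs <- X[o, feature]
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cost_fn <- function(i, j) {
    key <- paste0(i, "_", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit$objective)
    f <- lad_l1_fit(X[o[i:j], , drop = FALSE], y[o[i:j]], lambda)
    cache[[key]] <- f
    f$objective
  }
  sol <- segment_dp(n, R, control$min_region_size, cost_fn)
  if (is.null(sol)) stop("sizing error: no feasible segmentation")
  fits <- lapply(seq_len(R), function(r) {
    i <- sol$starts[r]
    j <- if (r == R) n else sol$starts[r + 1] - 1L
    cache[[paste0(i, "_", j)]]
  })
  bps <- vapply(seq_len(R - 1), function(r) {
    k <- sol$starts[r + 1] - 1L
    (xs[k] + xs[k + 1]) / 2
  }, numeric(1))
  mae <- sum(vapply(fits, function(f) f$mae * length(f$fitted), numeric(1))) / n
  new_oplra(feature, bps, fits, lambda, mae, sol$objective, n)
}

new_oplra <- function(feature, breakpoints, fits, lambda, mae, objective, n) {
  R <- length(fits)
  regions <- lapply(seq_len(R), function(r) {
    co <- fits[[r]]$coefficients
    list(index = r,
         lower = if (r == 1) -Inf else breakpoints[r - 1],
         upper = if (r == R) Inf else breakpoints[r],
         coefficients = co[co != 0],
         intercept = fits[[r]]$intercept)
  })
  structure(list(partition_feature = feature, breakpoints = breakpoints,
                 regions = regions, lambda = lambda, train_mae = mae,
                 objective = objective, n_samples = n, R = R),
            class = "oplra")
}

# Constant model used for singleton modules: prediction equals the stored
# activity, no descriptors involved.
constant_model <- function(value, n = 1) {
  m <- new_oplra(NA_character_, numeric(0),
                 list(list(coefficients = stats::setNames(numeric(0), character(0)),
                           intercept = value, fitted = rep(value, n), mae = 0)),
                 NA_real_, 0, 0, n)
  m$constant <- TRUE
  m
}

#' Fit an optimal piecewise linear regression model
#'
#' Starts from a single region and adds regions while the training MAE
#' improves by more than the relative tolerance `control$epsilon`, up to
#' `control$r_max`. At each region count, every candidate partition feature
#' (optionally shortlisted to `control$top_k` by a univariate
#' split-improvement score) is fitted with [fit_fixed()] and the best
#' objective kept. Modules smaller than `control$small_module` get a
#' single-region model; a single sample yields a constant model equal to its
#' activity.
#'
#' @inheritParams fit_fixed
#' @return An object of class `oplra` with elements `partition_feature`,
#'   `breakpoints`, `regions` (each with bounds, sparse coefficients and
#'   intercept), `lambda`, `train_mae`, `objective`, `n_samples`, `R`.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' y <- ifelse(x < 0.5, x + 1, 3 - x)
#' m <- fit_oplra(cbind(D1 = x), y, lambda = 0)
#' m$R # 2
#' @export
fit_oplra <- function(X, y, lambda = 0.005, control = oplra_control()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("no samples")
  if (n == 1) return(constant_model(y[1]))
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  best <- fit_fixed(X, y, R = 1, lambda = lambda, control = control)
  if (n < control$small_module) return(best)

  feats <- colnames(X)
  if (is.finite(control$top_k) && control$top_k < length(feats)) {
    sc <- vapply(feats, function(f)
      split_score(X[, f], y, control$min_region_size), numeric(1))
    feats <- feats[order(sc, decreasing = TRUE)][seq_len(control$top_k)]
  }
  caches <- lapply(feats, function(f) new.env(parent = emptyenv()))
  names(caches) <- feats

  for (R in 2:control$r_max) {
    if (n < R * control$min_region_size) break
    cand <- NULL
    for (f in feats) {
      m <- fit_fixed(X, y, feature = f, R = R, lambda = lambda,
                     control = control, cache = caches[[f]])
      if (is.null(cand) || m$objective < cand$objective) cand <- m
    }
    if (best$train_mae <= 1e-12) break
    if ((best$train_mae - cand$train_mae) / best$train_mae > control$epsilon) {
      best <- cand
    } else break
  }
  best
}

#' Predict from a piecewise linear model
#'
#' Locates the region by comparing the partition feature's value against the
#' breakpoints (half-open intervals: a value exactly at a breakpoint belongs
#' to the upper region) and evaluates that region's linear equation.
#'
#' @param model an `oplra` model.
#' @param x named numeric vector, matrix or data frame of descriptors on the
#'   model's (scaled) descriptor space.
#' @return Numeric vector of predictions.
#' @export
predict_piecewise <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  needed <- unique(c(if (!is.na(model$partition_feature)) model$partition_feature,
                     unlist(lapply(model$regions, function(r) names(r$coefficients)))))
  missing <- setdiff(needed, colnames(x))
  if (length(missing))
    stop("missing descriptor: ", paste(missing, collapse = ", "))
  ri <- if (model$R == 1) rep(1L, nrow(x))
        else findInterval(x[, model$partition_feature], model$breakpoints) + 1L
  vapply(seq_len(nrow(x)), function(k) {
    reg <- model$regions[[ri[k]]]
    reg$intercept + sum(reg$coefficients * x[k, names(reg$coefficients)])
  }, numeric(1))
}

#' @export
predict.oplra <- function(object, newdata, ...) predict_piecewise(object, newdata)

#' @export
coef.oplra <- function(object, ...) {
  lapply(object$regions, function(r)
    c(`(Intercept)` = r$intercept, r$coefficients))
}

#' Human-readable rule table for a piecewise model
#'
#' One row per region with the breakpoint rule and the fitted equation,
#' rounded to two decimals for display (prediction always uses full
#' precision).
#'
#' @param model an `oplra` model.
#' @param module optional module label for the first column.
#' @return A data frame with columns `module`, `region`, `rule`, `equation`.
#' @export
rule_table <- function(model, module = NA) {
  f <- model$partition_feature
  rows <- lapply(model$regions, function(r) {
    rule <- if (model$R == 1) "all" else {
      lo <- if (is.finite(r$lower)) paste0(round(r$lower, 2), " <= ") else ""
      hi <- if (is.finite(r$upper)) paste0(" < ", round(r$upper, 2)) else ""
      paste0(lo, f, hi)
    }
    co <- r$coefficients
    eq <- if (length(co) == 0) sprintf("pIC50 = %+.2f", r$intercept) else
      paste0("pIC50 = ",
             paste(sprintf("%+.2f %s", co, names(co)), collapse = " "),
             sprintf(" %+.2f", r$intercept))
    data.frame(module = module, region = r$index, rule = rule, equation = eq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.oplra <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("oplra constant model: pIC50 =", x$regions[[1]]$intercept, "\n")
    return(invisible(x))
  }
  cat("oplra model:", x$R, "region(s)",
      if (!is.na(x$partition_feature))
        paste0("split on ", x$partition_feature) else "",
      "\n  train MAE:", round(x$train_mae, 4),
      " lambda:", x$lambda, "\n")
  print(rule_table(x)[, c("region", "rule", "equation")], row.names = FALSE)
  invisible(x)
}
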