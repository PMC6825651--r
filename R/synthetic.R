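# Synthetic benchmark generator: molecules-as-bitsets with planted module
# structure and piecewise-linear activity surfaces, so the whole pipeline is
# testable without external chemistry data.
#
# Bit-overlap calibration. Every molecule carries exactly b set bits: it
# keeps a uniform random subset of size b - f of its module's b-bit core and
# replaces the rest with f bits drawn (without replacement) from a pool
# disjoint from all cores. Two molecules of the same module then share
# (b - f)^2 / b core bits in expectation, so the expected intra-module
# Tanimoto is I / (2b - I) with I = (b - f)^2 / b, and f is solved from the
# target: f = b - round(sqrt(b * I_target)), I_target = 2b t / (1 + t).
# All cores share g common bits, each retained with probability
# rho = (b - f) / b, so the expected inter-module intersection is g rho^2
# and g is solved the same way from the inter-module target.

#' Specification of a synthetic benchmark
#'
#' @param n_modules number of planted modules.
#' @param per_module molecules per module.
#' @param n_bits fingerprint length.
#' @param bits_per_mol set bits per molecule.
#' @param intra_tc,inter_tc target expected Tanimoto similarity within and
#'   between modules (`intra_tc > inter_tc`, guaranteeing a similarity gap).
#' @param n_descriptors number of descriptor columns (uniform on [0, 1],
#'   independent of the fingerprints so module recovery and regression
#'   recovery are separable).
#' @param regions_per_module number of planted activity regions per module.
#' @param noise_sd Gaussian noise added to the activities (log units).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_modules = 3, per_module = 20, n_bits = 1024,
                           bits_per_mol = 100, intra_tc = 0.6, inter_tc = 0.1,
                           n_descriptors = 8, regions_per_module = 2,
                           noise_sd = 0.1, seed = 1) {
  if (intra_tc <= inter_tc) stop("intra_tc must exceed inter_tc")
  if (regions_per_module < 1) stop("regions_per_module must be >= 1")
  structure(list(n_modules = n_modules, per_module = per_module,
                 n_bits = n_bits, bits_per_mol = bits_per_mol,
                 intra_tc = intra_tc, inter_tc = inter_tc,
                 n_descriptors = n_descriptors,
                 regions_per_module = regions_per_module,
                 noise_sd = noise_sd, seed = seed),
            class = "benchmark_spec")
}

overlap_calibration <- function(spec) {
  b <- spec$bits_per_mol
  keep <- round(sqrt(b * 2 * b * spec$intra_tc / (1 + spec$intra_tc)))
  f <- b - keep
  if (f < 0 || f >= b) stop("overlap targets incompatible with bits_per_mol")
  rho <- keep / b
  g <- round(2 * b * spec$inter_tc / (1 + spec$inter_tc) / rho^2)
  if (g < 0 || g >= b) stop("overlap targets incompatible with bits_per_mol")
  core_bits <- g + spec$n_modules * (b - g)
  pool <- spec$n_bits - core_bits
  if (pool < f) stop("overlap targets incompatible with n_bits")
  list(f = f, g = g, keep = keep)
}

#' Generate a synthetic benchmark data set
#'
#' Plants `n_modules` blocks of molecules whose fingerprints share a module
#' core (yielding the calibrated intra/inter Tanimoto gap) and whose
#' activity is a module-specific piecewise-linear function of one designated
#' descriptor plus Gaussian noise. Region equations are independent lines
#' (slope magnitude 2-4, alternating signs, and a discontinuity of 1-2 log
#' units at every breakpoint), matching the kind of per-region equations the
#' method is designed to recover. Deterministic given `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [benchmark_spec()].
#' @return A list with `molecules` (a [molecule_set()]) and `truth` (planted
#'   labels, per-module partition feature, breakpoints and region
#'   coefficients, and the noiseless activities).
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  cal <- overlap_calibration(spec)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  M <- spec$n_modules; n <- M * spec$per_module
  b <- spec$bits_per_mol; g <- cal$g; f <- cal$f
  ids <- sprintf("M%03d", seq_len(n))
  labels <- rep(seq_len(M), each = spec$per_module)

  all_bits <- seq_len(spec$n_bits)
  shared <- sample(all_bits, g)
  remaining <- setdiff(all_bits, shared)
  cores <- vector("list", M)
  for (m in seq_len(M)) {
    own <- sample(remaining, b - g)
    remaining <- setdiff(remaining, own)
    cores[[m]] <- c(shared, own)
  }
  pool <- remaining

  fps <- matrix(0L, n, spec$n_bits, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    kept <- sample(cores[[labels[i]]], b - f)
    fps[i, c(kept, sample(pool, f))] <- 1L
  }

  desc <- matrix(stats::runif(n * spec$n_descriptors), n, spec$n_descriptors,
                 dimnames = list(ids, paste0("D", seq_len(spec$n_descriptors))))

  R <- spec$regions_per_module
  features <- integer(M)
  regions <- vector("list", M)
  breakpoints <- vector("list", M)
  noiseless <- numeric(n)
  for (m in seq_len(M)) {
    features[m] <- sample(spec$n_descriptors, 1)
    bps <- if (R > 1) (seq_len(R - 1)) / R else numeric(0)
    s0 <- sample(c(-1, 1), 1)
    slopes <- s0 * (-1)^(seq_len(R) - 1) * stats::runif(R, 2, 4)
    ic <- numeric(R)
    ic[1] <- stats::runif(1, 5, 7)
    if (R > 1) for (r in 2:R) {
      left_val <- slopes[r - 1] * bps[r - 1] + ic[r - 1]
      jump <- sample(c(-1, 1), 1) * stats::runif(1, 1, 2)
      ic[r] <- left_val + jump - slopes[r] * bps[r - 1]
    }
    regions[[m]] <- data.frame(
      region = seq_len(R),
      lower = c(-Inf, bps), upper = c(bps, Inf),
      slope = slopes, intercept = ic)
    breakpoints[[m]] <- bps
    idx <- which(labels == m)
    x <- desc[idx, features[m]]
    ri <- findInterval(x, bps) + 1L
    noiseless[idx] <- slopes[ri] * x + ic[ri]
  }
  y <- noiseless + stats::rnorm(n, 0, spec$noise_sd)

  truth <- list(labels = stats::setNames(labels, ids),
                features = paste0("D", features),
                regions = regions, breakpoints = breakpoints,
                noiseless = stats::setNames(noiseless, ids),
                spec = spec)
  list(molecules = molecule_set(ids, y, fingerprints = fps,
                                descriptors = desc),
       truth = truth)
}

#' Recompute noiseless activities from the planted truth
#'
#' @param truth the `truth` component of [generate_benchmark()].
#' @param descriptors descriptor matrix of the generated molecules.
#' @return Named numeric vector of noiseless activities.
#' @export
noiseless_activity <- function(truth, descriptors) {
  n <- length(truth$labels)
  out <- numeric(n)
  for (m in seq_along(truth$features)) {
    idx <- which(truth$labels == m)
    x <- descriptors[idx, truth$features[m]]
    reg <- truth$regions[[m]]
    ri <- findInterval(x, truth$breakpoints[[m]]) + 1L
    out[idx] <- reg$slope[ri] * x + reg$intercept[ri]
  }
  stats::setNames(out, names(truth$labels))
}

#' Compare a trained model against the planted truth
#'
#' Reports how well a model trained on a generated benchmark recovered the
#' planted structure: the adjusted Rand index between planted and detected
#' modules, and, for each planted module whose majority detected module has a
#' piecewise submodel, whether the partition feature matches, the breakpoint
#' errors (on the raw descriptor scale), whether each recovered breakpoint
#' falls inside the true split's sample gap, and whether the per-region
#' slope signs on the planted feature match.
#'
#' @param molecules the generated [molecule_set()].
#' @param truth the planted truth from [generate_benchmark()].
#' @param model a [modsar()] model trained on `molecules`.
#' @return A list with `ari`, `residual_mae` and a per-module data frame
#'   `modules`.
#' @export
verify_recovery <- function(molecules, truth, model) {
  memb <- model$partition$membership[molecules$ids]
  ari <- mclust::adjustedRandIndex(truth$labels, memb)
  residual_mae <- mean(abs(model$residuals))

  unscale <- function(feature, v) {
    s <- model$prep$scaling
    k <- match(feature, s$name)
    s$min[k] + v * (s$max[k] - s$min[k])
  }
  rows <- lapply(seq_along(truth$features), function(m) {
    idx <- which(truth$labels == m)
    det <- as.integer(names(which.max(table(memb[idx]))))
    sub <- model$submodels[[as.character(det)]]
    feat_true <- truth$features[m]
    feat_match <- identical(sub$partition_feature, feat_true)
    bps_true <- truth$breakpoints[[m]]
    bp_err <- NA_real_; bp_in_gap <- NA; signs_ok <- NA
    if (feat_match && length(sub$breakpoints) > 0 && length(bps_true) > 0) {
      bps_rec <- unscale(feat_true, sub$breakpoints)
      # every true breakpoint must be matched by some recovered breakpoint;
      # extra recovered breakpoints (over-segmentation) are reported through
      # n_regions, not penalised here
      bp_err <- max(vapply(bps_true, function(b)
        min(abs(bps_rec - b)), numeric(1)))
      x <- molecules$descriptors[idx, feat_true]
      bp_in_gap <- all(vapply(bps_true, function(b) {
        lo <- max(x[x < b])
        hi <- min(x[x >= b])
        any(bps_rec >= lo & bps_rec <= hi)
      }, logical(1)))
      if (length(sub$breakpoints) == length(bps_true)) {
        signs_true <- sign(truth$regions[[m]]$slope)
        signs_rec <- vapply(sub$regions, function(r) {
          co <- r$coefficients[feat_true]
          if (is.na(co)) 0 else sign(co)
        }, numeric(1))
        signs_ok <- all(signs_rec == signs_true)
      }
    }
    data.frame(planted = m, detected = det, feature_match = feat_match,
               n_regions = sub$R, bp_error = bp_err, bp_in_gap = bp_in_gap,
               slope_signs_match = signs_ok)
  })
  list(ari = ari, residual_mae = residual_mae,
       modules = do.call(rbind, rows))
}

#' Write a generated benchmark to CSV files
#'
#' Writes the activity table and descriptor table in the schema
#' [read_molecules()] reads, plus a JSON truth file.
#'
#' @param bench output of [generate_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ms <- bench$molecules
  write_molecules(ms, file.path(dir, "activities.csv"))
  utils::write.csv(data.frame(id = ms$ids, ms$descriptors),
                   file.path(dir, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = ms$ids,
                              n_bits = ncol(ms$fingerprints),
                              bits = vapply(seq_len(nrow(ms$fingerprints)),
                                            function(k) paste(which(ms$fingerprints[k, ] == 1L),
                                                              collapse = ";"),
                                            character(1))),
                   file.path(dir, "fingerprints.csv"), row.names = FALSE)
  tr <- bench$truth
  jsonlite::write_json(list(labels = unname(tr$labels), ids = names(tr$labels),
                            features = tr$features,
                            breakpoints = tr$breakpoints,
                            regions = tr$regions,
                            noiseless = unname(tr$noiseless),
                            spec = unclass(tr$spec)),
                       file.path(dir, "truth.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(dir)
}
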