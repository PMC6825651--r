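#' Convert IC50 (molar) to pIC50
#'
#' pIC50 = -log10(IC50) with IC50 in molar units, so 1 uM = 6 and 10 nM = 8.
#' Higher values mean more potent compounds.
#'
#' @param value numeric vector of IC50 values in molar units, strictly
#'   positive and finite.
#' @return Numeric vector of pIC50 values.
#' @examples
#' to_pic50(1e-6) # 6
#' to_pic50(1e-8) # 8
#' @export
to_pic50 <- function(value) {
  if (!is.numeric(value) || length(value) == 0)
    stop("invalid activity: IC50 must be numeric")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("invalid activity: IC50 values must be finite and > 0")
  -log10(value)
}

#' Curate replicate activity measurements
#'
#' Applies the standard curation rules for public bioactivity data: compounds
#' with any flagged measurement (non-empty validity comment) are dropped;
#' compounds whose replicate pIC50 values have a sample standard deviation
#' greater than 1 log unit are dropped entirely; remaining replicates are
#' collapsed to their median; single measurements are kept verbatim.
#'
#' @param records data frame with columns `compound_id`, `pic50` and
#'   optionally `validity_comment` (empty string or `NA` means no flag).
#' @return Named numeric vector mapping compound id to curated pIC50. Empty
#'   input yields an empty vector.
#' @examples
#' recs <- data.frame(compound_id = c("a", "b", "b", "c", "c"),
#'                    pic50 = c(5, 5, 6, 4, 7))
#' curate_activities(recs) # a = 5, b = 5.5; c removed (sd > 1)
#' @export
curate_activities <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(stats::setNames(numeric(0), character(0)))
  if (!all(c("compound_id", "pic50") %in% names(records)))
    stop("records need columns 'compound_id' and 'pic50'")
  vc <- if ("validity_comment" %in% names(records)) records$validity_comment
        else rep("", nrow(records))
  vc[is.na(vc)] <- ""
  flagged <- unique(records$compound_id[vc != ""])
  records <- records[!(records$compound_id %in% flagged), , drop = FALSE]
  if (nrow(records) == 0) return(stats::setNames(numeric(0), character(0)))
  grp <- split(records$pic50, records$compound_id)
  out <- vapply(grp, function(v) {
    if (length(v) == 1) return(v)
    if (stats::sd(v) > 1) return(NA_real_)
    stats::median(v)
  }, numeric(1))
  out <- out[!is.na(out)]
  # preserve first-appearance order of compounds
  ord <- unique(records$compound_id)
  out[ord[ord %in% names(out)]]
}

#' Preprocess a descriptor matrix
#'
#' Removes near-zero-variance columns (most frequent / second most frequent
#' value ratio at least `freq_cut` and fewer distinct values than
#' `unique_cut` of the rows), removes one column of each highly correlated
#' pair (Pearson |r| above `corr_cutoff`; the column with the larger mean
#' absolute correlation to all others goes, mirroring
#' `caret::findCorrelation`), and min-max rescales the survivors to [0, 1].
#' The scaling parameters are retained so the identical transform can be
#' applied to test-set molecules with [apply_preprocessing()].
#'
#' @param x numeric matrix or data frame of descriptors (rows = molecules,
#'   named columns), at least two rows.
#' @param corr_cutoff pairwise absolute Pearson correlation above which one
#'   column of the pair is removed.
#' @param freq_cut,unique_cut near-zero-variance rule parameters.
#' @return An object of class `descriptor_prep` with elements `values` (the
#'   rescaled matrix), `names` (retained columns), `scaling` (per-column min
#'   and max), `dropped` and the parameters used.
#' @export
preprocess_descriptors <- function(x, corr_cutoff = 0.90,
                                   freq_cut = 19, unique_cut = 0.10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 molecules to preprocess descriptors")
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  dropped <- character(0)

  nzv <- caret::nearZeroVar(x, freqCut = freq_cut, uniqueCut = unique_cut * 100)
  # constant columns are always near-zero-variance, but guard explicitly
  const <- which(apply(x, 2, function(v) max(v) - min(v) == 0))
  nzv <- union(nzv, const)
  if (length(nzv)) {
    dropped <- colnames(x)[nzv]
    x <- x[, -nzv, drop = FALSE]
  }
  if (ncol(x) == 0) stop("degenerate descriptor matrix: all columns removed")

  if (ncol(x) > 1) {
    cm <- suppressWarnings(stats::cor(x))
    cm[is.na(cm)] <- 0
    hc <- caret::findCorrelation(cm, cutoff = corr_cutoff, exact = TRUE)
    if (length(hc)) {
      dropped <- c(dropped, colnames(x)[hc])
      x <- x[, -hc, drop = FALSE]
    }
  }
  if (ncol(x) == 0) stop("degenerate descriptor matrix: all columns removed")

  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  scaled <- sweep(sweep(x, 2, mins, "-"), 2, maxs - mins, "/")
  structure(list(values = scaled, names = colnames(x),
                 scaling = data.frame(name = colnames(x), min = mins, max = maxs,
                                      row.names = NULL),
                 dropped = dropped,
                 params = list(corr_cutoff = corr_cutoff, freq_cut = freq_cut,
                               unique_cut = unique_cut)),
            class = "descriptor_prep")
}

#' @export
print.descriptor_prep <- function(x, ...) {
  cat("descriptor_prep:", length(x$names), "descriptors retained,",
      length(x$dropped), "dropped;", nrow(x$values), "molecules\n")
  invisible(x)
}

#' Apply stored descriptor preprocessing to new molecules
#'
#' Selects the retained columns, applies the training min-max rescaling and
#' clips values falling outside the training range to [0, 1] so that region
#' rules stay well defined for out-of-range test compounds.
#'
#' @param prep a `descriptor_prep` from [preprocess_descriptors()].
#' @param newdata numeric matrix or data frame containing at least the
#'   retained descriptor columns.
#' @return Numeric matrix on the training scale, all values in [0, 1].
#' @export
apply_preprocessing <- function(prep, newdata) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(prep$names, colnames(newdata))
  if (length(missing))
    stop("missing descriptor columns: ", paste(missing, collapse = ", "))
  x <- newdata[, prep$names, drop = FALSE]
  storage.mode(x) <- "double"
  rng <- prep$scaling$max - prep$scaling$min
  x <- sweep(sweep(x, 2, prep$scaling$min, "-"), 2, rng, "/")
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
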