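#' Molecule set container
#'
#' Bundles everything the pipeline needs to know about a set of molecules:
#' identifiers, activities on the pIC50 scale, binary fingerprints and a
#' numeric descriptor matrix. Fingerprints and descriptors are optional at
#' construction time; fingerprints can be computed later from SMILES with
#' [compute_fingerprints()].
#'
#' @param ids character vector of unique compound identifiers.
#' @param activity numeric vector of pIC50 values, finite, one per compound.
#' @param fingerprints optional binary (0/1) integer matrix, one row per
#'   compound; all rows must have the same length (the configured number of
#'   bits).
#' @param descriptors optional numeric matrix or data frame, one row per
#'   compound, named columns.
#' @param smiles optional character vector of SMILES strings.
#' @return An object of class `molecule_set`.
#' @examples
#' ms <- molecule_set(c("a", "b"), c(6.1, 7.2),
#'                    fingerprints = rbind(c(1L, 0L, 1L), c(1L, 1L, 0L)),
#'                    descriptors = cbind(D1 = c(0.2, 0.8)))
#' ms
#' @export
molecule_set <- function(ids, activity, fingerprints = NULL,
                         descriptors = NULL, smiles = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicated compound identifiers")
  activity <- as.numeric(activity)
  if (length(activity) != n) stop("activity length must match ids")
  if (any(!is.finite(activity))) stop("activities must be finite")
  if (!is.null(fingerprints)) {
    fingerprints <- as.matrix(fingerprints)
    storage.mode(fingerprints) <- "integer"
    if (nrow(fingerprints) != n) stop("fingerprint rows must match ids")
    if (!all(fingerprints %in% c(0L, 1L))) stop("fingerprints must be 0/1")
    rownames(fingerprints) <- ids
  }
  if (!is.null(descriptors)) {
    descriptors <- as.matrix(descriptors)
    storage.mode(descriptors) <- "double"
    if (nrow(descriptors) != n) stop("descriptor rows must match ids")
    if (is.null(colnames(descriptors)))
      colnames(descriptors) <- paste0("D", seq_len(ncol(descriptors)))
    rownames(descriptors) <- ids
  }
  if (!is.null(smiles)) {
    smiles <- as.character(smiles)
    if (length(smiles) != n) stop("smiles length must match ids")
  }
  structure(list(ids = ids, activity = stats::setNames(activity, ids),
                 fingerprints = fingerprints, descriptors = descriptors,
                 smiles = smiles),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("molecule_set:", length(x$ids), "molecules\n")
  cat("  activity (pIC50): [", round(min(x$activity), 2), ",",
      round(max(x$activity), 2), "]\n")
  if (!is.null(x$fingerprints))
    cat("  fingerprints:", ncol(x$fingerprints), "bits\n")
  if (!is.null(x$descriptors))
    cat("  descriptors:", ncol(x$descriptors), "columns\n")
  invisible(x)
}

#' @export
length.molecule_set <- function(x) length(x$ids)

#' Subset a molecule set
#'
#' @param x a [molecule_set()].
#' @param i integer, logical or character index over molecules.
#' @param ... ignored.
#' @return A `molecule_set` restricted to the selected molecules.
#' @export
`[.molecule_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  molecule_set(x$ids[i], x$activity[i],
               fingerprints = if (!is.null(x$fingerprints)) x$fingerprints[i, , drop = FALSE],
               descriptors = if (!is.null(x$descriptors)) x$descriptors[i, , drop = FALSE],
               smiles = if (!is.null(x$smiles)) x$smiles[i])
}

#' Read molecules from CSV tables
#'
#' Reads an activity table (columns `id`, `activity`, optionally `smiles`,
#' `activity_units`, `validity_comment`) and an optional descriptor table
#' (first column `id`, remaining columns numeric), converts activities to the
#' pIC50 scale, applies the replicate-curation rules of
#' [curate_activities()], and assembles a [molecule_set()].
#'
#' Activity units: `"pic50"` values are taken as-is, `"molar"` IC50 values are
#' converted with [to_pic50()], and `"nM"` values are multiplied by 1e-9
#' first (the ChEMBL convention). A per-row `activity_units` column overrides
#' the `units` argument.
#'
#' @param file path to the activity CSV.
#' @param descriptor_file optional path to the descriptor CSV.
#' @param units default unit for the `activity` column: `"molar"`, `"nM"` or
#'   `"pic50"`.
#' @return A [molecule_set()] of curated compounds.
#' @export
read_molecules <- function(file, descriptor_file = NULL,
                           units = c("molar", "nM", "pic50")) {
  units <- match.arg(units)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("id", "activity") %in% names(tab)))
    stop("activity CSV needs columns 'id' and 'activity'")
  u <- if ("activity_units" %in% names(tab)) tab$activity_units else rep(units, nrow(tab))
  u[is.na(u) | u == ""] <- units
  pic50 <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    pic50[k] <- switch(u[k],
      pic50 = tab$activity[k],
      molar = to_pic50(tab$activity[k]),
      nM = to_pic50(tab$activity[k] * 1e-9),
      stop("unknown activity unit: ", u[k]))
  }
  records <- data.frame(compound_id = as.character(tab$id), pic50 = pic50,
                        validity_comment = if ("validity_comment" %in% names(tab))
                          tab$validity_comment else "",
                        stringsAsFactors = FALSE)
  act <- curate_activities(records)
  keep <- names(act)
  smiles <- NULL
  if ("smiles" %in% names(tab))
    smiles <- tab$smiles[match(keep, tab$id)]
  descriptors <- NULL
  if (!is.null(descriptor_file)) {
    d <- utils::read.csv(descriptor_file, stringsAsFactors = FALSE)
    rn <- as.character(d[[1]])
    d <- as.matrix(d[, -1, drop = FALSE])
    rownames(d) <- rn
    missing <- setdiff(keep, rn)
    if (length(missing))
      stop("descriptor table lacks rows for: ", paste(missing, collapse = ", "))
    descriptors <- d[keep, , drop = FALSE]
  }
  molecule_set(keep, act, descriptors = descriptors, smiles = smiles)
}

#' Read precomputed fingerprints from CSV
#'
#' Reads the sparse bitset schema written by [write_benchmark()]: columns
#' `id`, `n_bits` and `bits` (semicolon-separated indices of the set bits).
#'
#' @param file path to the fingerprint CSV.
#' @return Integer 0/1 matrix with ids as row names.
#' @export
read_fingerprints <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("id", "n_bits", "bits") %in% names(tab)))
    stop("fingerprint CSV needs columns 'id', 'n_bits' and 'bits'")
  n_bits <- tab$n_bits[1]
  fps <- matrix(0L, nrow(tab), n_bits,
                dimnames = list(as.character(tab$id), NULL))
  for (k in seq_len(nrow(tab))) {
    idx <- as.integer(strsplit(tab$bits[k], ";", fixed = TRUE)[[1]])
    fps[k, idx] <- 1L
  }
  fps
}

#' Write a molecule set's curated activity table
#'
#' @param x a [molecule_set()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_molecules <- function(x, file) {
  tab <- data.frame(id = x$ids, activity = unname(x$activity),
                    activity_units = "pic50")
  if (!is.null(x$smiles)) tab$smiles <- x$smiles
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
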