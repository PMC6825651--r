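# Circular (ECFP-style) fingerprints.
#
# Structures are canonicalised with OpenBabel (via ChemmineOB) so that
# equivalent SMILES map to the same molecular graph, parsed with ChemmineR,
# and hashed with an iterative Morgan-style neighbourhood scheme: each atom
# starts from an invariant built from its element, heavy-atom degree,
# bond-order sum and formal charge; at every iteration the invariant is
# rehashed together with the sorted (bond order, neighbour invariant) pairs;
# all identifiers produced at radii 0..radius set one bit each in the
# fixed-length bitset. radius = 2 corresponds to ECFP4 (neighbourhoods up to
# four bonds in diameter).

MODSAR_HASH_MOD <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles

hash_ints <- function(v) {
  h <- 7
  for (x in v) h <- (h * 31 + (x %% MODSAR_HASH_MOD)) %% MODSAR_HASH_MOD
  h
}

element_code <- function(sym) {
  tab <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
           Cl = 17, Br = 35, I = 53)
  code <- unname(tab[sym])
  ifelse(is.na(code), vapply(sym, function(s) sum(utf8ToInt(s)), numeric(1)) + 200,
         code)
}

ecfp_from_graph <- function(elements, bonds, radius, n_bits) {
  # bonds: matrix with columns from, to, order (1-based atom indices)
  n_atoms <- length(elements)
  adj <- vector("list", n_atoms)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  bosum <- vapply(adj, function(a) if (is.null(a)) 0 else sum(a[, 2]), numeric(1))
  inv <- vapply(seq_len(n_atoms), function(i)
    hash_ints(c(element_code(elements[i]), deg[i], bosum[i])), numeric(1))
  ids <- inv
  for (r in seq_len(radius)) {
    inv_new <- numeric(n_atoms)
    for (i in seq_len(n_atoms)) {
      a <- adj[[i]]
      if (is.null(a)) {
        inv_new[i] <- hash_ints(c(r, inv[i]))
      } else {
        codes <- sort(vapply(seq_len(nrow(a)), function(k)
          hash_ints(c(a[k, 2], inv[a[k, 1]])), numeric(1)))
        inv_new[i] <- hash_ints(c(r, inv[i], codes))
      }
    }
    inv <- inv_new
    ids <- c(ids, inv)
  }
  bits <- integer(n_bits)
  bits[unique(ids %% n_bits) + 1] <- 1L
  bits
}

#' Compute a circular fingerprint from a SMILES string
#'
#' Computes an ECFP-type circular fingerprint: the SMILES is canonicalised
#' with OpenBabel, atoms receive initial invariants (element, degree,
#' bond-order sum), and Morgan-style iterative neighbourhood hashing up to
#' the given radius sets bits in a fixed-length bitset. The default
#' (radius 2, 1024 bits) is the ECFP4 configuration customary for chemical
#' space networks. Deterministic: identical structures, however written,
#' yield identical bitsets.
#'
#' Requires the suggested packages \pkg{ChemmineR} and \pkg{ChemmineOB}.
#'
#' @param smiles a single SMILES string.
#' @param radius neighbourhood radius (2 = ECFP4).
#' @param n_bits fingerprint length in bits.
#' @param id optional compound id used in error messages.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
compute_fingerprint <- function(smiles, radius = 2, n_bits = 1024, id = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineR and ChemmineOB are required to compute fingerprints from SMILES")
  stopifnot(length(smiles) == 1)
  label <- if (is.null(id)) smiles else id
  can <- tryCatch(
    trimws(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  if (is.na(can) || !nzchar(can))
    stop("structure parse error for '", label, "': invalid SMILES")
  can <- strsplit(can, "[ \t]")[[1]][1]
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(can)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0)
    stop("structure parse error for '", label, "'")
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  elements <- gsub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  ecfp_from_graph(elements, bonds, radius, n_bits)
}

#' Compute fingerprints for a vector of SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @param radius,n_bits see [compute_fingerprint()].
#' @param ids optional identifiers for rows and error messages.
#' @return Integer 0/1 matrix with one row per structure.
#' @export
compute_fingerprints <- function(smiles, radius = 2, n_bits = 1024, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  out <- matrix(0L, length(smiles), n_bits, dimnames = list(ids, NULL))
  for (k in seq_along(smiles))
    out[k, ] <- compute_fingerprint(smiles[k], radius, n_bits, id = ids[k])
  out
}
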