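#' Newman-Girvan modularity of a partition
#'
#' Evaluates Q = sum_c ( e_c / m - (d_c / 2m)^2 ) on the unweighted
#' thresholded graph, where m is the number of edges, e_c the number of
#' intra-community edges of community c and d_c its degree sum. An edgeless
#' graph has Q = 0 by convention.
#'
#' @param g an \pkg{igraph} graph.
#' @param membership community labels, one per node (in `igraph::V(g)` order,
#'   or named by node).
#' @return Modularity Q.
#' @examples
#' g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
#' modularity_q(g, rep(1:2, each = 4)) # 0.5
#' @export
modularity_q <- function(g, membership) {
  n <- igraph::vcount(g)
  if (length(membership) != n) stop("membership must cover all nodes")
  vn <- igraph::V(g)$name
  if (!is.null(names(membership)) && !is.null(vn) && all(vn %in% names(membership)))
    membership <- membership[vn]
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (comm in unique(membership)) {
    in_c <- membership == comm
    e_c <- sum(in_c[ends[, 1]] & in_c[ends[, 2]])
    d_c <- sum(deg[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Detect network modules by Louvain modularity optimisation
#'
#' Runs the Louvain method (greedy two-phase local moving and aggregation)
#' on the unweighted thresholded similarity network. Isolated nodes end up
#' as singleton modules. The reported Q is recomputed from the final
#' assignment with [modularity_q()]. The node visiting order depends on the
#' random seed, so results are deterministic given `seed`.
#'
#' @param g an \pkg{igraph} graph from [build_graph()].
#' @param seed integer RNG seed.
#' @param resolution modularity resolution parameter (1 = classic Q; larger
#'   values yield finer modules).
#' @return An object of class `module_partition` with `membership` (named
#'   integer vector), `q`, `main_modules` (ids with at least 2 members),
#'   `singletons` (ids with exactly 1 member) and `sizes`.
#' @export
detect_modules <- function(g, seed = 20191018, resolution = 1) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = NA, resolution = resolution)
    memb <- igraph::membership(cl)
  }
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  memb <- stats::setNames(as.integer(memb), ids)
  sizes <- table(memb)
  structure(list(membership = memb,
                 q = modularity_q(g, memb),
                 main_modules = as.integer(names(sizes)[sizes >= 2]),
                 singletons = as.integer(names(sizes)[sizes == 1]),
                 sizes = sizes),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$main_modules), "main modules,",
      length(x$singletons), "singletons, Q =", round(x$q, 4), "\n")
  invisible(x)
}

#' Export a module partition as CSV
#'
#' Writes the node-to-module map and a per-module summary.
#'
#' @param partition a `module_partition`.
#' @param file output path for the node table.
#' @param summary_file optional output path for the module summary.
#' @return `file`, invisibly.
#' @export
export_partition <- function(partition, file, summary_file = NULL) {
  utils::write.csv(data.frame(node = names(partition$membership),
                              module = unname(partition$membership)),
                   file, row.names = FALSE)
  if (!is.null(summary_file)) {
    mods <- sort(unique(partition$membership))
    utils::write.csv(data.frame(module = mods,
                                size = as.integer(table(partition$membership)[as.character(mods)]),
                                is_singleton = mods %in% partition$singletons),
                     summary_file, row.names = FALSE)
  }
  invisible(file)
}
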