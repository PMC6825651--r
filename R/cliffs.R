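#' Per-molecule activity discontinuity score
#'
#' Measures how abruptly activity changes across a molecule's network
#' neighbourhood: the similarity-weighted mean absolute activity difference
#' to its neighbours, `sum_j Tc(i,j) |y_i - y_j| / sum_j Tc(i,j)`. High
#' scores mark activity cliffs - structurally similar molecules with large
#' activity differences. Isolated nodes have no neighbourhood and get `NA`
#' (their cliff class is undefined). The score function is pluggable via
#' `score_fn` so alternative discontinuity measures (e.g. a max-pairwise
#' SALI-style score) can be swapped in.
#'
#' @param g a similarity network from [build_graph()] with a `tanimoto` edge
#'   attribute.
#' @param activities named numeric vector of pIC50 values covering the nodes.
#' @param score_fn optional function(similarities, abs_differences) -> score
#'   replacing the default weighted mean.
#' @return Named numeric vector of scores (`NA` for isolated nodes).
#' @export
discontinuity_scores <- function(g, activities, score_fn = NULL) {
  ids <- igraph::V(g)$name
  y <- activities[ids]
  if (any(is.na(y))) stop("activities must cover every node")
  if (is.null(score_fn))
    score_fn <- function(w, d) sum(w * d) / sum(w)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$tanimoto
  scores <- rep(NA_real_, length(ids))
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  inc <- igraph::incident_edges(g, igraph::V(g))
  for (i in seq_along(ids)) {
    ei <- as.integer(inc[[i]])
    if (length(ei) == 0) next
    nb <- as.integer(adj[[i]])
    scores[i] <- score_fn(w[ei], abs(y[i] - y[nb]))
  }
  stats::setNames(scores, ids)
}

#' Classify molecules by activity discontinuity
#'
#' Assigns each molecule with a defined score to the `low`, `intermediate`
#' or `high` discontinuity class: `score < t_low` is low, `t_low <= score <
#' t_high` intermediate, `score >= t_high` high. When no thresholds are
#' supplied, the tertiles (33rd/67th percentiles) of the defined scores are
#' used; fixed cutoffs can be given instead. Molecules without a score
#' (singletons) are `undefined`.
#'
#' @param scores named numeric score vector from [discontinuity_scores()].
#' @param thresholds optional numeric `c(t_low, t_high)` with
#'   `t_low < t_high`.
#' @return An object of class `cliff_profile`: a data frame `table` with
#'   columns `node`, `score`, `class`, plus the `thresholds` used.
#' @export
classify_cliffs <- function(scores, thresholds = NULL) {
  defined <- scores[!is.na(scores)]
  if (length(defined) == 0) stop("no defined discontinuity scores")
  if (is.null(thresholds))
    thresholds <- unname(stats::quantile(defined, c(1 / 3, 2 / 3)))
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    stop("thresholds must satisfy t_low < t_high")
  cls <- ifelse(is.na(scores), "undefined",
         ifelse(scores < thresholds[1], "low",
         ifelse(scores < thresholds[2], "intermediate", "high")))
  structure(list(table = data.frame(node = names(scores),
                                    score = unname(scores), class = cls,
                                    stringsAsFactors = FALSE),
                 thresholds = thresholds),
            class = "cliff_profile")
}

#' @export
print.cliff_profile <- function(x, ...) {
  cat("cliff_profile:", nrow(x$table), "molecules; thresholds",
      round(x$thresholds[1], 3), "/", round(x$thresholds[2], 3), "\n")
  print(table(x$table$class))
  invisible(x)
}

#' Per-module distribution of activity-cliff classes
#'
#' For every main module, the fraction of high / intermediate / low
#' molecules among its defined (non-singleton) members. Modules with no
#' defined member are omitted. Activity cliffs are not necessarily spread
#' evenly across the network, and this table shows where they concentrate.
#'
#' @param profile a `cliff_profile`.
#' @param partition a `module_partition` over the same nodes.
#' @return A data frame with columns `module`, `n_defined`, `high`,
#'   `intermediate`, `low` (proportions summing to 1 per row).
#' @export
module_cliff_summary <- function(profile, partition) {
  tab <- profile$table
  memb <- partition$membership[tab$node]
  if (any(is.na(memb))) stop("partition does not cover all profiled nodes")
  rows <- lapply(sort(unique(memb)), function(m) {
    cls <- tab$class[memb == m & tab$class != "undefined"]
    if (length(cls) == 0) return(NULL)
    data.frame(module = m, n_defined = length(cls),
               high = mean(cls == "high"),
               intermediate = mean(cls == "intermediate"),
               low = mean(cls == "low"))
  })
  do.call(rbind, rows)
}

#' Activity-cliff profile of a fitted modSAR model
#'
#' Convenience wrapper scoring and classifying every training molecule on
#' the model's similarity network.
#'
#' @param model a fitted [modsar()] model.
#' @param thresholds optional fixed cutoffs, see [classify_cliffs()].
#' @param score_fn optional score function, see [discontinuity_scores()].
#' @return A `cliff_profile` whose table gains a `module` column.
#' @export
cliff_profile <- function(model, thresholds = NULL, score_fn = NULL) {
  sc <- discontinuity_scores(model$graph, model$activity, score_fn = score_fn)
  prof <- classify_cliffs(sc, thresholds = thresholds)
  prof$table$module <- unname(model$partition$membership[prof$table$node])
  prof
}

#' Export a cliff profile as CSV and optionally GraphML
#'
#' @param profile a `cliff_profile`.
#' @param file output CSV path (id, score, class, module when available).
#' @param graph optional similarity network; when given, a GraphML file with
#'   the class as node attribute is written next to `file`.
#' @param graphml_file path for the GraphML export.
#' @return `file`, invisibly.
#' @export
export_cliffs <- function(profile, file, graph = NULL, graphml_file = NULL) {
  utils::write.csv(profile$table, file, row.names = FALSE)
  if (!is.null(graph) && !is.null(graphml_file)) {
    cls <- profile$table$class[match(igraph::V(graph)$name, profile$table$node)]
    g2 <- igraph::set_vertex_attr(graph, "cliff_class", value = cls)
    igraph::write_graph(g2, graphml_file, format = "graphml")
  }
  invisible(file)
}
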