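# Independent oracles used to check the package against first principles.

# Newman-Girvan modularity evaluated term by term from the definition.
brute_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  deg <- igraph::degree(g)
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    nodes <- which(membership == cc)
    e_c <- 0
    for (k in seq_len(m))
      if (ends[k, 1] %in% nodes && ends[k, 2] %in% nodes) e_c <- e_c + 1
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Local clustering by explicit triangle counting over neighbour pairs;
# nodes of degree < 2 contribute 0.
brute_average_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  lc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    closed <- sum(apply(pairs, 2, function(p) A[p[1], p[2]] == 1))
    lc[i] <- closed / ncol(pairs)
  }
  mean(lc)
}

# Exact least-absolute-deviation line (intercept + one slope): some optimal
# LAD line interpolates two sample points, so enumerate all point pairs.
lad_line_oracle <- function(x, y) {
  n <- length(y)
  if (n == 1) return(list(objective = 0, slope = 0, intercept = y))
  best <- list(objective = Inf)
  # slope-zero candidate through the median
  b0 <- stats::median(y)
  o0 <- sum(abs(y - b0))
  if (o0 < best$objective) best <- list(objective = o0, slope = 0, intercept = b0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    a <- (y[j] - y[i]) / (x[j] - x[i])
    b <- y[i] - a * x[i]
    obj <- sum(abs(y - (a * x + b)))
    if (obj < best$objective)
      best <- list(objective = obj, slope = a, intercept = b)
  }
  best
}

# Exhaustive two-region oracle: every one of the n-1 candidate split points
# of the samples ordered by x, two LAD line fits each.
two_region_oracle <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  best <- Inf
  for (k in 1:(n - 1)) {
    obj <- lad_line_oracle(xs[1:k], ys[1:k])$objective +
      lad_line_oracle(xs[(k + 1):n], ys[(k + 1):n])$objective
    if (obj < best) best <- obj
  }
  best
}

# Small hand-assembled model with controllable similarities: six training
# molecules over 40 bits, t* = 0.3. Modules: 1 = {t1,t2,t3}, 2 = {t4,t5},
# 3 = singleton {t6}. Module 1 carries a 2-region piecewise model on D1,
# module 2 a constant-equation region, module 3 the singleton constant 6.25.
make_toy_model <- function() {
  n_bits <- 40
  bits <- function(idx) { v <- integer(n_bits); v[idx] <- 1L; v }
  # t1..t5 are subsets of the probe bits 1:10 so query similarities are exact
  fps <- rbind(t1 = bits(1:4),    # |fp| = 4
               t2 = bits(1:5),    # 5
               t3 = bits(1:6),    # 6
               t4 = bits(1:7),    # 7
               t5 = bits(1:8),    # 8
               t6 = bits(21:30))  # disjoint singleton
  memb <- c(t1 = 1L, t2 = 1L, t3 = 1L, t4 = 2L, t5 = 2L, t6 = 3L)
  activity <- c(t1 = 5, t2 = 5.5, t3 = 6, t4 = 7, t5 = 7.5, t6 = 6.25)
  prep <- structure(list(values = NULL, names = "D1",
                         scaling = data.frame(name = "D1", min = 0, max = 1),
                         dropped = character(0), params = list()),
                    class = "descriptor_prep")
  # two regions on D1 split at 0.5: y = x + 1 below, y = 3 - x above
  x <- seq(0.05, 0.95, length.out = 20)
  mod1 <- fit_oplra(cbind(D1 = x), ifelse(x < 0.5, x + 1, 3 - x), lambda = 0)
  mod2 <- fit_oplra(cbind(D1 = x[1:8]), rep(7.2, 8), lambda = 0.005)
  sizes <- table(memb)
  partition <- structure(list(membership = memb, q = NA_real_,
                              main_modules = c(1L, 2L), singletons = 3L,
                              sizes = sizes), class = "module_partition")
  structure(list(t_star = 0.3, scan = NULL, graph = NULL,
                 partition = partition,
                 submodels = list(`1` = mod1, `2` = mod2,
                                  `3` = modsar:::constant_model(6.25)),
                 prep = prep,
                 fingerprint_cfg = list(radius = 2, n_bits = n_bits),
                 lambda = 0.005, ids = rownames(fps),
                 activity = activity, fingerprints = fps),
            class = "modsar")
}

toy_query <- function(idx, n_bits = 40) {
  v <- integer(n_bits); v[idx] <- 1L
  v
}
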