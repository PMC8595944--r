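#' Threshold a bootstrap correlation matrix into a network
#'
#' Retains edges where the absolute bootstrap-median correlation meets the
#' threshold (inclusive, `|rho| >= threshold`), preserving signed weights.
#' Isolated nodes stay in the node set. Undefined entries never form edges.
#'
#' @param mat A `boot_cor_matrix` from [bootstrap_matrix()], or a plain
#'   symmetric correlation matrix with dimnames.
#' @param threshold Absolute-correlation threshold (default 0.30).
#' @return An object of class `cor_network` wrapping a signed weighted
#'   igraph graph plus (once computed) layout, module partition and
#'   centrality annotations.
#' @export
threshold_network <- function(mat, threshold = 0.30) {
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  if (inherits(mat, "boot_cor_matrix")) {
    M <- mat$median
    meta <- mat$nodes
    params <- mat$params
  } else {
    stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), !is.null(rownames(mat)))
    M <- mat
    meta <- node_metadata(rownames(mat))
    params <- list()
  }
  A <- M
  diag(A) <- 0
  A[is.na(A)] <- 0
  A[abs(A) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  igraph::V(g)$type <- meta$type
  igraph::V(g)$band <- meta$band
  igraph::V(g)$channel <- meta$channel
  igraph::V(g)$measure <- meta$measure
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$abs_weight <- abs(igraph::E(g)$weight)
  }
  structure(
    list(graph = g, nodes = meta, threshold = threshold, params = params,
         layout = NULL, modules = NULL, Q = NULL, centrality = NULL),
    class = "cor_network"
  )
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("<cor_network> %d nodes, %d edges (|rho| >= %.2f)%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold,
              if (!is.null(x$Q)) sprintf(", %d modules, Q = %.3f",
                                         length(unique(x$modules)), x$Q) else ""))
  invisible(x)
}

#' Fruchterman--Reingold layout for a correlation network
#'
#' Force-directed embedding with edge attraction proportional to the
#' absolute correlation, run for a fixed number of iterations; deterministic
#' under a seed. A single node is placed at the origin.
#'
#' @param net A `cor_network`.
#' @param iterations Number of iterations (default 500).
#' @param seed Integer seed.
#' @return The network with `$layout` set (matrix n x 2, rownames = nodes).
#' @export
layout_fruchterman_reingold <- function(net, iterations = 500, seed = NULL) {
  stopifnot(inherits(net, "cor_network"))
  n <- igraph::vcount(net$graph)
  if (n == 0) abort_field("net", "needs >= 1 node")
  if (n == 1) {
    xy <- matrix(0, 1, 2)
  } else {
    w <- if (igraph::ecount(net$graph) > 0) igraph::E(net$graph)$abs_weight else NULL
    xy <- with_seed(seed, igraph::layout_with_fr(net$graph, niter = iterations, weights = w))
  }
  rownames(xy) <- net$nodes$node
  colnames(xy) <- c("x", "y")
  net$layout <- xy
  net
}

#' Newman modularity partition (greedy agglomeration + refinement)
#'
#' Maximizes weighted Newman modularity on the absolute edge weights of the
#' thresholded network: negative and positive correlations contribute
#' connection strength equally (the signed network is preserved for
#' display). The search is greedy agglomeration from singletons (merging the
#' community pair with the largest modularity gain) followed by
#' Kernighan--Lin-style single-node moves until no move improves Q. With an
#' empty edge set every node is its own module and Q is defined as 0.
#'
#' @param net A `cor_network`, or a base adjacency matrix of nonnegative
#'   weights.
#' @return For a network: the network with `$modules` (integer labels, named
#'   by node) and `$Q` set. For a matrix: `list(modules, Q)`.
#' @export
modularity_partition <- function(net) {
  if (inherits(net, "cor_network")) {
    A <- abs_adjacency(net)
    res <- newman_partition(A)
    net$modules <- setNames(res$modules, net$nodes$node)
    net$Q <- res$Q
    return(net)
  }
  stopifnot(is.matrix(net))
  newman_partition(abs(net))
}

abs_adjacency <- function(net) {
  A <- igraph::as_adjacency_matrix(net$graph, attr = if (igraph::ecount(net$graph) > 0) "weight" else NULL,
                                   sparse = FALSE)
  abs(A)
}

# weighted Newman modularity of a partition (A: symmetric nonnegative matrix)
modularity_value <- function(A, membership) {
  m2 <- sum(A)
  if (m2 <= 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

newman_partition <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  if (n == 0) return(list(modules = integer(0), Q = 0))
  if (sum(A) <= 0) return(list(modules = seq_len(n), Q = 0))
  m2 <- sum(A)
  k <- rowSums(A)

  # --- greedy agglomeration (CNM): track the best partition along the path
  memb <- seq_len(n)
  # community-level aggregates
  e <- A / m2                       # pairwise community connection fractions
  a <- k / m2
  active <- rep(TRUE, n)
  best_memb <- memb
  best_q <- modularity_value(A, memb)
  q <- best_q
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    # gain of merging communities i, j: 2 (e_ij - a_i a_j)
    gain <- 2 * (e[act, act, drop = FALSE] - outer(a[act], a[act]))
    diag(gain) <- -Inf
    gmax <- max(gain)
    if (gmax <= 1e-15) break
    ij <- which(gain == gmax, arr.ind = TRUE)[1, ]
    i <- act[ij[1]]; j <- act[ij[2]]
    # merge j into i
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    memb[memb == j] <- i
    q <- q + gmax
    if (q > best_q + 1e-15) {
      best_q <- q
      best_memb <- memb
    }
  }

  # --- Kernighan-Lin-style refinement: full passes of locked single-node
  # moves (the best available move is applied even when its gain is negative,
  # each node moves at most once per pass) and the best intermediate state of
  # the pass is kept; repeated while a pass improves Q
  memb <- relabel(best_memb)
  q <- modularity_value(A, memb)
  repeat {
    res <- kl_pass(A, memb, q, k, m2)
    if (res$q > q + 1e-12) {
      memb <- relabel(res$memb)
      q <- modularity_value(A, memb)
    } else {
      break
    }
  }
  list(modules = relabel(memb), Q = modularity_value(A, memb))
}

# gain of moving node v from its community to each community label in `cands`
# (labels absent from memb denote a fresh singleton community)
move_gains <- function(A, memb, k, m2, v, cands) {
  kv_to <- rowsum(A[v, ], memb)                 # weight from v into each community
  kv <- k[v]
  K <- rowsum(k, memb)
  a <- memb[v]
  kva <- kv_to[as.character(a), 1]              # v's links into its own community
  Ka <- K[as.character(a), 1]
  vapply(cands, function(b) {
    kvb <- if (as.character(b) %in% rownames(kv_to)) kv_to[as.character(b), 1] else 0
    Kb <- if (as.character(b) %in% rownames(K)) K[as.character(b), 1] else 0
    2 * (kvb - kva) / m2 - 2 * kv * (Kb - Ka + kv) / m2^2
  }, numeric(1))
}

kl_pass <- function(A, memb, q, k, m2) {
  n <- nrow(A)
  locked <- rep(FALSE, n)
  cur <- memb
  cur_q <- q
  best_memb <- memb
  best_q <- q
  for (step in seq_len(n)) {
    best_gain <- -Inf
    best_v <- NA_integer_
    best_c <- NA_integer_
    free <- max(cur) + 1L
    for (v in which(!locked)) {
      cands <- setdiff(unique(c(cur, free)), cur[v])
      g <- move_gains(A, cur, k, m2, v, cands)
      j <- which.max(g)
      if (g[j] > best_gain) {
        best_gain <- g[j]
        best_v <- v
        best_c <- cands[j]
      }
    }
    if (!is.finite(best_gain)) break
    cur[best_v] <- best_c
    cur_q <- cur_q + best_gain
    locked[best_v] <- TRUE
    if (cur_q > best_q + 1e-12) {
      best_q <- cur_q
      best_memb <- cur
    }
  }
  list(memb = best_memb, q = best_q)
}

relabel <- function(memb) as.integer(factor(memb, levels = unique(memb)))

#' Node centrality measures
#'
#' Strength (sum of incident absolute weights), closeness and betweenness on
#' shortest-path distances `1/|rho|`. Closeness follows the
#' disconnected-network convention: for node `i` reaching `r` other nodes,
#' `closeness = (r / (n-1)) * (r / sum of distances to reached nodes)`;
#' an isolated node gets closeness 0 (and strength and betweenness 0).
#'
#' @param net A `cor_network`.
#' @return The network with `$centrality` set to a tibble with columns
#'   `node`, `strength`, `closeness`, `betweenness`.
#' @export
centrality_measures <- function(net) {
  stopifnot(inherits(net, "cor_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  has_edges <- igraph::ecount(g) > 0
  stren <- if (has_edges) igraph::strength(g, weights = igraph::E(g)$abs_weight) else rep(0, n)
  if (has_edges) {
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$abs_weight)
    btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$abs_weight)
  } else {
    d <- matrix(Inf, n, n); diag(d) <- 0
    btw <- rep(0, n)
  }
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    r <- sum(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(di[reach]))
  }, numeric(1))
  net$centrality <- tibble::tibble(node = net$nodes$node,
                                   strength = unname(stren),
                                   closeness = clo,
                                   betweenness = unname(btw))
  net
}

#' Annotate a network with layout, modules and centrality in one call
#'
#' @param net A `cor_network`.
#' @param iterations Layout iterations (default 500).
#' @param seed Layout seed.
#' @return The fully annotated network.
#' @export
annotate_network <- function(net, iterations = 500, seed = NULL) {
  net %>%
    layout_fruchterman_reingold(iterations = iterations, seed = seed) %>%
    modularity_partition() %>%
    centrality_measures()
}

#' Tidy a correlation network
#'
#' @param x A `cor_network`.
#' @param ... Unused.
#' @return A tibble of edges: `from`, `to`, `weight`, `abs_weight`, `sign`.
#' @method tidy cor_network
#' @export
tidy.cor_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric(), abs_weight = numeric(),
                          sign = character()))
  }
  el <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::tibble(from = el$from, to = el$to, weight = el$weight,
                 abs_weight = abs(el$weight),
                 sign = ifelse(el$weight >= 0, "positive", "negative"))
}

#' One-row network summary
#'
#' @param x A `cor_network`.
#' @param ... Unused.
#' @return A tibble with node/edge counts, density, module count and Q.
#' @method glance cor_network
#' @export
glance.cor_network <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  m <- igraph::ecount(x$graph)
  tibble::tibble(
    group = x$params$group %||% NA_character_,
    measure = x$params$measure %||% NA_character_,
    n_nodes = n, n_edges = m,
    density = if (n > 1) m / (n * (n - 1) / 2) else NA_real_,
    threshold = x$threshold,
    n_modules = if (!is.null(x$modules)) length(unique(x$modules)) else NA_integer_,
    Q = x$Q %||% NA_real_
  )
}

#' Tidy the node table of a network
#'
#' @param net An annotated `cor_network`.
#' @return A tibble with node metadata plus (where computed) layout
#'   coordinates, module labels and centrality.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "cor_network"))
  out <- net$nodes
  if (!is.null(net$layout)) {
    out$x <- net$layout[, 1]; out$y <- net$layout[, 2]
  }
  if (!is.null(net$modules)) out$module <- unname(net$modules[out$node])
  if (!is.null(net$centrality)) out <- dplyr::left_join(out, net$centrality, by = "node")
  out
}
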