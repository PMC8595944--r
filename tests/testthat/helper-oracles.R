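# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: exhaustive enumeration for modularity and Mann-Whitney,
# the recursive partial-correlation identity for partial Spearman.

# all set partitions of n elements as membership vectors (restricted growth)
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, next_label) {
    k <- length(memb)
    if (k == n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(memb, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# exhaustive maximum weighted modularity via igraph's Q (independent of the
# package's greedy search and of its Q implementation)
exhaustive_modularity <- function(A) {
  A <- abs(A)
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  w <- igraph::E(g)$weight
  best <- -Inf
  best_memb <- NULL
  for (memb in enumerate_partitions(nrow(A))) {
    q <- igraph::modularity(g, memb, weights = w)
    if (q > best) {
      best <- q
      best_memb <- memb
    }
  }
  list(Q = best, modules = best_memb)
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
# of the pooled (tie-free) sample
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# recursive partial-correlation formula applied to the Spearman matrix
recursive_partial_spearman <- function(x, y, Z) {
  M <- cbind(x = x, y = y, Z)
  S <- stats::cor(apply(M, 2, rank))
  drop_one <- function(S, z) {
    keep <- setdiff(rownames(S), z)
    out <- S[keep, keep, drop = FALSE]
    for (a in keep) for (b in keep) {
      out[a, b] <- (S[a, b] - S[a, z] * S[b, z]) /
        sqrt((1 - S[a, z]^2) * (1 - S[b, z]^2))
    }
    out
  }
  covs <- setdiff(colnames(S), c("x", "y"))
  for (z in covs) S <- drop_one(S, z)
  S["x", "y"]
}

# feature-table scaffold with planted node columns, covariates and ids
make_feature_table <- function(values, group = "g1", age = NULL, sex = NULL) {
  n <- nrow(values)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    age = age %||% seq(5, 9, length.out = n),
    sex = sex %||% rep(c(0, 1), length.out = n)
  ) %>% dplyr::bind_cols(tibble::as_tibble(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
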