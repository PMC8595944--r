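# correlation-network estimation: partial Spearman, bootstrap, threshold,
# layout, modularity, centrality, radar summaries

test_that("partial Spearman handles monotone, confounded and degenerate input", {
  x <- c(1, 3, 4, 7, 10, 15)
  expect_equal(partial_spearman(x, x^3, data.frame(z = rep(1, 6))), 1.0)

  set.seed(31)
  n <- 200
  age <- runif(n, 5, 9)
  x <- 2 * age + rnorm(n, sd = 0.5)
  y <- -3 * age + rnorm(n, sd = 0.8)
  expect_gt(abs(cor(x, y, method = "spearman")), 0.4)
  expect_lt(abs(partial_spearman(x, y, data.frame(age))), 0.15)

  expect_identical(partial_spearman(rep(2, 10), rnorm(10)), NA_real_)
  expect_error(partial_spearman(1:3, 3:1), ">= 4")
})

test_that("partial Spearman matches the recursive-formula oracle", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 6 + rep
    x <- rnorm(n); y <- rnorm(n)
    Z <- cbind(z1 = rnorm(n), z2 = rnorm(n))
    expect_equal(partial_spearman(x, y, Z),
                 recursive_partial_spearman(x, y, Z), tolerance = 1e-6)
  }
})

test_that("bootstrap matrix honors exact dependence, determinism and bounds", {
  set.seed(33)
  n <- 30
  v1 <- rnorm(n)
  tbl <- make_feature_table(cbind(a = v1, b = 2 * v1 + 5, c = rnorm(n)))
  bm <- bootstrap_matrix(tbl, nodes = c("a", "b", "c"), covariates = NULL,
                         n_boot = 200, n_subsample = 20, seed = 1)
  expect_equal(bm$median["a", "b"], 1.0)
  expect_equal(bm$p2_5["a", "b"], 1.0)
  expect_equal(bm$p97_5["a", "b"], 1.0)
  expect_true(all(bm$p2_5 <= bm$median + 1e-12))
  expect_true(all(bm$median <= bm$p97_5 + 1e-12))
  expect_true(all(abs(bm$median) <= 1))

  bm2 <- bootstrap_matrix(tbl, nodes = c("a", "b", "c"), covariates = NULL,
                          n_boot = 200, n_subsample = 20, seed = 1)
  expect_identical(bm$median, bm2$median)
})

test_that("bootstrap recovery of a planted Spearman correlation", {
  mp <- dplyr::bind_rows(lapply(c("controls", "mild", "mod_severe"), function(g) {
    tibble::tibble(group = g, variable = c("V1", "V2"), dist = "norm",
                   median = 10, q1 = 8, q3 = 12, lower = -Inf, upper = Inf)
  }))
  R <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("V1", "V2"), c("V1", "V2")))
  co <- synthesize_cohort(cohort_synthesis_spec(
    group_sizes = c(20, 0, 0), marginal_params = mp, latent_correlation = R,
    seed = 41))
  co$sex <- as.integer(co$sex == "M")
  bm <- bootstrap_matrix(co, group = "controls", nodes = c("V1", "V2"),
                         n_boot = 1000, n_subsample = 20, seed = 42)
  expect_lte(abs(bm$median["V1", "V2"] - 0.6), 0.15)
  expect_gte(bm$median["V1", "V2"], bm$p2_5["V1", "V2"])
  expect_lte(bm$median["V1", "V2"], bm$p97_5["V1", "V2"])
})

test_that("entries undefined in many runs are excluded and flagged", {
  set.seed(34)
  n <- 25
  vals <- cbind(a = rnorm(n), b = rnorm(n), c = c(1, rep(0, n - 1)))
  tbl <- make_feature_table(vals)
  bm <- bootstrap_matrix(tbl, nodes = c("a", "b", "c"), covariates = NULL,
                         n_boot = 100, n_subsample = 10, seed = 2)
  # column c is constant in most draws -> low valid-run counts
  expect_lt(bm$n_valid["a", "c"], 100)
  e <- tidy(bm)
  expect_true(any(e$flagged[e$to == "c" | e$from == "c"]))
  expect_equal(bm$n_valid["a", "b"], 100)
})

test_that("thresholding is inclusive at the boundary and keeps isolated nodes", {
  M <- diag(4)
  dimnames(M) <- list(letters[1:4], letters[1:4])
  M[1, 2] <- M[2, 1] <- 0.29
  M[1, 3] <- M[3, 1] <- 0.30
  M[2, 4] <- M[4, 2] <- -0.31
  net <- threshold_network(M, threshold = 0.30)
  e <- tidy(net)
  expect_equal(nrow(e), 2)
  expect_setequal(round(e$weight, 2), c(0.30, -0.31))
  expect_equal(igraph::vcount(net$graph), 4)

  empty <- threshold_network(`dimnames<-`(diag(5), list(letters[1:5], letters[1:5])))
  expect_equal(igraph::ecount(empty$graph), 0)
  expect_equal(igraph::vcount(empty$graph), 5)

  full <- matrix(1, 6, 6); dimnames(full) <- list(letters[1:6], letters[1:6])
  expect_equal(igraph::ecount(threshold_network(full)$graph), 15)
})

test_that("layout is deterministic, finite, and pulls linked nodes together", {
  M <- diag(6); dimnames(M) <- list(letters[1:6], letters[1:6])
  M[1, 2] <- M[2, 1] <- 0.9
  net <- threshold_network(M)
  l1 <- layout_fruchterman_reingold(net, seed = 5)$layout
  l2 <- layout_fruchterman_reingold(net, seed = 5)$layout
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1)))

  # the only edge (a, b): over seeds, that pair sits closer than the mean
  # distance of non-adjacent pairs
  closer <- vapply(1:10, function(s) {
    xy <- layout_fruchterman_reingold(net, seed = s)$layout
    d <- as.matrix(dist(xy))
    d["a", "b"] < mean(d[upper.tri(d)][d[upper.tri(d)] > 0])
  }, logical(1))
  expect_gte(mean(closer), 0.9)

  single <- threshold_network(matrix(1, 1, 1, dimnames = list("a", "a")))
  expect_equal(unname(layout_fruchterman_reingold(single)$layout), matrix(0, 1, 2))
})

test_that("greedy modularity matches exhaustive search on small graphs", {
  graphs <- list()
  # two disconnected unit triangles
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- A[4, 5] <- A[5, 6] <- A[4, 6] <- 1
  graphs$triangles <- A + t(A)
  # complete graph with uniform weights
  graphs$complete <- matrix(1, 5, 5) - diag(5)
  # path
  P <- matrix(0, 6, 6); for (i in 1:5) P[i, i + 1] <- 1
  graphs$path <- P + t(P)
  # random weighted graphs
  set.seed(35)
  for (k in 1:3) {
    n <- sample(5:8, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2) * (runif(n * (n - 1) / 2) < 0.6)
    graphs[[paste0("rand", k)]] <- W + t(W)
  }
  for (nm in names(graphs)) {
    A <- graphs[[nm]]
    res <- modularity_partition(A)
    oracle <- exhaustive_modularity(A)
    expect_lt(abs(res$Q - oracle$Q), 1e-9)
  }
  # known exact values
  expect_equal(modularity_partition(graphs$triangles)$Q, 0.5)
  expect_equal(modularity_partition(graphs$complete)$Q, 0)
})

test_that("modularity Q agrees with the igraph reference on the found partition", {
  set.seed(36)
  A <- matrix(0, 10, 10)
  A[upper.tri(A)] <- runif(45) * (runif(45) < 0.4)
  A <- A + t(A)
  res <- modularity_partition(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  q_ref <- igraph::modularity(g, res$modules, weights = igraph::E(g)$weight)
  expect_equal(res$Q, q_ref, tolerance = 1e-12)
})

test_that("empty edge set yields singleton modules with Q = 0", {
  net <- threshold_network(`dimnames<-`(diag(4), list(letters[1:4], letters[1:4])))
  net <- modularity_partition(net)
  expect_equal(net$Q, 0)
  expect_equal(length(unique(net$modules)), 4)
})

test_that("a planted two-block correlation structure is recovered exactly", {
  vars <- paste0("V", 1:8)
  R <- diag(8); dimnames(R) <- list(vars, vars)
  blocks <- list(1:4, 5:8)
  for (b in blocks) for (i in b) for (j in b) if (i != j) R[i, j] <- 0.7
  R[1:4, 5:8] <- 0.05; R[5:8, 1:4] <- 0.05
  mp <- dplyr::bind_rows(lapply(c("controls", "mild", "mod_severe"), function(g) {
    tibble::tibble(group = g, variable = vars, dist = "norm",
                   median = 0, q1 = -1, q3 = 1, lower = -Inf, upper = Inf)
  }))
  co <- synthesize_cohort(cohort_synthesis_spec(
    group_sizes = c(200, 0, 0), marginal_params = mp, latent_correlation = R,
    seed = 43))
  co$sex <- as.integer(co$sex == "M")
  bm <- bootstrap_matrix(co, group = "controls", nodes = vars,
                         n_boot = 200, n_subsample = 100, seed = 44)
  net <- modularity_partition(threshold_network(bm, 0.30))
  truth <- rep(1:2, each = 4)
  expect_equal(mclust::adjustedRandIndex(net$modules, truth), 1)
})

test_that("modularity declines as between-block correlation grows", {
  vars <- paste0("V", 1:8)
  mp <- dplyr::bind_rows(lapply(c("controls", "mild", "mod_severe"), function(g) {
    tibble::tibble(group = g, variable = vars, dist = "norm",
                   median = 0, q1 = -1, q3 = 1, lower = -Inf, upper = Inf)
  }))
  qs <- vapply(c(0.05, 0.5), function(between) {
    R <- diag(8); dimnames(R) <- list(vars, vars)
    for (b in list(1:4, 5:8)) for (i in b) for (j in b) if (i != j) R[i, j] <- 0.7
    R[1:4, 5:8] <- between; R[5:8, 1:4] <- between
    co <- synthesize_cohort(cohort_synthesis_spec(
      group_sizes = c(200, 0, 0), marginal_params = mp, latent_correlation = R,
      seed = 45))
    co$sex <- as.integer(co$sex == "M")
    bm <- bootstrap_matrix(co, group = "controls", nodes = vars,
                           n_boot = 200, n_subsample = 100, seed = 46)
    modularity_partition(threshold_network(bm, 0.30))$Q
  }, numeric(1))
  expect_lte(qs[2], qs[1])
})

test_that("bootstrap null calibration: few spurious edges among non-EEG pairs", {
  vars <- c(psg_variables(), cognitive_variables())
  co <- synthesize_cohort(cohort_synthesis_spec(
    group_sizes = c(100, 0, 0),
    latent_correlation = `dimnames<-`(diag(12), list(vars, vars)),
    seed = 47))
  co$sex <- as.integer(co$sex == "M")
  frac <- vapply(1:20, function(s) {
    bm <- bootstrap_matrix(co, group = "controls", nodes = vars,
                           n_boot = 200, n_subsample = 20, seed = 1000 + s)
    e <- tidy(bm)
    mean(abs(e$median) >= 0.30, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(frac), 0.10)
})

test_that("centrality follows the shortest-path conventions", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  dimnames(path3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- centrality_measures(threshold_network(path3, 0.5))
  cen <- net$centrality
  expect_equal(cen$betweenness[cen$node == "b"], 1)
  expect_equal(cen$betweenness[cen$node != "b"], c(0, 0))

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  dimnames(star) <- list(letters[1:6], letters[1:6])
  hub <- centrality_measures(threshold_network(star, 0.5))$centrality
  expect_equal(hub$strength[hub$node == "a"], 5)

  iso <- diag(3); iso[1, 2] <- iso[2, 1] <- 0.8
  dimnames(iso) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cen <- centrality_measures(threshold_network(iso))$centrality
  expect_equal(cen$strength[cen$node == "c"], 0)
  expect_equal(cen$closeness[cen$node == "c"], 0)
  expect_equal(cen$betweenness[cen$node == "c"], 0)
})

test_that("radar summaries average absolute correlations as specified", {
  channels <- c("F3", "F4", "C3", "C4")
  eeg <- paste0("rp_theta_", channels)
  nodes <- c(eeg, "AHI", "AR", "DAS")
  M <- diag(length(nodes)); dimnames(M) <- list(nodes, nodes)
  M[eeg, c("AHI", "AR")] <- 0.31
  M[c("AHI", "AR"), eeg] <- 0.31
  M[eeg, "DAS"] <- c(0.1, 0.2, -0.3, 0.4)
  M["DAS", eeg] <- c(0.1, 0.2, -0.3, 0.4)
  M["AHI", "DAS"] <- M["DAS", "AHI"] <- -0.5
  M["AR", "DAS"] <- M["DAS", "AR"] <- 0.2
  bm <- structure(list(median = M, p2_5 = M, p97_5 = M,
                       n_valid = matrix(10, length(nodes), length(nodes)),
                       nodes = osanet:::node_metadata(nodes),
                       params = list(measure = "rp", n_boot = 10)),
                  class = "boot_cor_matrix")
  rs <- radar_summary(bm)
  theta_psg <- rs$mean_abs_rho[rs$panel == "eeg_vs_psg" & rs$axis == "theta"]
  expect_equal(theta_psg, c(0.31, 0.31))
  theta_das <- rs$mean_abs_rho[rs$panel == "eeg_vs_cognitive" & rs$target == "DAS"]
  expect_equal(theta_das, mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(rs$mean_abs_rho[rs$panel == "psg_vs_cognitive" & rs$axis == "AHI"], 0.5)
  expect_equal(rs$mean_abs_rho[rs$panel == "cognitive_vs_psg" & rs$axis == "DAS"],
               mean(c(0.5, 0.2)))

  bm0 <- bm
  bm0$median <- `dimnames<-`(diag(length(nodes)), list(nodes, nodes))
  rs0 <- radar_summary(bm0)  # identity matrix: every off-diagonal block is 0
  expect_true(all(rs0$mean_abs_rho == 0))
})

test_that("bootstrap output is invariant to subject row order", {
  set.seed(37)
  n <- 40
  tbl <- make_feature_table(cbind(a = rnorm(n), b = rnorm(n)))
  shuffled <- tbl[sample(n), ]
  b1 <- bootstrap_matrix(tbl, nodes = c("a", "b"), covariates = NULL,
                         n_boot = 100, n_subsample = 15, seed = 3)
  b2 <- bootstrap_matrix(shuffled, nodes = c("a", "b"), covariates = NULL,
                         n_boot = 100, n_subsample = 15, seed = 3)
  expect_identical(b1$median, b2$median)
})
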