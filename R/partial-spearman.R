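#' Partial Spearman correlation adjusted for covariates
#'
#' All variables (including covariates) are rank-transformed with midranks;
#' the covariate effects are removed from both ranked `x` and ranked `y` by
#' least squares (with intercept), and the Pearson correlation of the
#' residuals is returned. With no covariates this reduces to the ordinary
#' Spearman correlation. Constant covariates are dropped; if `x` or `y` is
#' constant after ranking the correlation is undefined and `NA` is returned
#' (a signal distinct from an error).
#'
#' @param x,y Numeric vectors of equal length (n >= 4 complete observations).
#' @param covariates Optional data frame / matrix of covariates (e.g. age in
#'   years and sex coded 0/1); factors and characters are converted to
#'   numeric codes before ranking.
#' @return A single correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
#' @examples
#' set.seed(1)
#' age <- runif(50, 5, 9)
#' x <- age + rnorm(50, sd = 0.1); y <- 2 * age + rnorm(50, sd = 0.1)
#' cor(x, y, method = "spearman")            # confounded: near 1
#' partial_spearman(x, y, data.frame(age))   # adjusted: near 0
partial_spearman <- function(x, y, covariates = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  Z <- covariates_matrix(covariates, length(x))
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]
  if (!is.null(Z)) Z <- Z[ok, , drop = FALSE]
  if (length(x) < 4) rlang::abort("partial_spearman needs >= 4 complete observations")
  R <- rank_residuals(cbind(x, y), Z)
  safe_cor(R[, 1], R[, 2])
}

covariates_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    covariates <- vapply(covariates, function(col) {
      if (is.numeric(col)) col else as.numeric(as.factor(col))
    }, numeric(nrow(covariates)))
    covariates <- matrix(covariates, nrow = n)
  }
  Z <- as.matrix(covariates)
  if (nrow(Z) != n) abort_field("covariates", "must have one row per observation")
  Z
}

# midrank-transform columns of M, residualize on ranked covariates Z
rank_residuals <- function(M, Z) {
  Rm <- apply(M, 2, rank)
  if (is.null(Z) || ncol(Z) == 0) return(scale(Rm, center = TRUE, scale = FALSE))
  Rz <- apply(Z, 2, rank)
  keep <- apply(Rz, 2, function(v) max(v) > min(v))   # drop constant covariates
  X <- cbind(1, Rz[, keep, drop = FALSE])
  qr.resid(qr(X), Rm)
}

safe_cor <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa < 1e-12 || sb < 1e-12) return(NA_real_)
  min(1, max(-1, cor(a, b)))
}

#' Bootstrap partial Spearman correlation matrix
#'
#' Builds the node x node correlation matrix for one severity group and one
#' EEG measure the way the group networks are estimated: `n_boot` bootstrap
#' runs each draw `n_subsample` subjects with replacement (uniform
#' probability) from the group; within each run every pairwise partial
#' Spearman correlation (adjusted for the covariates, ranked within the run)
#' is computed; and per entry the median and the 2.5/97.5 percentiles over
#' the runs with a defined value are retained. Resampling a fixed-size
#' subsample per run equalizes the effective n across groups of very
#' different sizes.
#'
#' Entries undefined in a run (a variable constant in that draw) are
#' excluded from the aggregation; per-entry valid-run counts are kept, and
#' entries defined in fewer than half the runs are flagged. Subjects are
#' canonically ordered by id before resampling, so row order does not affect
#' results under a fixed seed.
#'
#' @param features Feature table from [build_feature_table()] (or any tibble
#'   with the node and covariate columns).
#' @param group Severity group label to subset on (`NULL` uses all rows).
#' @param measure `"rp"` or `"specen"`; selects the 64 EEG nodes of that
#'   measure. Ignored when `nodes` is given.
#' @param nodes Optional explicit character vector of node columns.
#' @param covariates Covariate column names (default `c("age", "sex")`).
#' @param n_boot Number of bootstrap runs (default 1000).
#' @param n_subsample Subjects drawn per run (default 20).
#' @param seed Integer seed for reproducible resampling.
#' @return An object of class `boot_cor_matrix` with elements `median`,
#'   `p2_5`, `p97_5`, `n_valid`, `nodes` (metadata tibble), and `params`.
#' @export
bootstrap_matrix <- function(features, group = NULL, measure = c("rp", "specen"),
                             nodes = NULL, covariates = c("age", "sex"),
                             n_boot = 1000, n_subsample = 20, seed = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(features))
  if (!is.null(group)) {
    features <- features[as.character(features$group) == as.character(group), , drop = FALSE]
  }
  if (nrow(features) < 2) abort_field("group", "needs >= 2 subjects")
  if ("subject_id" %in% names(features)) {
    features <- features[order(features$subject_id), , drop = FALSE]
  }
  if (is.null(nodes)) {
    eeg_nodes <- eeg_feature_columns(features, measure)
    noneeg <- intersect(c(psg_variables(), cognitive_variables()), names(features))
    nodes <- c(eeg_nodes, noneeg)
  }
  missing <- setdiff(c(nodes, covariates), names(features))
  if (length(missing) > 0) {
    abort_field("nodes", sprintf("column(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(dplyr::mutate(features[, nodes, drop = FALSE],
                               dplyr::across(dplyr::everything(), as.numeric)))
  Z <- if (length(covariates) > 0) {
    covariates_matrix(features[, covariates, drop = FALSE], nrow(features))
  } else NULL
  p <- length(nodes)
  n <- nrow(X)

  draws <- array(NA_real_, dim = c(p, p, n_boot))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n_subsample, replace = TRUE)
      R <- rank_residuals(X[idx, , drop = FALSE],
                          if (is.null(Z)) NULL else Z[idx, , drop = FALSE])
      sds <- apply(R, 2, sd)
      ok <- is.finite(sds) & sds > 1e-12
      if (!any(ok)) next
      C <- suppressWarnings(cor(R[, ok, drop = FALSE]))
      C[!is.finite(C)] <- NA_real_
      full <- matrix(NA_real_, p, p)
      full[ok, ok] <- pmin(1, pmax(-1, C))
      draws[, , b] <- full
    }
  })
  med <- apply(draws, c(1, 2), median, na.rm = TRUE)
  p2_5 <- apply(draws, c(1, 2), quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
  p97_5 <- apply(draws, c(1, 2), quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  n_valid <- apply(!is.na(draws), c(1, 2), sum)
  med[n_valid == 0] <- NA_real_
  diag(med) <- 1; diag(p2_5) <- 1; diag(p97_5) <- 1
  dimnames(med) <- dimnames(p2_5) <- dimnames(p97_5) <- dimnames(n_valid) <- list(nodes, nodes)

  meta <- node_metadata(nodes)
  structure(
    list(median = med, p2_5 = p2_5, p97_5 = p97_5, n_valid = n_valid,
         nodes = meta,
         params = list(group = group, measure = measure, n_boot = n_boot,
                       n_subsample = n_subsample, seed = seed,
                       n_subjects = n, covariates = covariates)),
    class = "boot_cor_matrix"
  )
}

node_metadata <- function(nodes) {
  is_eeg <- grepl("^(rp|specen)_", nodes)
  meta <- tibble::tibble(node = nodes,
                         type = dplyr::case_when(
                           is_eeg ~ "eeg",
                           nodes %in% psg_variables() ~ "psg",
                           nodes %in% cognitive_variables() ~ "cognitive",
                           TRUE ~ "other"),
                         measure = NA_character_, band = NA_character_,
                         channel = NA_character_)
  if (any(is_eeg)) {
    pf <- parse_feature_names(nodes[is_eeg])
    meta$measure[is_eeg] <- pf$measure
    meta$band[is_eeg] <- pf$band
    meta$channel[is_eeg] <- pf$channel
  }
  meta
}

#' @export
print.boot_cor_matrix <- function(x, ...) {
  p <- x$params
  cat(sprintf("<boot_cor_matrix> %d nodes | group %s, measure %s | %d runs of %d subjects (of %d)\n",
              nrow(x$median), p$group %||% "(all)", p$measure, p$n_boot, p$n_subsample,
              p$n_subjects))
  flagged <- sum(x$n_valid[upper.tri(x$n_valid)] < p$n_boot / 2)
  if (flagged > 0) cat(sprintf("  %d entr%s defined in < 50%% of runs\n",
                               flagged, ifelse(flagged == 1, "y", "ies")))
  invisible(x)
}

#' Tidy a bootstrap correlation matrix into an edge list
#'
#' @param x A `boot_cor_matrix`.
#' @param ... Unused.
#' @return A tibble of unordered node pairs with `median`, `p2_5`, `p97_5`,
#'   `n_valid`, and a `flagged` column marking entries defined in fewer than
#'   half the bootstrap runs.
#' @method tidy boot_cor_matrix
#' @export
tidy.boot_cor_matrix <- function(x, ...) {
  nodes <- rownames(x$median)
  ut <- which(upper.tri(x$median), arr.ind = TRUE)
  tibble::tibble(
    from = nodes[ut[, 1]], to = nodes[ut[, 2]],
    median = x$median[ut], p2_5 = x$p2_5[ut], p97_5 = x$p97_5[ut],
    n_valid = x$n_valid[ut],
    flagged = x$n_valid[ut] < x$params$n_boot / 2
  )
}

#' @method glance boot_cor_matrix
#' @export
glance.boot_cor_matrix <- function(x, ...) {
  e <- tidy(x)
  tibble::tibble(
    group = x$params$group %||% NA_character_, measure = x$params$measure,
    n_nodes = nrow(x$median), n_boot = x$params$n_boot,
    n_subsample = x$params$n_subsample, n_subjects = x$params$n_subjects,
    median_abs_rho = median(abs(e$median), na.rm = TRUE),
    frac_above_0_30 = mean(abs(e$median) >= 0.30, na.rm = TRUE),
    n_flagged = sum(e$flagged)
  )
}
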