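#' Severity group from the apnea--hypopnea index
#'
#' Standard pediatric cutoffs: AHI <= 1 event/h is a control, 1 < AHI < 5 is
#' mild, AHI >= 5 is moderate/severe.
#'
#' @param ahi Numeric vector of AHI values (events/hour, nonnegative).
#' @return Factor with levels `controls`, `mild`, `mod_severe`.
#' @export
#' @examples
#' severity_group(c(0.4, 1.5, 9.2))
severity_group <- function(ahi) {
  if (!is.numeric(ahi) || any(!is.finite(ahi))) abort_field("ahi", "must be finite numeric")
  if (any(ahi < 0)) abort_field("ahi", "must be nonnegative")
  factor(ifelse(ahi <= 1, "controls", ifelse(ahi < 5, "mild", "mod_severe")),
         levels = severity_levels())
}

#' Group-wise comparisons of cohort variables
#'
#' For every continuous variable: per-group median and interquartile range
#' plus two-sided Mann--Whitney U tests for the three pairwise comparisons
#' (controls vs mild, controls vs moderate/severe, mild vs moderate/severe;
#' exact p for small untied samples, tie-corrected normal approximation
#' otherwise). Sex is compared with Fisher's exact test on the 2x2 tables.
#' Raw p-values are flagged at p < 0.05; an optional Benjamini--Hochberg
#' correction (off by default) adjusts within each variable's three
#' comparisons.
#'
#' @param table Feature or cohort tibble with `group`, `sex` and the
#'   variables.
#' @param variables Variables to compare (default: age plus the PSG and
#'   cognitive variables present).
#' @param p_adjust Apply Benjamini--Hochberg across all comparisons
#'   (default `FALSE`, matching raw-p reporting).
#' @return A tibble, one row per variable x comparison, with columns
#'   `variable`, `test`, `comparison`, per-group summaries (`median`/`q25`/
#'   `q75` for both groups, or counts for sex), `p_value` and `significant`.
#'   Comparisons with an empty group are skipped with a reason.
#' @export
compare_groups <- function(table, variables = NULL, p_adjust = FALSE) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  if (is.null(variables)) {
    variables <- intersect(c("age", psg_variables(), cognitive_variables()), names(table))
  }
  groups <- severity_levels()
  pairs <- list(c("controls", "mild"), c("controls", "mod_severe"), c("mild", "mod_severe"))
  rows <- list()
  for (v in variables) {
    for (pr in pairs) {
      g1 <- table[[v]][as.character(table$group) == pr[1]]
      g2 <- table[[v]][as.character(table$group) == pr[2]]
      g1 <- g1[is.finite(g1)]; g2 <- g2[is.finite(g2)]
      cmp <- paste(pr, collapse = " vs ")
      if (length(g1) < 2 || length(g2) < 2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, test = "mann_whitney", comparison = cmp,
          median_1 = NA_real_, q25_1 = NA_real_, q75_1 = NA_real_,
          median_2 = NA_real_, q25_2 = NA_real_, q75_2 = NA_real_,
          p_value = NA_real_, skipped = "group with < 2 subjects")
        next
      }
      p <- suppressWarnings(wilcox.test(g1, g2, alternative = "two.sided"))$p.value
      q1 <- quantile(g1, c(0.25, 0.5, 0.75), names = FALSE)
      q2 <- quantile(g2, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, test = "mann_whitney", comparison = cmp,
        median_1 = q1[2], q25_1 = q1[1], q75_1 = q1[3],
        median_2 = q2[2], q25_2 = q2[1], q75_2 = q2[3],
        p_value = p, skipped = NA_character_)
    }
  }
  if ("sex" %in% names(table)) {
    for (pr in pairs) {
      sub <- table[as.character(table$group) %in% pr, c("group", "sex")]
      cmp <- paste(pr, collapse = " vs ")
      tab <- table(factor(as.character(sub$group), levels = pr), as.character(sub$sex))
      if (any(rowSums(tab) == 0) || ncol(tab) < 2) {
        p <- NA_real_
        skipped <- "degenerate sex table"
      } else {
        p <- fisher.test(tab)$p.value
        skipped <- NA_character_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = "sex", test = "fisher_exact", comparison = cmp,
        median_1 = NA_real_, q25_1 = NA_real_, q75_1 = NA_real_,
        median_2 = NA_real_, q25_2 = NA_real_, q75_2 = NA_real_,
        p_value = p, skipped = skipped)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust) out$p_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}

#' Cohort summary in the style of a clinical Table 1
#'
#' Per-group medians and interquartile ranges for the continuous variables
#' and sex counts, with pairwise significance letters (a: controls vs mild,
#' b: controls vs moderate/severe, c: mild vs moderate/severe).
#'
#' @inheritParams compare_groups
#' @return A tibble with one row per variable and formatted per-group
#'   summary strings plus a `signif` letter column.
#' @export
cohort_summary <- function(table, variables = NULL, p_adjust = FALSE) {
  cg <- compare_groups(table, variables = variables, p_adjust = p_adjust)
  letters_for <- c("controls vs mild" = "a", "controls vs mod_severe" = "b",
                   "mild vs mod_severe" = "c")
  fmt <- function(x) sprintf("%.2f", x)
  cont <- cg %>% dplyr::filter(.data$test == "mann_whitney")
  vars <- unique(cont$variable)
  rows <- purrr::map_dfr(vars, function(v) {
    d <- cont %>% dplyr::filter(.data$variable == v)
    per_group <- sapply(severity_levels(), function(g) {
      x <- table[[v]][as.character(table$group) == g]
      x <- x[is.finite(x)]
      if (length(x) == 0) return(NA_character_)
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%s (%s, %s)", fmt(q[2]), fmt(q[1]), fmt(q[3]))
    })
    sig <- paste(letters_for[d$comparison[d$significant & !is.na(d$significant)]],
                 collapse = ", ")
    tibble::tibble(variable = v, controls = per_group[1], mild = per_group[2],
                   mod_severe = per_group[3],
                   signif = ifelse(sig == "", "n.s.", sig))
  })
  if ("sex" %in% names(table)) {
    sexrow <- sapply(severity_levels(), function(g) {
      s <- table$sex[as.character(table$group) == g]
      sprintf("%d/%d (%.0f%%)", sum(s == "M"), sum(s == "F"),
              100 * mean(s == "M"))
    })
    dsex <- cg %>% dplyr::filter(.data$test == "fisher_exact")
    sig <- paste(letters_for[dsex$comparison[dsex$significant & !is.na(dsex$significant)]],
                 collapse = ", ")
    rows <- dplyr::bind_rows(
      tibble::tibble(variable = "sex (M/F)", controls = sexrow[1], mild = sexrow[2],
                     mod_severe = sexrow[3], signif = ifelse(sig == "", "n.s.", sig)),
      rows)
  }
  rows
}
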