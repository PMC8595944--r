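#' Default per-group marginal parameters for the synthetic cohort
#'
#' Location/scale parameters for the six PSG variables and six cognitive
#' scores in each severity group, parameterized by median and quartiles and
#' matched to published pediatric cohort summaries (e.g. controls AHI 0.40
#' (0.10, 0.60) events/h; moderate/severe AHI 9.20 (7.30, 17.20)). Positive
#' skewed rate-like variables (AHI, AR, AS, WASO) use log-normal marginals;
#' bounded or symmetric ones use (truncated) normal marginals. AHI bounds
#' enforce the severity cutoffs (<= 1, 1--5, >= 5 events/h) so group labels
#' are always consistent with the sampled AHI.
#'
#' @return A tibble with columns `group`, `variable`, `dist` ("lnorm" or
#'   "norm"), `median`, `q1`, `q3`, `lower`, `upper`.
#' @export
default_marginal_params <- function() {
  row <- function(group, variable, dist, med, q1, q3, lower = -Inf, upper = Inf) {
    tibble::tibble(group = group, variable = variable, dist = dist,
                   median = med, q1 = q1, q3 = q3, lower = lower, upper = upper)
  }
  dplyr::bind_rows(
    row("controls",   "AHI", "lnorm", 0.40, 0.10, 0.60, 0, 1),
    row("mild",       "AHI", "lnorm", 1.50, 1.20, 2.20, 1 + 1e-6, 5 - 1e-6),
    row("mod_severe", "AHI", "lnorm", 9.20, 7.30, 17.20, 5, Inf),
    row("controls",   "AR", "lnorm", 0.30, 0.05, 0.80, 0, Inf),
    row("mild",       "AR", "lnorm", 1.00, 0.40, 2.82, 0, Inf),
    row("mod_severe", "AR", "lnorm", 7.30, 4.88, 9.55, 0, Inf),
    row("controls",   "AS", "lnorm", 6.70, 4.70, 9.00, 0, Inf),
    row("mild",       "AS", "lnorm", 6.60, 4.20, 9.00, 0, Inf),
    row("mod_severe", "AS", "lnorm", 3.10, 1.52, 6.88, 0, Inf),
    row("controls",   "NadirSpO2", "norm", 94, 92, 95, 50, 100),
    row("mild",       "NadirSpO2", "norm", 91, 89, 94, 50, 100),
    row("mod_severe", "NadirSpO2", "norm", 84, 75, 87, 50, 100),
    row("controls",   "WASO", "lnorm", 45.5, 27.0, 79.5, 0, Inf),
    row("mild",       "WASO", "lnorm", 37.5, 23.3, 64.3, 0, Inf),
    row("mod_severe", "WASO", "lnorm", 41.0, 19.8, 75.4, 0, Inf),
    row("controls",   "SleepEff", "norm", 90.6, 84.03, 94.10, 40, 100),
    row("mild",       "SleepEff", "norm", 91.0, 85.23, 94.50, 40, 100),
    row("mod_severe", "SleepEff", "norm", 91.0, 85.45, 95.05, 40, 100),
    row("controls",   "DAS", "norm", 101.5, 92, 111.5),
    row("mild",       "DAS", "norm", 100.5, 86, 111.0),
    row("mod_severe", "DAS", "norm", 97.0, 85, 104.0),
    row("controls",   "PPVT3", "norm", 99, 89.5, 110.0),
    row("mild",       "PPVT3", "norm", 98, 89.8, 109.3),
    row("mod_severe", "PPVT3", "norm", 96, 88.25, 101.5),
    row("controls",   "EVT", "norm", 100.0, 89.3, 108),
    row("mild",       "EVT", "norm", 97.0, 85.5, 105),
    row("mod_severe", "EVT", "norm", 96.5, 91.0, 99),
    row("controls",   "DesCop", "norm", 11, 8.0, 13),
    row("mild",       "DesCop", "norm", 10, 7.0, 12),
    row("mod_severe", "DesCop", "norm", 9, 7.5, 11),
    row("controls",   "PhPro", "norm", 10.0, 8.0, 12),
    row("mild",       "PhPro", "norm", 9.0, 8.0, 13),
    row("mod_severe", "PhPro", "norm", 7.5, 5.5, 10),
    row("controls",   "Tow", "norm", 12.0, 10, 14.0),
    row("mild",       "Tow", "norm", 11.0, 9, 14.0),
    row("mod_severe", "Tow", "norm", 9.5, 7, 11.5)
  )
}

#' Default latent Spearman correlation over the cohort variables
#'
#' A modest, clinically plausible dependence preset used when no explicit
#' structure is planted: AHI correlates with the respiratory arousal index
#' (+0.6) and oxygen nadir (-0.5), arousals with the nadir (-0.35) and
#' spontaneous arousals weakly negatively with AHI; WASO and sleep efficiency
#' oppose each other (-0.5); cognitive scores inter-correlate (+0.4) and
#' decline weakly with disease burden (AHI -0.25, AR -0.2). Magnitudes are
#' free parameters of the generator, not estimates.
#'
#' @param variables Variable names; defaults to the 12 PSG + cognitive
#'   variables.
#' @return Symmetric unit-diagonal positive-definite matrix of Spearman
#'   targets.
#' @export
default_latent_correlation <- function(variables = c(psg_variables(), cognitive_variables())) {
  p <- length(variables)
  R <- diag(p)
  dimnames(R) <- list(variables, variables)
  set2 <- function(a, b, r) {
    if (a %in% variables && b %in% variables) {
      R[a, b] <<- r
      R[b, a] <<- r
    }
  }
  set2("AHI", "AR", 0.6); set2("AHI", "NadirSpO2", -0.5); set2("AR", "NadirSpO2", -0.35)
  set2("AHI", "AS", -0.2); set2("WASO", "SleepEff", -0.5)
  cg <- intersect(cognitive_variables(), variables)
  if (length(cg) > 1) {
    for (i in seq_len(length(cg) - 1)) for (j in (i + 1):length(cg)) set2(cg[i], cg[j], 0.4)
  }
  for (v in cg) { set2("AHI", v, -0.25); set2("AR", v, -0.2) }
  R
}

#' Specification for a synthetic cohort
#'
#' @param group_sizes Integer triple: number of controls, mild and
#'   moderate/severe subjects (default `c(176, 98, 20)`).
#' @param age_range Age bounds in years (default 5--9).
#' @param marginal_params Per-group marginal tibble as produced by
#'   [default_marginal_params()]; must cover every variable named in the
#'   latent correlation for every group.
#' @param latent_correlation Target correlation matrix over the generated
#'   variables, or a named list of per-group matrices. Must be symmetric with
#'   unit diagonal and positive semidefinite.
#' @param correlation_type `"spearman"` (default) interprets the targets as
#'   Spearman correlations and applies the copula conversion
#'   `rho_P = 2 sin(pi rho_S / 6)`; `"pearson"` uses them directly as the
#'   Gaussian copula correlation.
#' @param sex_prob_male Probability of male sex (default 0.57, matching a
#'   57%-male cohort).
#' @param eeg Named list of [eeg_synthesis_spec()] overrides shared by all
#'   per-subject EEG specs (e.g. `duration`, `artifact_rate`).
#' @param seed Integer master seed.
#' @return An object of class `cohort_synthesis_spec`.
#' @export
cohort_synthesis_spec <- function(group_sizes = c(176, 98, 20),
                                  age_range = c(5, 9),
                                  marginal_params = default_marginal_params(),
                                  latent_correlation = default_latent_correlation(),
                                  correlation_type = c("spearman", "pearson"),
                                  sex_prob_male = 0.57,
                                  eeg = list(duration = 600),
                                  seed = NULL) {
  correlation_type <- match.arg(correlation_type)
  if (length(group_sizes) != 3 || any(group_sizes < 0) || any(group_sizes != round(group_sizes))) {
    abort_field("group_sizes", "must be three non-negative integers (controls, mild, mod/severe)")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort_field("age_range", "must be increasing c(lower, upper)")
  }
  assert_scalar_number(sex_prob_male, "sex_prob_male", lower = 0, upper = 1)
  mats <- if (is.list(latent_correlation)) latent_correlation else
    setNames(rep(list(latent_correlation), 3), severity_levels())
  if (!all(severity_levels() %in% names(mats))) {
    abort_field("latent_correlation", "per-group list must name all three groups")
  }
  for (g in severity_levels()) validate_latent_correlation(mats[[g]])
  vars <- colnames(mats[[1]])
  for (g in severity_levels()) {
    have <- marginal_params$variable[marginal_params$group == g]
    missing <- setdiff(vars, have)
    if (length(missing) > 0) {
      abort_field("marginal_params", sprintf(
        "no marginal for variable(s) %s in group '%s'", paste(missing, collapse = ", "), g))
    }
  }
  if (!is.null(seed)) assert_scalar_number(seed, "seed")
  structure(
    list(group_sizes = as.integer(group_sizes), age_range = age_range,
         marginal_params = marginal_params, latent_correlation = mats,
         correlation_type = correlation_type, sex_prob_male = sex_prob_male,
         eeg = eeg, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cohort_synthesis_spec"
  )
}

validate_latent_correlation <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R) || is.null(colnames(R))) {
    abort_field("latent_correlation", "must be a square named matrix")
  }
  if (max(abs(R - t(R))) > 1e-10) abort_field("latent_correlation", "must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) abort_field("latent_correlation", "diagonal must be 1")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_field("latent_correlation", sprintf(
      "must be positive semidefinite (min eigenvalue %.3g)", min(ev)))
  }
  invisible(R)
}

#' Synthesize a cohort table with planted dependence structure
#'
#' Generates one row per subject: id, age, sex, severity group, the six PSG
#' variables and six cognitive scores (plus any extra variables named in the
#' latent correlation). Cross-variable dependence is induced per group by a
#' Gaussian copula carrying the target correlation, then mapped to the stated
#' marginals by quantile transformation (truncated where bounds apply, so
#' e.g. every control's AHI is <= 1 event/h). A per-subject
#' [eeg_synthesis_spec()] is attached as the list-column `eeg_spec`, with the
#' slow-oscillation peak parameters and delta weighting tied to the
#' subject's severity group (peak frequency 0.75 / 0.417 / 0.267 Hz and
#' increasing peak amplitude from controls to moderate/severe).
#'
#' @param spec A [cohort_synthesis_spec()].
#' @return A tibble with columns `subject_id`, `group` (factor), `age`,
#'   `sex` ("M"/"F"), the cohort variables, and the `eeg_spec` list-column.
#' @export
#' @examples
#' cohort <- synthesize_cohort(cohort_synthesis_spec(group_sizes = c(8, 5, 3), seed = 1))
#' dplyr::count(cohort, group)
synthesize_cohort <- function(spec) {
  if (!inherits(spec, "cohort_synthesis_spec")) {
    abort_field("spec", "must be a cohort_synthesis_spec")
  }
  with_seed(spec$seed, {
    groups <- severity_levels()
    out <- vector("list", 3)
    counter <- 0
    for (gi in seq_along(groups)) {
      ng <- spec$group_sizes[gi]
      if (ng == 0) next
      g <- groups[gi]
      R <- spec$latent_correlation[[g]]
      if (spec$correlation_type == "spearman") {
        Rp <- spearman_to_pearson(R)
        diag(Rp) <- 1
        validate_latent_correlation(Rp)
      } else {
        Rp <- R
      }
      vars <- colnames(Rp)
      # Gaussian copula draw
      L <- chol_psd(Rp)
      z <- matrix(rnorm(ng * length(vars)), nrow = ng) %*% L
      u <- pnorm(z)
      colnames(u) <- vars
      dat <- tibble::as_tibble(lapply(setNames(vars, vars), function(v) {
        mp <- spec$marginal_params[spec$marginal_params$group == g &
                                   spec$marginal_params$variable == v, ]
        marginal_quantile(u[, v], mp)
      }))
      ids <- sprintf("S%03d", counter + seq_len(ng))
      counter <- counter + ng
      age <- truncnorm_quantile(runif(ng), mean = 6.9, sd = 0.7,
                                lower = spec$age_range[1], upper = spec$age_range[2])
      sex <- ifelse(rbinom(ng, 1, spec$sex_prob_male) == 1, "M", "F")
      severity <- (gi - 1) / 2
      eeg_specs <- lapply(seq_len(ng), function(i) {
        severity_eeg_spec(group = g, subject_id = ids[i],
                          seed = if (is.null(spec$seed)) NULL else
                            substream_seed(spec$seed, counter - ng + i),
                          overrides = spec$eeg)
      })
      out[[gi]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = ids,
                       group = factor(g, levels = groups),
                       age = age, sex = sex),
        dat
      ) %>% dplyr::mutate(eeg_spec = eeg_specs)
    }
    dplyr::bind_rows(out)
  })
}

# Cholesky tolerant of semidefinite matrices (zero-pads null directions)
chol_psd <- function(R) {
  ok <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), nrow = length(v)))
}

# quantile transform u -> marginal defined by (dist, median, q1, q3, bounds)
marginal_quantile <- function(u, mp) {
  stopifnot(nrow(mp) == 1)
  iqr_z <- 2 * qnorm(0.75)
  if (mp$dist == "lnorm") {
    if (mp$median <= 0 || mp$q1 <= 0) abort_field("marginal_params", "lnorm needs positive quartiles")
    meanlog <- log(mp$median)
    sdlog <- (log(mp$q3) - log(mp$q1)) / iqr_z
    lo <- plnorm(max(mp$lower, 0), meanlog, sdlog)
    hi <- plnorm(mp$upper, meanlog, sdlog)
    qlnorm(lo + u * (hi - lo), meanlog, sdlog)
  } else if (mp$dist == "norm") {
    mean <- mp$median
    sd <- (mp$q3 - mp$q1) / iqr_z
    lo <- pnorm(mp$lower, mean, sd)
    hi <- pnorm(mp$upper, mean, sd)
    qnorm(lo + u * (hi - lo), mean, sd)
  } else {
    abort_field("marginal_params", sprintf("unknown dist '%s'", mp$dist))
  }
}

truncnorm_quantile <- function(u, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + u * (hi - lo), mean, sd)
}

#' Severity-dependent EEG synthesis presets
#'
#' Maps a severity group to an [eeg_synthesis_spec()] in the regime of the
#' group-median spectra: a slow-oscillation peak whose frequency decreases
#' (0.75, 0.417, 0.267 Hz for controls, mild, moderate/severe) and whose
#' relative amplitude increases with severity, over delta-dominant band
#' fractions that shift further toward delta1 as severity grows.
#'
#' @param group One of `"controls"`, `"mild"`, `"mod_severe"`.
#' @param subject_id Identifier for the generated spec.
#' @param seed Integer seed or `NULL`.
#' @param overrides Named list of [eeg_synthesis_spec()] arguments to
#'   override (e.g. `duration`, `artifact_rate`).
#' @return An [eeg_synthesis_spec()].
#' @export
severity_eeg_spec <- function(group, subject_id = "synthetic", seed = NULL,
                              overrides = list()) {
  group <- match.arg(group, severity_levels())
  gi <- match(group, severity_levels())
  s <- (gi - 1) / 2
  fr <- default_band_fractions()
  fr["delta1"] <- fr["delta1"] + 0.08 * s
  fr <- fr / sum(fr)
  args <- list(
    duration = 600,
    band_power_fractions = fr,
    peak_frequency = c(0.75, 0.417, 0.267)[gi],
    peak_relative_amplitude = 0.10 + 0.08 * s,
    subject_id = subject_id,
    seed = seed
  )
  args <- utils::modifyList(args, overrides)
  do.call(eeg_synthesis_spec, args)
}
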