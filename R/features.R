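#' Assemble the per-subject feature table
#'
#' Combines the cohort table with band-wise EEG features computed from each
#' subject's normalized spectrum: relative power (`rp_`) and spectral entropy
#' (`specen_`) for every band x channel, named deterministically as
#' `"{measure}_{band}_{channel}"` (e.g. `rp_delta1_F3`). With 8 channels and
#' the 8 canonical bands this yields 128 EEG feature columns alongside the 6
#' PSG variables, 6 cognitive scores, age, sex and group.
#'
#' Subjects present in the cohort but missing a spectrum, or whose spectrum
#' lacks an expected channel, are excluded and listed in the completeness
#' report attached as `attr(x, "completeness")`.
#'
#' @param cohort Cohort tibble with at least `subject_id`, `group`, `age`,
#'   `sex` (the `eeg_spec` list-column, if present, is dropped).
#' @param spectra Named list of [eeg_spectrum()] objects keyed by subject id
#'   (or keyed implicitly by each spectrum's `subject_id`).
#' @param bands Bands tibble (default all eight canonical bands).
#' @param channels Expected channel set (default: the channels of the first
#'   spectrum).
#' @return A tibble, one row per subject with complete EEG data.
#' @export
build_feature_table <- function(cohort, spectra, bands = eeg_bands(), channels = NULL) {
  stopifnot(is.data.frame(cohort), "subject_id" %in% names(cohort))
  if (is.null(names(spectra))) {
    names(spectra) <- vapply(spectra, function(s) s$subject_id, character(1))
  }
  if (is.null(channels)) channels <- spectra[[1]]$channel_labels
  bands <- validate_band(bands)

  issues <- list()
  rows <- list()
  for (id in cohort$subject_id) {
    s <- spectra[[id]]
    if (is.null(s)) {
      issues[[id]] <- tibble::tibble(subject_id = id, reason = "missing_eeg")
      next
    }
    miss <- setdiff(channels, s$channel_labels)
    if (length(miss) > 0) {
      issues[[id]] <- tibble::tibble(
        subject_id = id, reason = paste0("missing_channel:", paste(miss, collapse = ",")))
      next
    }
    rp <- relative_power(s, bands)
    se <- spectral_entropy(s, bands)
    feats <- dplyr::bind_rows(
      rp %>% dplyr::mutate(name = paste("rp", .data$band, .data$channel, sep = "_"),
                           value = .data$rp) %>%
        dplyr::select("name", "value"),
      se %>% dplyr::mutate(name = paste("specen", .data$band, .data$channel, sep = "_"),
                           value = .data$specen) %>%
        dplyr::select("name", "value")
    )
    feats <- feats[order(match(sub("_.*", "", feats$name), c("rp", "specen"))), ]
    rows[[id]] <- tibble::tibble(subject_id = id) %>%
      dplyr::bind_cols(tidyr::pivot_wider(feats, names_from = "name", values_from = "value"))
  }
  if (length(rows) == 0) rlang::abort("no subject has complete EEG data")
  eeg_tbl <- dplyr::bind_rows(rows)
  out <- cohort %>%
    dplyr::select(-dplyr::any_of("eeg_spec")) %>%
    dplyr::inner_join(eeg_tbl, by = "subject_id")
  attr(out, "completeness") <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(subject_id = character(), reason = character())
  out
}

#' Read and write feature tables losslessly
#'
#' CSV serialization that round-trips double-precision feature values
#' bit-exactly (numeric columns are written with 17 significant digits, the
#' shortest representation guaranteed to reproduce any double).
#'
#' @param features A feature table from [build_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table()`: `path`, invisibly. `read_feature_table()`:
#'   the feature tibble with `group` restored as an ordered severity factor.
#' @export
write_feature_table <- function(features, path) {
  out <- dplyr::mutate(features, dplyr::across(
    dplyr::where(is.numeric), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base parser (strtod) is correctly rounded, so 17-digit decimals map back
  # to the exact original doubles
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("group" %in% names(tbl) && all(tbl$group %in% severity_levels())) {
    tbl$group <- factor(tbl$group, levels = severity_levels())
  }
  tbl
}

#' Names of EEG feature columns in a feature table
#'
#' @param features A feature table from [build_feature_table()].
#' @param measure `"rp"`, `"specen"`, or both.
#' @return Character vector of matching column names.
#' @export
eeg_feature_columns <- function(features, measure = c("rp", "specen")) {
  measure <- match.arg(measure, several.ok = TRUE)
  pat <- paste0("^(", paste(measure, collapse = "|"), ")_")
  grep(pat, names(features), value = TRUE)
}

# parse "{measure}_{band}_{channel}" names into metadata
parse_feature_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  tibble::tibble(
    node = x,
    measure = vapply(parts, `[`, character(1), 1),
    band = vapply(parts, `[`, character(1), 2),
    channel = vapply(parts, `[`, character(1), 3)
  )
}
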