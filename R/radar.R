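#' Radar-style band-averaged correlation summaries
#'
#' Summarizes a bootstrap correlation matrix the way the radar (spider)
#' charts do: for every band and every non-EEG variable, the mean over the
#' EEG channels of the absolute bootstrap-median correlation; and,
#' separately, for each PSG variable the mean absolute correlation over the
#' six cognitive scores and vice versa.
#'
#' @param mat A `boot_cor_matrix` from [bootstrap_matrix()] whose node set
#'   contains EEG nodes plus PSG and/or cognitive variables.
#' @return A tibble with columns `panel` (`"eeg_vs_psg"`,
#'   `"eeg_vs_cognitive"`, `"psg_vs_cognitive"`, `"cognitive_vs_psg"`),
#'   `axis` (band name for EEG panels, variable name otherwise), `target`
#'   (the variable correlated against, or `"average"` for the cross-block
#'   panels), and `mean_abs_rho`.
#' @export
radar_summary <- function(mat) {
  stopifnot(inherits(mat, "boot_cor_matrix"))
  meta <- mat$nodes
  M <- abs(mat$median)
  eeg <- meta$node[meta$type == "eeg"]
  psg <- meta$node[meta$type == "psg"]
  cog <- meta$node[meta$type == "cognitive"]

  eeg_panel <- function(vars, panel) {
    if (length(eeg) == 0 || length(vars) == 0) return(NULL)
    purrr::map_dfr(unique(meta$band[meta$type == "eeg"]), function(b) {
      nodes_b <- meta$node[meta$type == "eeg" & meta$band == b]
      purrr::map_dfr(vars, function(v) {
        tibble::tibble(panel = panel, axis = b, target = v,
                       mean_abs_rho = mean(M[nodes_b, v], na.rm = TRUE))
      })
    })
  }
  cross_panel <- function(from, to, panel) {
    if (length(from) == 0 || length(to) == 0) return(NULL)
    purrr::map_dfr(from, function(v) {
      tibble::tibble(panel = panel, axis = v, target = "average",
                     mean_abs_rho = mean(M[v, to], na.rm = TRUE))
    })
  }
  dplyr::bind_rows(
    eeg_panel(psg, "eeg_vs_psg"),
    eeg_panel(cog, "eeg_vs_cognitive"),
    cross_panel(psg, cog, "psg_vs_cognitive"),
    cross_panel(cog, psg, "cognitive_vs_psg")
  )
}
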