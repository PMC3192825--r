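#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with optional top-level blocks `demography`,
#' `selection`, and `layout`, whose keys are the arguments of
#' [demographic_model()], [selection_model()], and [build_layout()]
#' respectively, and returns the constructed objects (defaults fill
#' anything omitted). Example:
#'
#' ```yaml
#' demography:
#'   N_anc: 20000
#'   lambda: 40
#'   bottleneck: {N: 1000, t_start: 1500, t_end: 1000}
#' selection:
#'   p_minus: 1
#'   intron_del_fraction: 0.25
#'   s_intron: 2.5e-4
#' layout:
#'   n_exons: 8
#' ```
#'
#' @param path YAML file path.
#' @return list with `demography`, `selection`, `layout`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_param("reading YAML configs requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  list(
    demography = do.call(demographic_model, cfg$demography %||% list()),
    selection = do.call(selection_model, cfg$selection %||% list()),
    layout = build_layout(cfg$layout %||% list())
  )
}
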