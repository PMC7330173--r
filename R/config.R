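#' Default analysis thresholds
#'
#' One place for the tunable cutoffs used across the pipeline. Values can
#' be overridden per call or collectively via a YAML file ([load_config()]).
#'
#' * `cpg_p`: nominal CpG p-value cutoff (0.0005)
#' * `delta_beta`: CpG group-mean methylation difference cutoff (0.05)
#' * `dmr_fdr`: region-level false discovery rate cutoff (0.05)
#' * `dmr_delta_beta`: region mean methylation-change cutoff (0.10)
#' * `dmr_max_gap`: maximum gap between member CpGs, bp (1000)
#' * `dmr_min_cpgs`: minimum CpGs per region (3)
#' * `hit_p`: nominal per-feature significance cutoff (0.05)
#' * `het_low`, `het_high`: mitochondrial heteroplasmy band (0.05, 0.95)
#' * `haploblock_max_gap`: maximum gap between haploblock members, bp (50000)
#' * `haploblock_min_size`: minimum variants per haploblock (3)
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cpg_p = 5e-4,
    delta_beta = 0.05,
    dmr_fdr = 0.05,
    dmr_delta_beta = 0.10,
    dmr_max_gap = 1000L,
    dmr_min_cpgs = 3L,
    hit_p = 0.05,
    het_low = 0.05,
    het_high = 0.95,
    haploblock_max_gap = 50000L,
    haploblock_min_size = 3L
  )
}

#' Load analysis thresholds from a YAML file
#'
#' Reads a YAML mapping of threshold overrides and merges it over
#' [default_config()]. Unknown keys are rejected so typos fail loudly; the
#' resolved configuration is reported once via `message()`.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param quiet Suppress the resolved-config message.
#' @return Named list of resolved thresholds.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  if (!quiet) {
    message("resolved config: ",
            paste(names(cfg), unlist(cfg), sep = "=", collapse = ", "))
  }
  cfg
}
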