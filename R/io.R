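#' Read / write per-individual trait tables
#'
#' CSV with header `id,sex,offspring_weaned,weight_weaning,tail_length,
#' ear_size,hind_foot_length`; missing values are empty cells. Counts must
#' be non-negative.
#'
#' @param path file path.
#' @return `read_traits()`: data frame with those columns;
#'   `write_traits()`: `path` invisibly.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex")
  if (!all(need %in% names(x)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  x$id <- as.character(x$id)
  x$sex <- toupper(substr(x$sex, 1, 1))
  if ("offspring_weaned" %in% names(x) &&
      any(x$offspring_weaned < 0, na.rm = TRUE))
    stop("offspring_weaned must be non-negative")
  x
}

#' @rdname read_traits
#' @param traits trait data frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' Bundles the reproducibility-relevant analysis settings. The defaults
#' are the study's: 100 neutral-simulation replicates, 100 MLH resampling
#' replicates, 1000 permutations, D' threshold 0.8, FDR level 0.05.
#'
#' @param seed integer master seed.
#' @param n_null_replicates,n_mlh_replicates,n_permutations replicate
#'   counts (all >= 1).
#' @param dprime_threshold D' grouping cutoff in (0, 1].
#' @param fdr_alpha FDR level in (0, 1).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_null_replicates = 100L,
                       n_mlh_replicates = 100L, n_permutations = 1000L,
                       dprime_threshold = 0.8, fdr_alpha = 0.05) {
  stopifnot(n_null_replicates >= 1, n_mlh_replicates >= 1,
            n_permutations >= 1,
            dprime_threshold > 0, dprime_threshold <= 1,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(seed = as.integer(seed),
                 n_null_replicates = as.integer(n_null_replicates),
                 n_mlh_replicates = as.integer(n_mlh_replicates),
                 n_permutations = as.integer(n_permutations),
                 dprime_threshold = dprime_threshold,
                 fdr_alpha = fdr_alpha),
            class = "run_config")
}

#' Write a JSON run manifest
#'
#' Records the seed, the full run configuration, and package/R versions
#' next to a set of result tables, so any output can be regenerated.
#'
#' @param config a [run_config()].
#' @param path output JSON path.
#' @param extra optional named list merged into the manifest.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(seed = config$seed, config = unclass(config),
                     package = "captivepop",
                     package_version =
                       as.character(utils::packageVersion("captivepop")),
                     r_version = as.character(getRversion()),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
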