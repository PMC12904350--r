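#' Read a scenario configuration file
#'
#' YAML or JSON (chosen by extension) with optional top-level sections
#' `cat` (fields of [cat_config()], plus `policy_method` and
#' `first_item_rule`), `synthetic` (fields of [synthetic_spec()]) and
#' `grid` (`thresholds`, `max_items`). Missing fields fall back to the
#' constructors' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `cat` ([cat_config()]), `synthetic`
#'   ([synthetic_spec()]), `thresholds` and `max_items`.
#' @export
read_cat_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  cc <- raw$cat %||% list()
  policy <- selection_policy(
    method = cc$policy_method %||% "mpwi",
    first_item_rule = cc$first_item_rule %||% "max_info_at_theta0")
  cc <- cc[setdiff(names(cc), c("policy_method", "first_item_rule"))]
  cfg <- do.call(cat_config, c(cc, list(policy = policy)))
  spec <- do.call(synthetic_spec, raw$synthetic %||% list())
  list(cat = cfg, synthetic = spec,
       thresholds = raw$grid$thresholds %||% c(0.50, 0.45),
       max_items = as.integer(raw$grid$max_items %||% c(15L, 18L, 22L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the seed, a hash of the effective configuration, md5 checksums
#' of the input files, the package version and a timestamp, so every output
#' file is traceable to the run that produced it.
#'
#' @param path Output path for the JSON manifest.
#' @param config The effective configuration (any list).
#' @param seed Integer seed used for the run (`NA` for RNG-free runs).
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, seed = NA_integer_,
                               inputs = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    seed = seed,
    tool_version = as.character(utils::packageVersion("adaptcat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
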