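# YAML configuration files: full parameter set plus optional scenarios.

CONFIG_SCHEMA_VERSION <- 1L

#' Read a model configuration file
#'
#' The config dialect is YAML with three top-level keys:
#' \code{schema_version} (must equal 1), \code{params} (every model parameter,
#' no omissions), and an optional \code{scenarios} list, each entry with
#' \code{name}, optional \code{overrides}, and optional \code{arm_overrides}
#' (sub-keys \code{prescribed} / \code{not_prescribed}). Unknown keys at any
#' level are rejected rather than ignored, so typos surface as errors.
#'
#' @param path path to a YAML config file.
#' @return A list with elements \code{params} (\code{model_params}) and
#'   \code{scenarios} (named list of \code{scenario_spec}, possibly empty).
#' @seealso [save_config()] for the inverse; the packaged base case is at
#'   \code{system.file("extdata", "base_case.yaml", package = "epivalue")}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw))
    stop("config error: missing required field 'schema_version' ",
         "(file empty or not a mapping)", call. = FALSE)
  allowed_top <- c("schema_version", "params", "scenarios")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (req in c("schema_version", "params"))
    if (is.null(raw[[req]]))
      stop("config error: missing required field '", req, "'", call. = FALSE)
  if (!identical(as.integer(raw$schema_version), CONFIG_SCHEMA_VERSION))
    stop("config error: unsupported schema_version ",
         format(raw$schema_version), call. = FALSE)

  fields <- param_field_names()
  unknown <- setdiff(names(raw$params), fields)
  if (length(unknown))
    stop("config error: unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(fields, names(raw$params))
  if (length(missing))
    stop("config error: missing required field(s) under params: ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- do.call(model_params, raw$params)

  scenarios <- list()
  for (sc in raw$scenarios) {
    unknown <- setdiff(names(sc), c("name", "overrides", "arm_overrides"))
    if (length(unknown))
      stop("config error: unknown scenario field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (is.null(sc$name))
      stop("config error: scenario without a name", call. = FALSE)
    scenarios[[sc$name]] <- scenario_spec(
      sc$name,
      overrides = if (is.null(sc$overrides)) list() else sc$overrides,
      arm_overrides = if (is.null(sc$arm_overrides)) list()
                      else sc$arm_overrides)
  }
  list(params = params, scenarios = scenarios)
}

#' Write a model configuration file
#'
#' Serializes a full parameter set (and optional scenarios) to the YAML
#' dialect read by [load_config()]; writing then reading reproduces the
#' input.
#'
#' @param params a \code{model_params} object.
#' @param path output file path.
#' @param scenarios optional named list of \code{scenario_spec}.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(params, path, scenarios = list()) {
  validate_params(params)
  doc <- list(schema_version = CONFIG_SCHEMA_VERSION,
              params = unclass(params))
  if (length(scenarios)) {
    doc$scenarios <- lapply(unname(scenarios), function(sc) {
      stopifnot(inherits(sc, "scenario_spec"))
      out <- list(name = sc$name)
      if (length(sc$overrides)) out$overrides <- sc$overrides
      if (length(sc$arm_overrides)) out$arm_overrides <- sc$arm_overrides
      out
    })
  }
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}
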