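#' Read a parameter set from a JSON or YAML file
#'
#' The file must be a flat mapping with exactly the eleven keys of
#' [param_names]; unknown keys and missing keys are errors — there are no
#' silent defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `game_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension: .", ext,
         " (use .json, .yaml or .yml)"))
  if (!is.list(vals)) vals <- as.list(vals)
  if (any(vapply(vals, length, integer(1)) != 1L))
    stop("parameter file must be a flat mapping of scalars")
  as_game_parameters(vals)
}

#' Write a parameter set to a JSON file
#'
#' @param params A `game_parameters` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  p <- as_game_parameters(params)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
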