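# Run configuration files.
#
# A YAML (or JSON) file may override any argument of dflgmd_params(); keys
# that are not parameters are rejected so typos fail loudly rather than
# silently falling back to defaults.  An empty file yields the full default
# parameter set.

#' Load a parameter configuration file
#'
#' @param path YAML or JSON file whose keys are [dflgmd_params()] argument
#'   names.  Unknown keys are an error; missing keys take the defaults.
#' @return A [dflgmd_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a mapping of parameter names",
                           call. = FALSE)
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back to the
  # grid-side parameter (no other parameter name collides with a boolean)
  names(vals)[names(vals) == "FALSE"] <- "n"
  known <- names(formals(dflgmd_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$memory_window) && identical(vals$memory_window, "full")) {
    vals$memory_window <- Inf
  }
  do.call(dflgmd_params, vals)
}
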