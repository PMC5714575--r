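#' Named NTCP parameter set with provenance
#'
#' Couples a model parameter triple with the metadata needed to apply it
#' correctly: which lung volume the source study scored (paired lungs vs.
#' ipsilateral lung), the complication endpoint, and which treatment types it
#' is intended for.
#'
#' @param name short identifier, e.g. `"seppenwoolde_lkb"`.
#' @param model `"LKB"` or `"RS"`.
#' @param parameters an [lkb_parameters] or [rs_parameters] object matching
#'   `model`.
#' @param lung_volume `"paired"` or `"ipsilateral"`.
#' @param endpoint free-text endpoint description.
#' @param used_on character vector of treatment types the set applies to
#'   (subset of `"Tang"`, `"LGL"`, `"Lung"`).
#' @param provenance free-text source description.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(name, model = c("LKB", "RS"), parameters,
                          lung_volume = c("paired", "ipsilateral"),
                          endpoint = "", used_on = character(),
                          provenance = "") {
  model <- match.arg(model)
  lung_volume <- match.arg(lung_volume)
  want <- if (model == "LKB") "lkb_parameters" else "rs_parameters"
  if (!inherits(parameters, want))
    stop("`parameters` must be of class ", want, " for model ", model,
         call. = FALSE)
  if (length(used_on) && !all(used_on %in% c("Tang", "LGL", "Lung")))
    stop("`used_on` entries must be among Tang, LGL, Lung", call. = FALSE)
  structure(
    list(name = as.character(name), model = model, parameters = parameters,
         lung_volume = lung_volume, endpoint = as.character(endpoint),
         used_on = as.character(used_on), provenance = as.character(provenance)),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  p <- x$parameters
  vals <- if (x$model == "LKB")
    sprintf("D50 = %g Gy, m = %g, n = %g", p$d50, p$m, p$n)
  else
    sprintf("D50 = %g Gy, gamma = %g, s = %g", p$d50, p$gamma, p$s)
  cat(sprintf("<parameter_set> %s [%s, %s lung] %s\n  endpoint: %s\n",
              x$name, x$model, x$lung_volume, vals, x$endpoint))
  invisible(x)
}

#' Registry of published lung NTCP parameter sets
#'
#' The parameter sets shipped with the package: pencil-beam-era lung
#' (pneumonitis) dose-response parameters from four published studies —
#' Seppenwoolde et al. (LKB and RS, paired lungs), Gagliardi et al. (RS,
#' ipsilateral lung), Rancati et al. (LKB and RS, ipsilateral lung), and
#' De Jaeger et al. (LKB, paired lungs; equivalent-path-length and
#' convolution-superposition variants). Values are stored as data in
#' `inst/extdata/parameter_sets.yaml`, not as constants in code.
#'
#' @param name optional set name; omit to get the full named list.
#' @param file optional path to an alternative registry YAML.
#' @return A named list of [parameter_set] objects, or a single set if `name`
#'   is given.
#' @examples
#' names(ntcp_parameter_sets())
#' ntcp_parameter_sets("seppenwoolde_rs")
#' @export
ntcp_parameter_sets <- function(name = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "parameter_sets.yaml", package = "ntcprefit",
                        mustWork = TRUE)
  sets <- read_parameter_sets(file)
  if (is.null(name)) return(sets)
  if (!name %in% names(sets))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  sets[[name]]
}

#' Read / write parameter-set registries
#'
#' Structured-config (YAML) serialization of [parameter_set] lists. Numeric
#' parameter values round-trip exactly through read/write.
#'
#' @param file path to a YAML file.
#' @return `read_parameter_sets()`: named list of [parameter_set];
#'   `write_parameter_sets()`: `file`, invisibly.
#' @export
read_parameter_sets <- function(file) {
  raw <- yaml::read_yaml(file)
  sets <- lapply(raw, function(x) {
    # YAML 1.1 parses an unquoted key `n` as a boolean; tolerate both spellings
    n_val <- if (!is.null(x$parameters[["n"]])) x$parameters[["n"]] else
      x$parameters[["FALSE"]]
    pars <- if (x$model == "LKB")
      lkb_parameters(x$parameters$d50, x$parameters$m, n_val)
    else
      rs_parameters(x$parameters$d50, x$parameters$gamma, x$parameters$s)
    parameter_set(
      name = x$name, model = x$model, parameters = pars,
      lung_volume = x$lung_volume,
      endpoint = if (is.null(x$endpoint)) "" else x$endpoint,
      used_on = if (is.null(x$used_on)) character() else unlist(x$used_on),
      provenance = if (is.null(x$provenance)) "" else x$provenance
    )
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname read_parameter_sets
#' @param sets a list of [parameter_set] objects.
#' @export
write_parameter_sets <- function(sets, file) {
  if (inherits(sets, "parameter_set")) sets <- list(sets)
  out <- lapply(sets, function(s) {
    list(name = s$name, model = s$model,
         parameters = unclass(s$parameters),
         lung_volume = s$lung_volume, endpoint = s$endpoint,
         used_on = as.list(s$used_on), provenance = s$provenance)
  })
  names(out) <- NULL
  yaml::write_yaml(out, file, precision = 17)
  invisible(file)
}
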