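#' Default run configuration
#'
#' The full configuration with every field at its reference-baseline value:
#' seasonal environment `s = -1, r = 1, S0 = 1, R0 = 3, sigma_R = 0.1,
#' sigma_S = 0.4`, demography `s_A = 0.5, k = 0.5, q_c = 1, v = 0.5`, the
#' default solver controls, and an `ess` experiment.
#'
#' @return An object of class `run_config` (a nested named list with blocks
#'   `seasonal`, `demography`, `solver`, `experiment`, `output`, `seed`).
#' @export
default_config <- function() {
  structure(list(
    seasonal = list(r = 1, sigma_R = 0.1, R0 = 3, s = -1, sigma_S = 0.4, S0 = 1),
    demography = list(s_A = 0.5, k = 0.5, q_c = 1, v = 0.5),
    solver = list(bracket = c(-3, 3), scan_points = 17, tol = 1e-8,
                  max_iter = 1000, eq_tol = 1e-10, extinct_tol = 1e-12,
                  n0 = 1),
    experiment = list(kind = "ess", mu = 0, delta_s = 0, delta_r = 0,
                      vary = "s_A", grid = "0.3:0.9:5"),
    output = list(path = "", format = "csv"),
    seed = 1L
  ), class = "run_config")
}

config_schema <- function() {
  lapply(unclass(default_config()), function(block) {
    if (is.list(block)) names(block) else NULL
  })
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly partial) YAML configuration, fills every missing field
#' from [default_config()], validates parameter invariants, and rejects
#' unknown keys. An empty file yields the full baseline configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  merge_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x A (possibly partial) nested list with any of the blocks
#'   `seasonal`, `demography`, `solver`, `experiment`, `output`, `seed`.
#' @return A validated `run_config` object.
#' @export
merge_config <- function(x = list()) {
  cfg <- unclass(default_config())
  schema <- config_schema()
  unknown_top <- setdiff(names(x), names(cfg))
  if (length(unknown_top) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  }
  for (block in names(x)) {
    if (is.null(schema[[block]])) {  # scalar block (seed)
      cfg[[block]] <- x[[block]]
      next
    }
    unknown <- setdiff(names(x[[block]]), schema[[block]])
    if (length(unknown) > 0L) {
      stop("unknown key(s) in '", block, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (key in names(x[[block]])) {
      cfg[[block]][[key]] <- x[[block]][[key]]
    }
  }
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  do.call(seasonal_params, cfg$seasonal)
  do.call(demography_params, cfg$demography)
  sv <- cfg$solver
  if (length(sv$bracket) != 2L || !all(is.finite(sv$bracket)) ||
      sv$bracket[1] >= sv$bracket[2]) {
    stop("solver$bracket must be an increasing length-2 interval",
         call. = FALSE)
  }
  for (nm in c("tol", "eq_tol", "extinct_tol", "n0")) {
    if (!is.numeric(sv[[nm]]) || length(sv[[nm]]) != 1L ||
        !is.finite(sv[[nm]]) || sv[[nm]] <= 0) {
      stop("solver$", nm, " must be a single positive number", call. = FALSE)
    }
  }
  kinds <- c("ess", "equilibrium", "scenario", "sweep")
  if (!cfg$experiment$kind %in% kinds) {
    stop("experiment$kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write a run configuration to a YAML file
#'
#' Serialisation is lossless: `load_config(save_config(cfg, path))` returns a
#' configuration identical to `cfg`.
#'
#' @param cfg A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_seasonal <- function(cfg) do.call(seasonal_params, cfg$seasonal)
config_demography <- function(cfg) do.call(demography_params, cfg$demography)

parse_grid <- function(spec) {
  if (is.numeric(spec)) return(as.numeric(spec))
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("grid must be numeric or a string 'from:to:n'", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || vals[3] < 1) stop("malformed grid spec: ", spec,
                                       call. = FALSE)
  seq(vals[1], vals[2], length.out = as.integer(vals[3]))
}
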