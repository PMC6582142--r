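config_error <- function(msg, key = NULL) {
  stop(structure(class = c("mucoflow_config_error", "error", "condition"),
                 list(message = if (is.null(key)) msg
                      else sprintf("%s (key: %s)", msg, key),
                      call = NULL)))
}

scenario_builders <- function() {
  list(
    "antrum-borderline" = function(ov) scenario_antrum_borderline(ov),
    "cardia"            = function(ov) scenario_cardia(ov),
    "linear-ulcer"      = function(ov) scenario_linear_ulcer(ov),
    "watershed"         = function(ov) do.call(scenario_watershed, ov %||% list()),
    "necrosis-pre"      = function(ov) scenario_necrosis("pre"),
    "necrosis-post"     = function(ov) scenario_necrosis("post"),
    "homogeneous"       = function(ov) do.call(scenario_homogeneous, ov %||% list())
  )
}

#' Build a named scenario
#'
#' @param name One of `"antrum-borderline"`, `"cardia"`, `"linear-ulcer"`,
#'   `"watershed"`, `"necrosis-pre"`, `"necrosis-post"`, `"homogeneous"`.
#' @param overrides Named list of constants passed through to the builder.
#' @return A `mucoflow_scenario`.
#' @export
build_scenario <- function(name, overrides = NULL) {
  builders <- scenario_builders()
  if (!name %in% names(builders))
    config_error(paste0("unknown scenario '", name, "'; available: ",
                        paste(names(builders), collapse = ", ")))
  builders[[name]](overrides)
}

read_tsv_matrix <- function(path) {
  # row = y ascending, column = x ascending (figure orientation)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  t(m) # stored internally as nx x ny
}

write_tsv_matrix <- function(m, path) {
  # transpose so a printed file shows x left-to-right, y top-to-bottom
  tm <- t(m)
  lines <- apply(tm, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
}

resolve_field_entry <- function(value, grid, name, dir) {
  if (is.character(value)) {
    path <- if (file.exists(value)) value else file.path(dir, value)
    if (!file.exists(path))
      config_error(paste0("matrix file not found: ", value), key = name)
    m <- read_tsv_matrix(path)
    if (!identical(dim(m), c(grid$nx, grid$ny)))
      config_error(sprintf("matrix in '%s' is %d x %d, expected %d x %d",
                           value, nrow(m), ncol(m), grid$nx, grid$ny),
                   key = name)
    m
  } else if (is.numeric(value) && length(value) == 1L) {
    value
  } else config_error("field must be a scalar constant or a TSV path", key = name)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    config_error(paste0("unknown key(s) in ", where, ": ",
                        paste(unknown, collapse = ", ")),
                 key = unknown[1L])
}

#' Read a run configuration
#'
#' Structured-text (YAML) configuration resolving to a scenario plus
#' solver options. Either name a built-in scenario (with optional constant
#' overrides) or give grid + fields explicitly, each field as a constant
#' or a path to a TSV matrix (row = y, column = x, as written by
#' [write_solution()]). Unknown keys are rejected with the offending key
#' named; omitted keys take the documented defaults.
#'
#' @param path Config file path.
#' @return List with `scenario` (a `mucoflow_scenario`) and `opts`
#'   (a [solver_options()]).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("scenario: antrum-borderline", cfg)
#' read_config(cfg)$scenario$name
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(
                    paste0("config parse failure in '", path, "': ",
                           conditionMessage(e))))
  if (!is.list(raw)) config_error("config must be a mapping")
  check_keys(raw, c("scenario", "overrides", "solver", "grid", "fields"),
             "config")
  opts_spec <- raw$solver %||% list()
  check_keys(opts_spec, c("tolerance", "max_iterations", "relaxation",
                          "face_convention"), "solver")
  opts <- do.call(solver_options, opts_spec)
  if (!is.null(raw$scenario)) {
    scenario <- build_scenario(raw$scenario, raw$overrides)
  } else {
    if (is.null(raw$grid) || is.null(raw$fields))
      config_error("config must name a scenario or give both grid and fields")
    check_keys(raw$grid, c("nx", "ny", "h", "boundary"), "grid")
    grid <- do.call(grid_spec, raw$grid)
    check_keys(raw$fields, c("alpha", "omega", "lambda_x", "lambda_y",
                             "delta_p0"), "fields")
    dir <- dirname(path)
    fv <- lapply(c(alpha = "alpha", omega = "omega", lambda_x = "lambda_x",
                   lambda_y = "lambda_y"),
                 function(nm) resolve_field_entry(raw$fields[[nm]], grid, nm, dir))
    fields <- param_fields(grid, fv$alpha, fv$omega, fv$lambda_x, fv$lambda_y,
                           delta_p0 = raw$fields$delta_p0 %||% 1)
    v <- validate_fields(fields, grid)
    if (nrow(v) > 0L)
      config_error(paste0("invalid fields: ",
                          paste(v$message, collapse = "; ")))
    scenario <- new_scenario("custom", grid, fields,
                             list(all = matrix(TRUE, grid$nx, grid$ny)),
                             list(source = path))
  }
  list(scenario = scenario, opts = opts)
}

manifest_from <- function(sol, scenario, opts, metrics = NULL, seed = NULL) {
  list(
    scenario = scenario$name,
    constants = scenario$metadata,
    solver = list(
      tolerance = resolve_tolerance(opts, scenario$fields),
      max_iterations = opts$max_iterations,
      relaxation = opts$relaxation,
      face_convention = opts$face_convention
    ),
    iterations = sol$iterations,
    converged = sol$converged,
    max_residual = sol$max_residual,
    global_imbalance = sol$global_imbalance,
    metrics = metrics,
    version = as.character(utils::packageVersion("mucoflow")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Write a solution to a directory
#'
#' Writes `p.tsv`, `j_alpha.tsv`, `j_omega.tsv`, `j_lambda_x.tsv`,
#' `j_lambda_y.tsv` (tab-separated numeric matrices, row = y ascending,
#' column = x ascending, full double precision) plus `manifest.json`.
#' Output bytes are deterministic for deterministic runs (the manifest
#' timestamp aside).
#'
#' @param sol A `mucoflow_solution`.
#' @param outdir Output directory (created if missing).
#' @param scenario Optional scenario for the manifest.
#' @param metrics Optional named list of metric values for the manifest.
#' @param seed Optional seed to record.
#' @return Invisibly, the paths written.
#' @export
write_solution <- function(sol, outdir, scenario = NULL, metrics = NULL,
                           seed = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mats <- list(p = sol$p, j_alpha = sol$j_alpha, j_omega = sol$j_omega,
               j_lambda_x = sol$j_lambda_x, j_lambda_y = sol$j_lambda_y)
  paths <- character(0)
  for (nm in names(mats)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write_tsv_matrix(mats[[nm]], path)
    paths <- c(paths, path)
  }
  if (is.null(scenario))
    scenario <- list(name = "unnamed", metadata = NULL, fields = sol$fields)
  man <- manifest_from(sol, scenario, sol$opts, metrics, seed)
  man_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, man_path))
}

#' Read a solution directory back
#'
#' @param dir Directory written by [write_solution()].
#' @return List of matrices `p`, `j_alpha`, `j_omega`, `j_lambda_x`,
#'   `j_lambda_y` and the parsed `manifest`.
#' @export
read_solution <- function(dir) {
  out <- lapply(c(p = "p", j_alpha = "j_alpha", j_omega = "j_omega",
                  j_lambda_x = "j_lambda_x", j_lambda_y = "j_lambda_y"),
                function(nm) read_tsv_matrix(file.path(dir, paste0(nm, ".tsv"))))
  man_path <- file.path(dir, "manifest.json")
  out$manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
  out
}
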