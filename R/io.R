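.schema_version <- "1.0"

.fmt17 <- function(x) sprintf("%.17g", x)

#' Stable fingerprint of an R object
#'
#' MD5 digest of the object's canonical JSON serialization (full 17-digit
#' numeric precision); identical inputs give identical fingerprints across
#' sessions.
#'
#' @param x Any jsonlite-serializable object.
#' @return Hex digest string.
#' @export
fingerprint <- function(x) {
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}

#' Serialize / load a parameter set as flat JSON
#'
#' Writes the parameter set as a flat mapping keyed by the ASCII symbol
#' names (plus a `schema_version` field); `read_parameters()` restores it
#' exactly (17 significant digits survive the round trip).
#'
#' @param params Parameter set.
#' @param path File path (`.json`).
#' @return `write_parameters()` the path invisibly; `read_parameters()` a
#'   parameter set.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(as_parameters(params))
  obj <- c(list(schema_version = .schema_version),
           as.list(unclass(params)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schema_version <- NULL
  validate_parameters(as_parameters(obj))
}

#' Load a run configuration from JSON or YAML
#'
#' A configuration file may carry any of the top-level sections
#' `parameters` (flat symbol-keyed overrides of the built-in baselines),
#' `scenario` (fields of [make_scenario()], including `severity`), and
#' `design` (eFAST settings: `names`, `M`, `Ns`, `NR`, `seed`), plus
#' `schema_version`.  Unknown keys anywhere are rejected with the
#' offending key path; missing keys fall back to the built-in fixtures.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return `list(params, scenario, design)`; `design` is `NULL` unless the
#'   file has a `design` section.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  known <- c("schema_version", "parameters", "scenario", "design")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- tryCatch(
    validate_parameters(as_parameters(cfg$parameters %||% list())),
    error = function(e) stop("in config section 'parameters': ",
                             conditionMessage(e), call. = FALSE))

  sc_cfg <- as.list(cfg$scenario %||% list())
  sev <- sc_cfg$severity %||% "mild"
  stem <- sc_cfg$stem_injection %||% TRUE
  mult <- list(delta = sc_cfg$delta %||% 1, omega = sc_cfg$omega %||% 1,
               gamma = sc_cfg$gamma %||% 1)
  sc_cfg[c("severity", "stem_injection", "delta", "omega", "gamma")] <- NULL
  scenario <- tryCatch(
    make_scenario(sev, stem_injection = stem, delta = mult$delta,
                  omega = mult$omega, gamma = mult$gamma,
                  overrides = sc_cfg),
    error = function(e) stop("in config section 'scenario': ",
                             conditionMessage(e), call. = FALSE))

  design <- NULL
  if (!is.null(cfg$design)) {
    dn <- as.list(cfg$design)
    known_d <- c("names", "M", "Ns", "NR", "seed")
    unknown <- setdiff(names(dn), known_d)
    if (length(unknown))
      stop("unknown config key(s) under design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    design <- efast_design(names = dn$names, M = dn$M %||% 4,
                           Ns = dn$Ns %||% 65, NR = dn$NR %||% 5,
                           seed = dn$seed %||% 1)
  }
  list(params = params, scenario = scenario, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as CSV
#'
#' RFC-4180 CSV with header
#' `t_days,Mc,Md,IL1,IL10,IL17,N,M0,M1,M2,C,F,S,T,R`, '.' decimal, one row
#' per output time, numbers at 17 significant digits (values survive the
#' round trip to better than 1e-12 relative); stage-switch and bolus
#' events are echoed as `# event:` comment lines above the header.
#'
#' @param traj Trajectory from [simulate_protocol()].
#' @param path Output file.
#' @return `write_trajectory_csv()` the path invisibly;
#'   `read_trajectory_csv()` a `data.frame` with the events as attribute
#'   `"events"`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "mi_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(traj$events)))
    writeLines(sprintf("# event: t_days=%s %s", .fmt17(traj$events$time[i]),
                       traj$events$label[i]), con)
  tab <- cbind(t_days = traj$times, traj$states)
  writeLines(paste(colnames(tab), collapse = ","), con)
  body <- apply(tab, 1L, function(r) paste(.fmt17(r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  ev_lines <- grep("^# event:", lines, value = TRUE)
  df <- read.csv(text = lines[!startsWith(lines, "#")],
                 check.names = FALSE)
  events <- if (length(ev_lines)) {
    m <- regmatches(ev_lines,
                    regexec("^# event: t_days=([^ ]+) (.+)$", ev_lines))
    data.frame(time = as.numeric(vapply(m, `[`, "", 2L)),
               label = vapply(m, `[`, "", 3L), stringsAsFactors = FALSE)
  } else data.frame(time = numeric(0), label = character(0))
  attr(df, "events") <- events
  df
}

#' Write a sensitivity result as CSV
#'
#' One row per varied parameter with columns
#' `parameter,S1,ST,interaction`.
#'
#' @param sens From [efast_for_model()] or [run_efast()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sensitivity_csv <- function(sens, path) {
  stopifnot(inherits(sens, "mi_sensitivity"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("parameter,S1,ST,interaction", con)
  writeLines(sprintf("%s,%s,%s,%s", sens$parameter, .fmt17(sens$S1),
                     .fmt17(sens$ST), .fmt17(sens$interaction)), con)
  invisible(path)
}

#' Build a run manifest
#'
#' Captures what produced a set of output files: configuration hash,
#' parameter fingerprint, seed, package version, timestamp and the file
#' list.  The hash covers only the inputs, so identical inputs and seed
#' give an identical `config_hash` across reruns.
#'
#' @param params Parameter set used.
#' @param scenario Scenario used.
#' @param outputs Character vector of output file paths.
#' @param seed Seed used (or `NA`).
#' @return A manifest list.
#' @export
run_manifest <- function(params, scenario, outputs, seed = NA) {
  params <- as_parameters(params)
  inputs <- list(parameters = as.list(unclass(params)),
                 scenario = unclass(scenario)[!vapply(unclass(scenario),
                                                      is.null, TRUE)],
                 seed = seed)
  list(schema_version = .schema_version,
       tool = "postmi",
       tool_version = as.character(packageVersion("postmi")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config_hash = fingerprint(inputs),
       parameter_fingerprint = fingerprint(as.list(unclass(params))),
       outputs = outputs)
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path Output `.json` path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
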