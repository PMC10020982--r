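#' Load a run configuration
#'
#' Reads a simulation configuration from a JSON (or YAML, by file
#' extension) document: niche capacity `K`, one block of rates per clone
#' (`b`, `u`, `r`, `d_A`, `d_I`, optional `label`), optional `downstream`
#' progenitor-pool block, initial state (`"equilibrium"` or explicit
#' `N`/`A`/`I` vectors), `t_span`, an optional `events` list, solver
#' tolerances and a seed. Defaults are filled in; validation errors name
#' the offending key.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` list with elements `params`
#'   ([system_params()]), `init`, `t_span`, `events` (tibble),
#'   `output_times`, `rtol`, `atol`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  as_run_config(raw)
}

#' Build system parameters from a plain list
#'
#' Converts the `{K, clones, downstream}` block of a configuration
#' document (as parsed from JSON/YAML) into a [system_params()] object,
#' validating every key.
#'
#' @param raw A list with elements `K`, `clones` (list of lists with keys
#'   `b`, `u`, `r`, `d_A`, `d_I`, optional `label`) and optionally
#'   `downstream`.
#' @return A [system_params()] object.
#' @export
params_from_list <- function(raw) {
  if (is.null(raw$K)) stop("config is missing required key `K`", call. = FALSE)
  if (is.null(raw$clones) || length(raw$clones) == 0L) {
    stop("config is missing required key `clones`", call. = FALSE)
  }
  clones <- lapply(raw$clones, function(cl) {
    for (nm in c("b", "u", "r", "d_A", "d_I")) {
      if (is.null(cl[[nm]])) {
        stop(sprintf("clone block is missing key `%s`", nm), call. = FALSE)
      }
    }
    clone_params(cl$b, cl$u, cl$r, cl$d_A, cl$d_I, label = cl$label)
  })
  system_params(raw$K, clones, downstream = raw$downstream)
}

as_run_config <- function(raw) {
  params <- params_from_list(raw)
  init <- raw$init %||% "equilibrium"
  if (!identical(init, "equilibrium")) {
    init <- make_state(params, N = unlist(init$N),
                       A = unlist(init$A %||% 0), I = unlist(init$I %||% 0),
                       D = if (!is.null(params$downstream)) unlist(init$D %||% 0))
  }
  events <- if (is.null(raw$events)) empty_events() else {
    dplyr::bind_rows(lapply(raw$events, function(e) {
      for (nm in c("time", "kind", "magnitude")) {
        if (is.null(e[[nm]])) {
          stop(sprintf("event is missing key `%s`", nm), call. = FALSE)
        }
      }
      new_event(e$time, e$kind, e$clone, e$target %||% NA_character_,
                e$magnitude)
    }))
  }
  t_span <- unlist(raw$t_span %||% c(0, 100))
  rtol <- raw$rtol %||% 1e-9
  atol <- raw$atol %||% 1e-12
  if (rtol <= 0 || atol <= 0) {
    stop("`rtol` and `atol` must be positive", call. = FALSE)
  }
  structure(list(params = params, init = init, t_span = t_span,
                 events = events,
                 output_times = if (!is.null(raw$output_times))
                   unlist(raw$output_times),
                 rtol = rtol, atol = atol, seed = raw$seed),
            class = "run_config")
}

#' Write a run configuration
#'
#' Inverse of [load_config()]; the written JSON round-trips to an identical
#' configuration.
#'
#' @param config A `run_config`.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  raw <- list(
    K = p$K,
    clones = lapply(p$clones, function(cl) {
      cl[c("b", "u", "r", "d_A", "d_I", "label")]
    }),
    downstream = p$downstream,
    init = if (identical(config$init, "equilibrium")) "equilibrium" else {
      s <- unpack_state(config$init, p)
      lapply(s, unname)
    },
    t_span = config$t_span,
    events = if (nrow(config$events)) {
      lapply(seq_len(nrow(config$events)), function(i) {
        as.list(config$events[i, ])
      })
    },
    output_times = config$output_times,
    rtol = config$rtol, atol = config$atol, seed = config$seed
  )
  raw <- raw[!vapply(raw, is.null, logical(1))]
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a loaded configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return A `niche_trajectory`.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_niche(config$params, config$init, config$t_span,
                 events = config$events, output_times = config$output_times,
                 rtol = config$rtol, atol = config$atol)
}

#' Write / read a trajectory as tidy CSV
#'
#' One row per (time, clone, compartment) with full floating-point
#' precision, so a write/read cycle is lossless.
#'
#' @param traj A `niche_trajectory` (or any tibble with columns `time`,
#'   `clone` and per-compartment value columns).
#' @param path CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble with one column per compartment,
#'   clones ordered as written.
#' @export
write_trajectory <- function(traj, path) {
  long <- if (all(c("compartment", "value") %in% names(traj))) {
    tibble::as_tibble(traj)
  } else {
    tidy_trajectory(traj)
  }
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            time = "d", clone = "c", compartment = "c",
                            value = "d"))
  if (nrow(long) == 0L) {
    return(tibble::tibble(time = numeric(), clone = character()))
  }
  wide <- tidyr::pivot_wider(long, names_from = "compartment",
                             values_from = "value")
  dplyr::arrange(wide, .data$time, factor(.data$clone,
                                          levels = unique(long$clone)))
}
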