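#' Timed intervention events
#'
#' Build an event schedule for [simulate_niche()] / [run_schedule()]. Four
#' kinds of events are supported, mirroring the interventions studied with
#' this model: persistent parameter changes (`event_scale`, `event_set`,
#' e.g. doubling the attachment rate to emulate niche-affinity changes, or a
#' transient detachment increase to emulate mobilizing agents), transplants
#' (`event_add`, cells entering the unbound inactive pool by default, since
#' only inactive cells can home to the niche) and preconditioning or blood
#' loss (`event_kill`, a fractional kill of chosen compartments).
#'
#' @param ... Events built with `event_scale()`, `event_set()`,
#'   `event_add()` or `event_kill()`, or tibbles of such events.
#' @return A tibble with columns `time`, `kind`, `clone`, `target`,
#'   `magnitude`, sorted by time.
#' @examples
#' niche_events(event_scale(1, "u", 2))           # double detachment at day 1
#' niche_events(event_add(0, 20, clone = 2))      # transplant 20 cells
#' @export
niche_events <- function(...) {
  ev <- dplyr::bind_rows(...)
  if (nrow(ev) == 0L) return(empty_events())
  dplyr::arrange(ev, .data$time)
}

empty_events <- function() {
  tibble::tibble(time = numeric(), kind = character(), clone = integer(),
                 target = character(), magnitude = numeric())
}

new_event <- function(time, kind, clone, target, magnitude) {
  tibble::tibble(time = time, kind = kind,
                 clone = if (is.null(clone)) NA_integer_ else as.integer(clone),
                 target = target, magnitude = magnitude)
}

#' @rdname niche_events
#' @param time Event time, days.
#' @param param Parameter name: one of `"b"`, `"u"`, `"r"`, `"d_A"`,
#'   `"d_I"`, `"K"`.
#' @param factor Multiplicative factor applied to the parameter.
#' @param clone Clone index; `NULL` applies to all clones (required for
#'   `"K"`).
#' @export
event_scale <- function(time, param, factor, clone = NULL) {
  stopifnot(factor >= 0)
  new_event(time, "scale_param", clone, param, factor)
}

#' @rdname niche_events
#' @param value New parameter value.
#' @export
event_set <- function(time, param, value, clone = NULL) {
  stopifnot(value >= 0)
  new_event(time, "set_param", clone, param, value)
}

#' @rdname niche_events
#' @param cells Number of cells added (>= 0).
#' @param compartment Compartment receiving the cells; default `"I"`.
#' @export
event_add <- function(time, cells, clone = 1L, compartment = "I") {
  stopifnot(cells >= 0)
  new_event(time, "add_cells", clone, compartment, cells)
}

#' @rdname niche_events
#' @param fraction Fraction killed, in `[0, 1]`.
#' @param compartments Compartments affected; default all.
#' @export
event_kill <- function(time, fraction, clone = NULL,
                       compartments = c("N", "A", "I", "D")) {
  stopifnot(fraction >= 0, fraction <= 1)
  new_event(time, "kill_fraction", clone,
            paste(compartments, collapse = "+"), fraction)
}

validate_events <- function(events, params, t_span) {
  if (is.null(events) || nrow(events) == 0L) return(empty_events())
  stopifnot(all(c("time", "kind", "clone", "target", "magnitude") %in%
                  names(events)))
  nc <- n_clones(params)
  bad <- !is.na(events$clone) & (events$clone < 1L | events$clone > nc)
  if (any(bad)) {
    stop(sprintf("event references unknown clone %d", events$clone[bad][1L]),
         call. = FALSE)
  }
  pars <- events$kind %in% c("scale_param", "set_param")
  ok <- events$target[pars] %in% c("b", "u", "r", "d_A", "d_I", "K")
  if (!all(ok)) {
    stop(sprintf("unknown event target `%s`",
                 events$target[pars][!ok][1L]), call. = FALSE)
  }
  if (any(events$time < t_span[1] - 1e-12 | events$time > t_span[2] + 1e-12)) {
    stop("event times must lie within t_span", call. = FALSE)
  }
  dplyr::arrange(events, .data$time)
}

apply_event <- function(ev, params, y) {
  nc <- n_clones(params)
  idx <- if (is.na(ev$clone)) seq_len(nc) else ev$clone
  if (ev$kind %in% c("scale_param", "set_param")) {
    if (ev$target == "K") {
      params$K <- if (ev$kind == "scale_param") params$K * ev$magnitude else ev$magnitude
    } else {
      for (j in idx) {
        old <- params$clones[[j]][[ev$target]]
        params$clones[[j]][[ev$target]] <-
          if (ev$kind == "scale_param") old * ev$magnitude else ev$magnitude
      }
    }
  } else if (ev$kind == "add_cells") {
    comp <- match(ev$target, c("N", "A", "I", "D"))
    if (is.na(comp) || (comp == 4L && is.null(params$downstream))) {
      stop(sprintf("unknown compartment `%s` in add_cells event", ev$target),
           call. = FALSE)
    }
    for (j in idx) y[(comp - 1L) * nc + j] <- y[(comp - 1L) * nc + j] + ev$magnitude
  } else if (ev$kind == "kill_fraction") {
    comps <- strsplit(ev$target, "+", fixed = TRUE)[[1L]]
    for (comp in match(comps, c("N", "A", "I", "D"))) {
      if (is.na(comp) || (comp == 4L && is.null(params$downstream))) next
      for (j in idx) y[(comp - 1L) * nc + j] <- y[(comp - 1L) * nc + j] * (1 - ev$magnitude)
    }
  } else {
    stop(sprintf("unknown event kind `%s`", ev$kind), call. = FALSE)
  }
  list(params = params, state = y)
}
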