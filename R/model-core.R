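# State vectors are plain named numerics laid out as
#   N1..Nnc, A1..Anc, I1..Inc [, D1..Dnc]
# (niche-bound, active unbound, inactive unbound, optional progenitor pool).

state_names <- function(params) {
  nc <- n_clones(params)
  nm <- c(paste0("N", seq_len(nc)), paste0("A", seq_len(nc)),
          paste0("I", seq_len(nc)))
  if (!is.null(params$downstream)) nm <- c(nm, paste0("D", seq_len(nc)))
  nm
}

#' Build a state vector
#'
#' @param params A [system_params()] object.
#' @param N,A,I Per-clone counts of niche-bound, active unbound and inactive
#'   unbound stem cells (recycled to the number of clones).
#' @param D Optional per-clone progenitor-pool counts; required when
#'   `params$downstream` is set.
#' @return A named numeric state vector.
#' @export
make_state <- function(params, N, A = 0, I = 0, D = NULL) {
  nc <- n_clones(params)
  N <- rep_len(N, nc); A <- rep_len(A, nc); I <- rep_len(I, nc)
  y <- c(N, A, I)
  if (!is.null(params$downstream)) y <- c(y, rep_len(D %||% 0, nc))
  names(y) <- state_names(params)
  validate_state(y, params)
  y
}

validate_state <- function(state, params, tol = 1e-8) {
  nc <- n_clones(params)
  need <- if (is.null(params$downstream)) 3L * nc else 4L * nc
  if (length(state) != need) {
    stop(sprintf("state has length %d, expected %d", length(state), need),
         call. = FALSE)
  }
  if (any(state < -tol)) {
    stop("state has negative components", call. = FALSE)
  }
  if (sum(state[seq_len(nc)]) > params$K * (1 + tol) + tol) {
    stop("niche-bound cells exceed capacity K", call. = FALSE)
  }
  invisible(state)
}

unpack_state <- function(state, params) {
  nc <- n_clones(params)
  out <- list(N = state[seq_len(nc)], A = state[nc + seq_len(nc)],
              I = state[2L * nc + seq_len(nc)])
  if (!is.null(params$downstream)) out$D <- state[3L * nc + seq_len(nc)]
  out
}

#' Time derivative of the niche model
#'
#' The deterministic rates of change for clones sharing a finite niche.
#' Inactive unbound cells attach to empty niche spaces by mass action
#' (`b * I * E` with `E = K - sum(N)`), bound cells detach and activate
#' (`u * N`), active cells leave by division or differentiation
#' (`(r + d_A) * A`) and each division returns two inactive daughters
#' (`2 * r * A`). Differentiation (`d_A * A + d_I * I`) is the only sink;
#' the division factor 2 is the only source. With the optional progenitor
#' pool, `dD = amp * (d_A * A + d_I * I) - clear * D`.
#'
#' @param state A state vector from [make_state()].
#' @param params A [system_params()] object.
#' @param t Time (days); the system is autonomous, so `t` is unused.
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' niche_rhs(make_state(p0, N = 70, A = 28 / 3, I = 14 / 3), p0)
#' @export
niche_rhs <- function(state, params, t = 0) {
  validate_state(state, params)
  d <- rhs_core(t, unname(state), params)[[1L]]
  names(d) <- state_names(params)
  d
}

# deSolve-facing rhs; no validation in the hot path
rhs_core <- function(t, y, params) {
  nc <- length(params$clones)
  rt <- params$.rates %||% clone_rates(params)
  N <- y[seq_len(nc)]; A <- y[nc + seq_len(nc)]; I <- y[2L * nc + seq_len(nc)]
  E <- params$K - sum(N)
  attach <- rt$b * I * E
  diff_out <- rt$d_A * A + rt$d_I * I
  dN <- attach - rt$u * N
  dA <- rt$u * N - (rt$r + rt$d_A) * A
  dI <- 2 * rt$r * A - attach - rt$d_I * I
  if (is.null(params$downstream)) return(list(c(dN, dA, dI)))
  D <- y[3L * nc + seq_len(nc)]
  dD <- params$downstream$amp * diff_out - params$downstream$clear * D
  list(c(dN, dA, dI, dD))
}

#' Progenitor-production flux
#'
#' The number of stem cells per clone differentiating into progenitors per
#' day, `d_A * A + d_I * I`. Mature blood-cell production scales with this
#' flux, so it is the model's proxy for peripheral output. At a
#' single-clone equilibrium it equals `r * u * (K - E*) / (r + d_A)`.
#'
#' @inheritParams niche_rhs
#' @return Named numeric vector, one non-negative flux per clone
#'   (cells/day).
#' @export
progenitor_flux <- function(state, params) {
  validate_state(state, params)
  s <- unpack_state(state, params)
  rt <- clone_rates(params)
  fl <- rt$d_A * s$A + rt$d_I * s$I
  names(fl) <- clone_labels(params)
  fl
}

#' Simulate the niche model
#'
#' Integrates the model with a stiff-capable solver (`deSolve::ode`,
#' `lsoda`), restarting the integration exactly at every event time so that
#' discontinuous interventions (parameter changes, cell additions,
#' fractional kills) are handled without smoothing. The output grid is
#' decoupled from the solver's internal steps.
#'
#' @param params A [system_params()] object.
#' @param init Initial state from [make_state()], or `"equilibrium"` to
#'   start a single clone at its homeostatic equilibrium.
#' @param t_span Length-2 numeric, start and end time (days).
#' @param events Optional event schedule built with [niche_events()];
#'   event times must lie within `t_span`.
#' @param output_times Time grid for the returned trajectory; defaults to
#'   201 equally spaced points over `t_span`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `niche_trajectory` tibble with columns `time`, `clone`, `N`,
#'   `A`, `I` (plus `D` if a progenitor pool is configured) and `flux`, the
#'   progenitor-production flux recomputed from the stored state.
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' traj <- simulate_niche(p0, make_state(p0, N = 50), c(0, 2000))
#' dplyr::last(traj$N)
#' @export
simulate_niche <- function(params, init, t_span, events = NULL,
                           output_times = NULL, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "system_params"))
  if (identical(init, "equilibrium")) init <- equilibrium_state(params)
  validate_state(init, params)
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(output_times)) {
    output_times <- seq(t_span[1], t_span[2], length.out = 201L)
  }
  output_times <- sort(unique(output_times))
  if (output_times[1] < t_span[1] - 1e-12 ||
      output_times[length(output_times)] > t_span[2] + 1e-12) {
    stop("output_times must lie within t_span", call. = FALSE)
  }

  ev <- validate_events(events, params, t_span)
  cuts <- sort(unique(c(t_span, if (nrow(ev)) ev$time)))
  y <- unname(init)
  cur <- params
  rows <- vector("list", length(cuts) - 1L)

  for (seg in seq_len(length(cuts) - 1L)) {
    t0 <- cuts[seg]; t1 <- cuts[seg + 1L]
    here <- ev[abs(ev$time - t0) < 1e-12, , drop = FALSE]
    for (k in seq_len(nrow(here))) {
      upd <- apply_event(here[k, ], cur, y)
      cur <- upd$params; y <- upd$state
    }
    grid <- output_times[output_times > t0 + 1e-12 & output_times < t1 - 1e-12]
    times <- unique(c(t0, grid, t1))
    rt <- clone_rates(cur)
    cur$.rates <- rt
    sol <- deSolve::ode(y = y, times = times, func = rhs_core, parms = cur,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("integration failed near t = %g", max(sol[, 1L])),
           call. = FALSE)
    }
    # progenitor flux under the parameters in force during this segment
    nc <- n_clones(cur)
    A <- sol[, 1L + nc + seq_len(nc), drop = FALSE]
    I <- sol[, 1L + 2L * nc + seq_len(nc), drop = FALSE]
    flux <- sweep(A, 2L, rt$d_A, `*`) + sweep(I, 2L, rt$d_I, `*`)
    keep <- times %in% output_times | times == t1
    rows[[seg]] <- cbind(sol, flux)[keep, , drop = FALSE]
    y <- unname(sol[nrow(sol), -1L])
  }
  out <- do.call(rbind, rows)
  # at an event time keep the post-event row (the state integration
  # continued from)
  out <- out[!duplicated(out[, 1L], fromLast = TRUE), , drop = FALSE]
  out <- out[out[, 1L] %in% output_times, , drop = FALSE]
  new_trajectory(out, params)
}

# sol: [time, states..., flux_1..flux_nc] with flux precomputed per segment
new_trajectory <- function(sol, params) {
  nc <- n_clones(params)
  lab <- clone_labels(params)
  times <- sol[, 1L]
  nstate <- if (is.null(params$downstream)) 3L * nc else 4L * nc
  pieces <- lapply(seq_len(nc), function(j) {
    N <- sol[, 1L + j]; A <- sol[, 1L + nc + j]; I <- sol[, 1L + 2L * nc + j]
    tb <- tibble::tibble(time = times, clone = lab[j], N = unname(N),
                         A = unname(A), I = unname(I))
    if (!is.null(params$downstream)) tb$D <- unname(sol[, 1L + 3L * nc + j])
    tb$flux <- unname(sol[, 1L + nstate + j])
    tb
  })
  traj <- dplyr::arrange(dplyr::bind_rows(pieces), .data$time, .data$clone)
  attr(traj, "system_params") <- params
  class(traj) <- c("niche_trajectory", class(traj))
  traj
}

#' Final state of a trajectory
#'
#' @param traj A `niche_trajectory`.
#' @return A state vector usable as `init` for a follow-up simulation.
#' @export
final_state <- function(traj) {
  params <- attr(traj, "system_params")
  last <- dplyr::filter(traj, .data$time == max(.data$time))
  last <- last[match(clone_labels(params), last$clone), ]
  make_state(params, N = pmax(last$N, 0), A = pmax(last$A, 0),
             I = pmax(last$I, 0),
             D = if (!is.null(params$downstream)) pmax(last$D, 0))
}

#' Pivot a trajectory to one row per (time, clone, compartment)
#'
#' @param traj A `niche_trajectory`.
#' @return Tibble with columns `time`, `clone`, `compartment`
#'   (one of N, A, I, D, flux) and `value`.
#' @export
tidy_trajectory <- function(traj) {
  tidyr::pivot_longer(tibble::as_tibble(traj),
                      cols = -c("time", "clone"),
                      names_to = "compartment", values_to = "value")
}
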