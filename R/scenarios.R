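#' Run an intervention schedule
#'
#' Thin wrapper around [simulate_niche()] for event-driven scenario runs:
#' events are sorted by time and the integration restarts exactly at each
#' event, so parameter steps, transplanted-cell additions and fractional
#' kills are applied discontinuously.
#'
#' @inheritParams simulate_niche
#' @param events Event schedule from [niche_events()].
#' @return A `niche_trajectory`.
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' run_schedule(p0, "equilibrium", niche_events(event_scale(1, "u", 2)),
#'              t_span = c(0, 200))
#' @export
run_schedule <- function(params, init, events, t_span, output_times = NULL,
                         rtol = 1e-9, atol = 1e-12) {
  simulate_niche(params, init, t_span, events = events,
                 output_times = output_times, rtol = rtol, atol = atol)
}

#' Simulate a transplantation protocol
#'
#' The host clones start at homeostatic equilibrium; optional
#' preconditioning kills a fraction of all host compartments at time 0;
#' optional mobilization temporarily scales the detachment rate of all
#' niche-resident clones (mobilizing agents are not clone-selective); the
#' donor graft enters the unbound inactive pool, either as a single dose or
#' split into `n_doses` portions `dose_interval` days apart. Splitting the
#' graft exploits niche turnover: between doses some host cells detach and
#' free niche spaces that the next donor portion can fill.
#'
#' @param host A [system_params()] for the host clone(s).
#' @param donor A [clone_params()] for the donor graft.
#' @param total_dose Total transplanted cells across all doses.
#' @param n_doses Number of portions (>= 1).
#' @param dose_interval Days between portions (> 0 when `n_doses > 1`).
#' @param preconditioning_fraction Fraction of host cells killed at time 0,
#'   in `[0, 1]`.
#' @param mobilization Optional `list(days =, u_multiplier =)`: detachment
#'   rates of all pre-existing clones are multiplied by `u_multiplier` from
#'   time 0 for `days` days; the first transplant dose is given when the
#'   pulse ends.
#' @param endpoint Evaluation time, days (default 365).
#' @param host_fractions Initial niche fractions of the host clones
#'   (multi-clone hosts); default the first host clone's monoclonal
#'   equilibrium split equally.
#' @inheritParams simulate_niche
#' @return A `protocol_result` list: `endpoint`, `chimerism` (donor share
#'   of niche-bound cells at the endpoint), `burden` (tibble of per-clone
#'   niche-bound and total stem cells at the endpoint) and `trajectory`.
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' donor <- clone_params(0.1, 0.2, 1, 0.5, 1, label = "donor")
#' transplant_protocol(p0, donor, total_dose = 20, n_doses = 4,
#'                     dose_interval = 1)$chimerism
#' @export
transplant_protocol <- function(host, donor, total_dose, n_doses = 1L,
                                dose_interval = 1, preconditioning_fraction = 0,
                                mobilization = NULL, endpoint = 365,
                                host_fractions = NULL, rtol = 1e-9,
                                atol = 1e-12) {
  stopifnot(inherits(host, "system_params"), inherits(donor, "clone_params"))
  if (n_doses < 1L) stop("`n_doses` must be at least 1", call. = FALSE)
  if (n_doses > 1L && dose_interval <= 0) {
    stop("`dose_interval` must be positive when n_doses > 1", call. = FALSE)
  }
  stopifnot(preconditioning_fraction >= 0, preconditioning_fraction <= 1)

  nh <- n_clones(host)
  donor$label <- donor$label %||% "donor"
  params <- system_params(host$K, c(host$clones, list(donor)),
                          downstream = host$downstream)
  host_eq <- equilibrium_state(
    host, fractions = host_fractions %||% rep(1 / nh, nh))
  s <- unpack_state(host_eq, host)
  init <- make_state(params, N = c(s$N, 0), A = c(s$A, 0), I = c(s$I, 0),
                     D = if (!is.null(host$downstream)) c(s$D, 0))

  ev <- list()
  if (preconditioning_fraction > 0) {
    for (j in seq_len(nh)) {
      ev <- c(ev, list(event_kill(0, preconditioning_fraction, clone = j)))
    }
  }
  t_first_dose <- 0
  if (!is.null(mobilization)) {
    stopifnot(is.numeric(mobilization$days), mobilization$days >= 0,
              mobilization$u_multiplier >= 0)
    if (mobilization$days > 0 && mobilization$u_multiplier != 1) {
      for (j in seq_len(nh)) {
        ev <- c(ev, list(
          event_scale(0, "u", mobilization$u_multiplier, clone = j),
          event_scale(mobilization$days, "u", 1 / mobilization$u_multiplier,
                      clone = j)))
      }
    }
    t_first_dose <- mobilization$days
  }
  dose_times <- numeric()
  if (total_dose > 0) {
    dose_times <- t_first_dose + (seq_len(n_doses) - 1L) * dose_interval
    if (max(dose_times) >= endpoint) {
      stop("dosing schedule extends beyond the endpoint", call. = FALSE)
    }
    for (td in dose_times) {
      ev <- c(ev, list(event_add(td, total_dose / n_doses, clone = nh + 1L)))
    }
  }

  traj <- simulate_niche(params, init, c(0, endpoint),
                         events = do.call(niche_events, ev),
                         output_times = unique(sort(c(
                           seq(0, endpoint, length.out = 201L), dose_times))),
                         rtol = rtol, atol = atol)
  fin <- unpack_state(final_state(traj), params)
  burden <- tibble::tibble(clone = clone_labels(params),
                           niche = unname(fin$N),
                           total = unname(fin$N + fin$A + fin$I))
  structure(list(endpoint = endpoint,
                 chimerism = unname(fin$N[nh + 1L] / sum(fin$N)),
                 burden = burden, trajectory = traj),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> endpoint %g d, donor niche chimerism %.4f\n",
              x$endpoint, x$chimerism))
  print(x$burden)
  invisible(x)
}

#' Mobilization followed by transplantation against a malignant clone
#'
#' The host niche is populated by a cancer-stem-cell (CSC) clone at its
#' monoclonal equilibrium. The same transplant of healthy donor cells is
#' simulated with and without a preceding mobilization pulse (detachment
#' rates scaled by `u_multiplier` for `mobilization_days` days), and the
#' CSC burden at the endpoint is compared. Mobilization empties niche
#' spaces that donor cells can fill, but detached CSC are prone to divide,
#' so prolonged mobilization expands the malignant population instead.
#'
#' @param host A single-clone [system_params()] describing the CSC clone.
#' @param donor A [clone_params()] for the healthy graft.
#' @param mobilization_days Duration of the mobilization pulse, days.
#' @param u_multiplier Factor applied to the detachment rate during the
#'   pulse.
#' @param transplant_dose Donor cells transplanted (single dose, given when
#'   the pulse ends); 0 simulates mobilization alone.
#' @param endpoint Evaluation time, days.
#' @param burden Which CSC burden to compare: niche-bound cells
#'   (`"niche"`, default) or all CSC stem cells (`"total"`).
#' @return A list with the two `protocol_result`s (`with`, `without`), the
#'   endpoint burdens and `relative_reduction =
#'   (burden_without - burden_with) / burden_without`.
#' @export
mobilization_hsct <- function(host, donor, mobilization_days = 1,
                              u_multiplier = 3, transplant_dose = 50,
                              endpoint = 365, burden = c("niche", "total")) {
  burden <- match.arg(burden)
  run <- function(mult) {
    # both arms transplant when the pulse window ends, so the only
    # difference between them is the detachment multiplier itself
    transplant_protocol(host, donor, total_dose = transplant_dose,
                        n_doses = 1L,
                        mobilization = list(days = mobilization_days,
                                            u_multiplier = mult),
                        endpoint = endpoint)
  }
  without <- run(1)
  with_mob <- run(u_multiplier)
  pick <- function(res) res$burden[[burden]][1L]
  b0 <- pick(without); b1 <- pick(with_mob)
  list(with = with_mob, without = without,
       burden_with = b1, burden_without = b0,
       relative_reduction = (b0 - b1) / b0)
}
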