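#' Design a synthetic observation experiment
#'
#' Describes a simulated experiment whose output has the structure the
#' fitting module expects, emulating the kinds of murine observations this
#' model is calibrated against: recovery of the homeostatic state after a
#' depletion (e.g. blood loss), the decline of stem cells deprived of a
#' niche, or a two-clone competition time course. Measurement noise, when
#' requested, is multiplicative log-normal — cell counts are positive and
#' their measurement error scales with magnitude.
#'
#' @param params Generator [system_params()].
#' @param experiment One of `"recovery_after_depletion"`,
#'   `"no_niche_decline"`, `"competition_timecourse"`.
#' @param times Increasing sampling times, days.
#' @param sigma Log-normal noise scale (standard deviation of log counts);
#'   0 for noiseless data.
#' @param replicates Number of noisy replicates per time point (>= 1).
#' @param seed Optional RNG seed; generation is deterministic given the
#'   seed.
#' @param kill_fraction Depletion fraction for the recovery experiment.
#' @param init_unbound For the no-niche experiment: initial `c(A, I)`
#'   counts per clone.
#' @param fractions Initial niche fractions for the competition time
#'   course.
#' @param compartments Which compartments are observed.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(params, experiment = c("recovery_after_depletion",
                                                    "no_niche_decline",
                                                    "competition_timecourse"),
                             times, sigma = 0, replicates = 1L, seed = NULL,
                             kill_fraction = 0.5, init_unbound = c(10, 10),
                             fractions = c(0.9, 0.1),
                             compartments = c("N", "A", "I")) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(params, "system_params"))
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (replicates < 1L) stop("`replicates` must be at least 1", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(params = params, experiment = experiment, times = times,
                 sigma = sigma, replicates = as.integer(replicates),
                 seed = seed, kill_fraction = kill_fraction,
                 init_unbound = init_unbound, fractions = fractions,
                 compartments = compartments),
            class = "synthetic_design")
}

#' State after a fractional depletion of the equilibrium
#'
#' @param params A [system_params()] object.
#' @param fraction Fraction of every compartment removed.
#' @return A state vector at `(1 - fraction)` times the equilibrium.
#' @export
depleted_state <- function(params, fraction = 0.5) {
  fr <- if (n_clones(params) > 1L) NULL else 1
  equilibrium_state(params, fractions = fr) * (1 - fraction)
}

#' Generate a synthetic dataset
#'
#' Simulates the designed experiment, samples the requested compartments at
#' the design times, applies the noise model and returns both the observed
#' table (ready for [fit_problem()]) and the ground truth.
#'
#' @param design A [synthetic_design()].
#' @return A list with `observed` (tibble: `time`, `clone`, `compartment`,
#'   `replicate`, `count`) and `truth` (list: generator `params`, the
#'   noiseless `trajectory`, and the initial state used).
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' d <- synthetic_design(p0, "recovery_after_depletion", times = 1:10,
#'                       sigma = 0.1, seed = 7)
#' generate_synthetic(d)$observed
#' @export
generate_synthetic <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  params <- design$params
  init <- switch(design$experiment,
    recovery_after_depletion = depleted_state(params, design$kill_fraction),
    no_niche_decline = {
      p <- params; p$K <- 0
      params <- p
      make_state(p, N = 0, A = design$init_unbound[1L],
                 I = design$init_unbound[2L])
    },
    competition_timecourse = {
      if (n_clones(params) < 2L) {
        stop("competition_timecourse needs at least two clones",
             call. = FALSE)
      }
      equilibrium_state(params, design$fractions)
    })
  t0 <- min(0, design$times[1L])
  traj <- simulate_niche(params, init, c(t0, max(design$times)),
                         output_times = sort(unique(c(t0, design$times))))
  long <- tidy_trajectory(traj)
  long$clone_idx <- match(long$clone, clone_labels(params))
  obs <- long[long$time %in% design$times &
                long$compartment %in% design$compartments, ]
  obs <- tidyr::expand_grid(replicate = seq_len(design$replicates),
                            obs)
  if (!is.null(design$seed)) set.seed(design$seed)
  noise <- if (design$sigma > 0) {
    exp(stats::rnorm(nrow(obs), 0, design$sigma))
  } else rep(1, nrow(obs))
  observed <- tibble::tibble(time = obs$time, clone = obs$clone_idx,
                             compartment = obs$compartment,
                             replicate = obs$replicate,
                             count = obs$value * noise)
  list(observed = observed,
       truth = list(params = params, trajectory = traj, init = init))
}
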