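#' Predict the outcome of clonal competition
#'
#' When several clones compete for one finite niche, the clone with the
#' highest fitness [clone_fitness()] eventually excludes all others — an
#' R*-style rule: the winner is the clone that can sustain itself on the
#' fewest empty niches, and the shared niche settles at the winner's
#' monoclonal empty-niche count `E* = 1 / F_winner`. Clones whose fitness
#' agrees within `tolerance` (relative) compete neutrally and coexist with
#' frozen niche composition. If no clone is persistent, all go extinct.
#'
#' @param clones A list of [clone_params()] (at least two).
#' @param tolerance Relative fitness difference below which the top clones
#'   are declared neutral. Any true difference eventually wins given enough
#'   time; how long depends on the specific parameters.
#' @return A `competition_outcome` list with elements `fitness` (tibble of
#'   per-clone fitness), `winner` (clone index, `"neutral"` or
#'   `"extinction"`) and `final_E` (predicted long-run empty-niche count,
#'   `1 / max(F)` when a winner or neutral group exists).
#' @examples
#' c1 <- clone_params(0.1, 0.2, 1, 0.5, 1)
#' c2 <- clone_params(0.1, 0.2, 1.2, 0.5, 1)
#' predict_outcome(list(c1, c2))
#' @export
predict_outcome <- function(clones, tolerance = 1e-9) {
  stopifnot(is.list(clones), length(clones) >= 2L)
  f <- vapply(clones, clone_fitness, numeric(1))
  lab <- vapply(seq_along(clones), function(j) {
    clones[[j]]$label %||% paste0("clone", j)
  }, character(1))
  fit <- tibble::tibble(clone = lab, index = seq_along(clones), fitness = f)
  if (all(f == 0)) {
    out <- list(fitness = fit, winner = "extinction", final_E = NA_real_)
  } else {
    top <- max(f)
    near <- which(f >= top * (1 - tolerance))
    winner <- if (length(near) > 1L) "neutral" else near
    out <- list(fitness = fit, winner = winner, final_E = 1 / top)
  }
  structure(out, class = "competition_outcome")
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat("<competition_outcome> winner:", format(x$winner),
      " predicted final E:", format(x$final_E), "\n")
  print(x$fitness)
  invisible(x)
}

#' Simulate clonal competition for the niche
#'
#' Starts the clones at a shared-niche quasi-equilibrium — the niche filled
#' to the reference clone's monoclonal `N*`, split by `initial_fractions`,
#' unbound pools at their conditional equilibria — and integrates the
#' multi-clone system. Reports, alongside the trajectory, the fitness-based
#' prediction and each losing clone's exclusion time: the first time its
#' niche fraction falls below `threshold` (`NA` if not reached).
#'
#' @param params A multi-clone [system_params()].
#' @param initial_fractions Initial niche fractions per clone (sum <= 1).
#' @param t_span Length-2 time interval, days.
#' @param threshold Niche fraction defining exclusion, default 1%.
#' @param reference Clone whose monoclonal `N*` sets initial occupancy.
#' @inheritParams simulate_niche
#' @return A list with elements `trajectory` (a `niche_trajectory`),
#'   `outcome` (a `competition_outcome`) and `exclusion_times` (named
#'   numeric, `NA` where the threshold was not reached).
#' @examples
#' p <- system_params(100, list(clone_params(0.1, 0.2, 1, 0.5, 1),
#'                              clone_params(0.1, 0.2, 1.2, 0.5, 1)))
#' res <- simulate_competition(p, c(0.9, 0.1), c(0, 400))
#' res$outcome$winner
#' @export
simulate_competition <- function(params, initial_fractions, t_span,
                                 threshold = 0.01, reference = 1L,
                                 output_times = NULL, rtol = 1e-9,
                                 atol = 1e-12) {
  stopifnot(inherits(params, "system_params"), n_clones(params) >= 2L)
  init <- equilibrium_state(params, initial_fractions, reference)
  traj <- simulate_niche(params, init, t_span, output_times = output_times,
                         rtol = rtol, atol = atol)
  outcome <- predict_outcome(params$clones)
  ab <- abundance_metrics(traj)
  lab <- clone_labels(params)
  excl <- vapply(lab, function(cl) {
    sub <- ab[ab$clone == cl & !is.na(ab$niche_fraction) &
                ab$niche_fraction < threshold, ]
    if (nrow(sub) == 0L) NA_real_ else min(sub$time)
  }, numeric(1))
  list(trajectory = traj, outcome = outcome, exclusion_times = excl)
}

#' Clonal abundance in the niche versus in progenitor output
#'
#' For each time point and clone, the fraction of niche-bound stem cells
#' belonging to the clone (`N_j / sum(N)`) and the clone's share of
#' progenitor production (`flux_j / sum(flux)`). The two can diverge
#' strongly: a clone with a higher detachment rate contributes
#' over-proportionally to progenitors (and hence blood) while holding the
#' same share of the niche — which is why minimal residual disease measured
#' in blood or bulk marrow need not reflect the clone's abundance among
#' niche stem cells.
#'
#' @param traj A `niche_trajectory`.
#' @return A tibble with columns `time`, `clone`, `niche_fraction`,
#'   `progenitor_fraction`; fractions are `NA` where the corresponding
#'   total is zero.
#' @export
abundance_metrics <- function(traj) {
  stopifnot(inherits(traj, "niche_trajectory"))
  tibble::as_tibble(traj) |>
    dplyr::group_by(.data$time) |>
    dplyr::mutate(
      niche_fraction = if (sum(.data$N) > 0) .data$N / sum(.data$N)
                       else rep(NA_real_, dplyr::n()),
      progenitor_fraction = if (sum(.data$flux) > 0)
                              .data$flux / sum(.data$flux)
                            else rep(NA_real_, dplyr::n())
    ) |>
    dplyr::ungroup() |>
    dplyr::select("time", "clone", "niche_fraction", "progenitor_fraction")
}
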