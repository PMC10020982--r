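#' Define a parameter-fitting problem
#'
#' Pairs an observed time series with the model configuration needed to
#' reproduce it. Observations are a tidy table with one row per measured
#' count: columns `time`, `clone` (index), `compartment` (one of `N`, `A`,
#' `I`, `D`, `flux`) and `count`. Free parameters are named `"b"`, `"u"`,
#' ... for clone 1 or `"b[2]"` etc. for later clones (`"K"` addresses the
#' capacity). Pairwise-equality constraints tie two parameters together so
#' they move as one during the search.
#'
#' @param observed Observed tibble (`time`, `clone`, `compartment`,
#'   `count`; an optional `replicate` column is allowed).
#' @param params A [system_params()] template providing all fixed values.
#' @param free Character vector of free parameter names.
#' @param equal Optional list of length-2 character vectors; within each
#'   pair the second parameter is set equal to the first.
#' @param init Initial state for the fitting simulations: a state vector,
#'   `"equilibrium"`, or a function of the candidate [system_params()]
#'   returning a state (used when the initial state itself depends on the
#'   parameters, e.g. a depletion experiment starting from equilibrium).
#' @param rtol,atol Solver tolerances used during fitting (looser than the
#'   analysis defaults, for speed).
#' @return A `fit_problem` list.
#' @export
fit_problem <- function(observed, params, free, equal = list(),
                        init = "equilibrium", rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "system_params"))
  need <- c("time", "clone", "compartment", "count")
  if (!all(need %in% names(observed))) {
    stop("observed table needs columns time, clone, compartment, count",
         call. = FALSE)
  }
  observed <- tibble::as_tibble(observed)
  if (!all(observed$compartment %in% c("N", "A", "I", "D", "flux"))) {
    stop("unknown compartment in observed table", call. = FALSE)
  }
  all_names <- unlist(lapply(seq_len(n_clones(params)), function(j) {
    suff <- if (j == 1L) "" else sprintf("[%d]", j)
    paste0(c("b", "u", "r", "d_A", "d_I"), suff)
  }))
  all_names <- c(all_names, "K")
  check <- function(nms, what) {
    bad <- setdiff(nms, all_names)
    if (length(bad)) {
      stop(sprintf("unknown %s parameter `%s`", what, bad[1L]), call. = FALSE)
    }
  }
  check(free, "free")
  for (pair in equal) {
    stopifnot(length(pair) == 2L)
    check(pair, "constrained")
  }
  structure(list(observed = observed, params = params, free = free,
                 equal = equal, init = init, rtol = rtol, atol = atol),
            class = "fit_problem")
}

parse_par_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z_]+)(\\[([0-9]+)\\])?$", name))[[1L]]
  list(param = m[2L], clone = if (m[4L] == "") 1L else as.integer(m[4L]))
}

set_params <- function(params, values) {
  for (nm in names(values)) {
    if (nm == "K") { params$K <- values[[nm]]; next }
    p <- parse_par_name(nm)
    params$clones[[p$clone]][[p$param]] <- values[[nm]]
  }
  params
}

get_params <- function(params, names) {
  vapply(names, function(nm) {
    if (nm == "K") return(params$K)
    p <- parse_par_name(nm)
    params$clones[[p$clone]][[p$param]]
  }, numeric(1))
}

apply_equality <- function(values, equal) {
  for (pair in equal) {
    if (pair[1L] %in% names(values)) values[pair[2L]] <- values[[pair[1L]]]
  }
  values
}

# Model predictions at the observed (time, clone, compartment) triples.
# Bypasses trajectory assembly: one deSolve call, then matrix indexing.
predict_observed <- function(values, problem) {
  params <- set_params(problem$params, apply_equality(values, problem$equal))
  init <- problem$init
  if (is.function(init)) init <- init(params)
  if (identical(init, "equilibrium")) init <- equilibrium_state(params)
  obs <- problem$observed
  t0 <- min(0, obs$time)
  times <- sort(unique(c(t0, obs$time)))
  rt <- clone_rates(params)
  params$.rates <- rt
  sol <- deSolve::ode(y = unname(init), times = times, func = rhs_core,
                      parms = params, method = "lsoda",
                      rtol = problem$rtol, atol = problem$atol)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times)) {
    stop("integration failed", call. = FALSE)
  }
  nc <- n_clones(params)
  ti <- match(obs$time, times)
  comp <- match(obs$compartment, c("N", "A", "I", "D"))
  out <- numeric(nrow(obs))
  plain <- !is.na(comp)
  out[plain] <- sol[cbind(ti[plain],
                          1L + (comp[plain] - 1L) * nc + obs$clone[plain])]
  if (any(!plain)) {  # flux = d_A * A + d_I * I
    j <- obs$clone[!plain]
    A <- sol[cbind(ti[!plain], 1L + nc + j)]
    I <- sol[cbind(ti[!plain], 1L + 2L * nc + j)]
    out[!plain] <- rt$d_A[j] * A + rt$d_I[j] * I
  }
  out
}

#' Sum-of-squared-residuals cost
#'
#' `sum((observed - predicted)^2)` between the observed counts and the
#' model trajectory simulated at the candidate parameter values; zero iff
#' the fit is perfect. A failed simulation yields `Inf`, so such proposals
#' are rejected during annealing.
#'
#' @param values Named numeric vector of free-parameter values.
#' @param problem A [fit_problem()].
#' @return Non-negative scalar cost.
#' @export
ssr_cost <- function(values, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  if (any(values < 0)) return(Inf)
  pred <- NULL
  # capture.output silences the solver's diagnostic prints when a wild
  # proposal makes the integration fail; such proposals simply cost Inf
  utils::capture.output(
    pred <- tryCatch(suppressWarnings(predict_observed(values, problem)),
                     error = function(e) NULL))
  if (is.null(pred) || anyNA(pred)) return(Inf)
  sum((problem$observed$count - pred)^2)
}

#' Fit parameters by simulated annealing
#'
#' Metropolis search over positive parameter values with geometric cooling
#' (`T_k = T0 * alpha^k`) and multiplicative log-normal proposals, which
#' keep parameters positive without imposing an upper bound. The proposal
#' scale is mildly adapted to hold the acceptance rate near 30%. With
#' `t0 = 0` the search degenerates to pure downhill (greedy) descent.
#' Equality-constrained pairs move as one throughout.
#'
#' Raw parameters of this model are not uniquely identifiable from
#' trajectory data alone, so alongside the best parameters the result
#' carries the identifiable derived summaries of each clone: fitness `F`,
#' empty-niche count `E*`, the inactive/active ratio and the equilibrium
#' progenitor flux. Recovery should be judged on these.
#'
#' @param problem A [fit_problem()].
#' @param init Named numeric vector of starting values for the free
#'   parameters (positive).
#' @param t0 Initial temperature; default the cost at `init`.
#' @param alpha Geometric cooling factor per iteration.
#' @param sigma Initial log-normal proposal scale.
#' @param adapt Adapt `sigma` toward 30% acceptance every 200 iterations?
#' @param max_iter Number of annealing iterations.
#' @param polish Number of zero-temperature downhill iterations run from
#'   the best-ever point after annealing (small fixed step, scale 0.02);
#'   default a fifth of `max_iter`, 0 to disable.
#' @param seed Optional RNG seed for reproducibility.
#' @return A `niche_fit` object: best parameters (`par`), `cost`, the
#'   per-iteration `trace` tibble, `seed`, acceptance rate and `summaries`
#'   (per-clone identifiable quantities at the best fit).
#' @examples
#' \donttest{
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' design <- synthetic_design(p0, "recovery_after_depletion",
#'                            times = seq(1, 40, by = 3))
#' obs <- generate_synthetic(design)$observed
#' prob <- fit_problem(obs, p0, free = c("b", "u"),
#'                     init = function(p) depleted_state(p, 0.5))
#' fit <- anneal_fit(prob, init = c(b = 0.2, u = 0.1), max_iter = 500,
#'                   seed = 1)
#' glance(fit)
#' }
#' @export
anneal_fit <- function(problem, init, t0 = NULL, alpha = 0.999,
                       sigma = 0.05, adapt = TRUE, max_iter = 20000L,
                       polish = round(max_iter / 5), seed = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  if (max_iter < 1L) stop("`max_iter` must be at least 1", call. = FALSE)
  if (!all(problem$free %in% names(init))) {
    stop("`init` must name every free parameter", call. = FALSE)
  }
  init <- init[problem$free]
  if (any(init <= 0)) stop("initial parameters must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  cur <- init
  cur_cost <- ssr_cost(cur, problem)
  if (!is.finite(cur_cost)) {
    stop("simulation fails at the initial parameters", call. = FALSE)
  }
  if (is.null(t0)) t0 <- cur_cost
  best <- cur; best_cost <- cur_cost
  np <- length(cur)
  trace_cost <- numeric(max_iter)
  accepted <- logical(max_iter)
  window_acc <- 0L

  for (k in seq_len(max_iter)) {
    temp <- t0 * alpha^k
    prop <- cur * exp(stats::rnorm(np, 0, sigma))
    prop_cost <- ssr_cost(prop, problem)
    take <- if (!is.finite(prop_cost)) FALSE
      else if (prop_cost <= cur_cost) TRUE
      else temp > 0 && stats::runif(1) < exp(-(prop_cost - cur_cost) / temp)
    if (take) {
      cur <- prop; cur_cost <- prop_cost
      window_acc <- window_acc + 1L
      if (cur_cost < best_cost) { best <- cur; best_cost <- cur_cost }
    }
    accepted[k] <- take
    trace_cost[k] <- cur_cost
    if (adapt && k %% 200L == 0L) {
      rate <- window_acc / 200
      sigma <- min(max(sigma * exp(0.5 * (rate - 0.3)), 1e-3), 0.5)
      window_acc <- 0L
    }
  }

  # downhill polish from the best-ever point: the annealing phase locates
  # the basin, a zero-temperature phase with small steps refines within it
  if (polish > 0L) {
    cur <- best; cur_cost <- best_cost
    psig <- 0.02
    for (k in seq_len(polish)) {
      prop <- cur * exp(stats::rnorm(np, 0, psig))
      prop_cost <- ssr_cost(prop, problem)
      if (is.finite(prop_cost) && prop_cost <= cur_cost) {
        cur <- prop; cur_cost <- prop_cost
      }
      if (cur_cost < best_cost) { best <- cur; best_cost <- cur_cost }
    }
  }

  best_params <- set_params(problem$params,
                            apply_equality(best, problem$equal))
  summaries <- dplyr::bind_rows(lapply(seq_len(n_clones(best_params)),
    function(j) {
      cl <- best_params$clones[[j]]
      f <- clone_fitness(cl)
      eq <- monoclonal_equilibrium(system_params(best_params$K, cl))
      tibble::tibble(clone = cl$label %||% paste0("clone", j),
                     fitness = f,
                     E_star = empty_niche_equilibrium(cl),
                     IA_ratio = if (cl$d_I > 0) (cl$r - cl$d_A) / cl$d_I
                                else NA_real_,
                     flux_star = eq$flux_star)
    }))
  structure(list(par = best, cost = best_cost,
                 trace = tibble::tibble(iteration = seq_len(max_iter),
                                        cost = trace_cost,
                                        accepted = accepted),
                 accept_rate = mean(accepted), seed = seed,
                 problem = problem, params = best_params,
                 summaries = summaries),
            class = "niche_fit")
}

#' @export
print.niche_fit <- function(x, ...) {
  cat(sprintf("<niche_fit> cost %.6g after %d iterations (accept %.1f%%)\n",
              x$cost, nrow(x$trace), 100 * x$accept_rate))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters
#'
#' @param x A `niche_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy niche_fit
#' @export
tidy.niche_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row fit summary
#'
#' @param x A `niche_fit`.
#' @param ... Unused.
#' @return A one-row tibble: final cost, iterations, acceptance rate, seed
#'   and the first clone's identifiable summaries.
#' @method glance niche_fit
#' @export
glance.niche_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, iterations = nrow(x$trace),
                 accept_rate = x$accept_rate,
                 seed = x$seed %||% NA_integer_,
                 fitness = x$summaries$fitness[1L],
                 E_star = x$summaries$E_star[1L])
}
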