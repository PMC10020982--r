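#' Clonal fitness
#'
#' The invasion fitness of a stem-cell clone,
#' `F = (b / d_I) * (r - d_A) / (r + d_A)`: the better new stem-cell
#' production outweighs differentiation loss, the higher the fitness. In
#' competition for a shared niche the clone with the highest `F` excludes
#' all others; `F` is independent of the detachment rate `u`, and equals the
#' reciprocal of the clone's monoclonal empty-niche count
#' ([empty_niche_equilibrium()]). A non-persistent clone (`r <= d_A`) is
#' assigned fitness 0 so that orderings remain total.
#'
#' @param clone A [clone_params()] object.
#' @return Non-negative scalar fitness.
#' @examples
#' clone_fitness(clone_params(0.1, 0.2, 1, 0.5, 1))  # 1/30
#' @export
clone_fitness <- function(clone) {
  stopifnot(inherits(clone, "clone_params"))
  if (clone$r + clone$d_A == 0) {
    stop("fitness undefined when r + d_A = 0", call. = FALSE)
  }
  if (!is_persistent(clone)) return(0)
  if (clone$d_I == 0) return(Inf)
  (clone$b / clone$d_I) * (clone$r - clone$d_A) / (clone$r + clone$d_A)
}

#' Homeostatic number of empty niche spaces
#'
#' In monoclonal homeostasis the number of vacant niche spaces is
#' `E* = d_I * (r + d_A) / (b * (r - d_A)) = 1 / F`, independent of the
#' detachment rate `u` and of the capacity `K`. High differentiation means
#' many empty niches; high attachment or proliferation means few. For a
#' non-persistent clone no positive equilibrium exists and `Inf` is
#' returned.
#'
#' @inheritParams clone_fitness
#' @return `E*` in cells; `Inf` when `r <= d_A`.
#' @export
empty_niche_equilibrium <- function(clone) {
  f <- clone_fitness(clone)
  if (f == 0) return(Inf)
  1 / f
}

#' Monoclonal homeostatic equilibrium
#'
#' Closed-form equilibrium of the single-clone system:
#' `N* = K - E*`, `A* = u * N* / (r + d_A)`, `I* = A* * (r - d_A) / d_I`,
#' `flux* = r * A*` (equivalently `d_A * A* + d_I * I*`). The equilibrium
#' exists when the clone is persistent and `E* < K`; stability is assessed
#' from the numerically evaluated Jacobian at the equilibrium (all
#' eigenvalue real parts below `-1e-8`).
#'
#' @param params A single-clone [system_params()] object.
#' @return A one-row tibble with columns `N_star`, `A_star`, `I_star`,
#'   `E_star`, `flux_star`, `exists`, `stable`, `degenerate` (`TRUE` when
#'   `u = 0`, in which case any `N` with `A = I = 0` is stationary and the
#'   starred unbound counts are 0).
#' @examples
#' p0 <- system_params(100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' monoclonal_equilibrium(p0)
#' @export
monoclonal_equilibrium <- function(params) {
  stopifnot(inherits(params, "system_params"))
  if (n_clones(params) != 1L) {
    stop("monoclonal_equilibrium needs exactly one clone", call. = FALSE)
  }
  cl <- params$clones[[1L]]
  E <- empty_niche_equilibrium(cl)
  if (!is.finite(E) || E >= params$K) {
    return(tibble::tibble(N_star = NA_real_, A_star = NA_real_,
                          I_star = NA_real_, E_star = E, flux_star = NA_real_,
                          exists = FALSE, stable = NA, degenerate = FALSE))
  }
  N <- params$K - E
  A <- cl$u * N / (cl$r + cl$d_A)
  I <- A * (cl$r - cl$d_A) / cl$d_I
  res <- tibble::tibble(N_star = N, A_star = A, I_star = I, E_star = E,
                        flux_star = cl$r * A, exists = TRUE,
                        stable = NA, degenerate = cl$u == 0)
  res$stable <- equilibrium_stable(params, make_state(params, N, A, I,
                                                      D = equilibrium_D(params, A, I)))
  res
}

equilibrium_D <- function(params, A, I) {
  if (is.null(params$downstream)) return(NULL)
  cl <- clone_rates(params)
  if (params$downstream$clear == 0) return(0)
  params$downstream$amp * (cl$d_A * A + cl$d_I * I) / params$downstream$clear
}

# Jacobian eigenvalues at a state; real parts < -tol => locally stable
equilibrium_stable <- function(params, state, tol = 1e-8) {
  f <- function(y) unname(niche_rhs(pmax(y, 0), params))
  J <- pracma::jacobian(f, unname(state))
  all(Re(eigen(J, only.values = TRUE)$values) < -tol)
}

#' Equilibrium initial state
#'
#' Builds a state at homeostatic equilibrium. For a single clone this is
#' the [monoclonal_equilibrium()]. For several clones the niche is filled
#' to the monoclonal `N*` of a reference clone, split across clones by
#' `fractions`, with each clone's unbound pools at their conditional
#' equilibria (`A_j = u_j N_j / (r_j + d_Aj)`,
#' `I_j = A_j (r_j - d_Aj) / d_Ij`) — the standard starting point for
#' competition experiments.
#'
#' @param params A [system_params()] object.
#' @param fractions Per-clone niche fractions (summing to at most 1);
#'   default equal split.
#' @param reference Index of the clone whose monoclonal `N*` sets the total
#'   initial niche occupancy.
#' @return A state vector.
#' @export
equilibrium_state <- function(params, fractions = NULL, reference = 1L) {
  nc <- n_clones(params)
  if (is.null(fractions)) fractions <- rep(1 / nc, nc)
  fractions <- rep_len(fractions, nc)
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-12) {
    stop("`fractions` must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  ref <- params$clones[[reference]]
  E <- empty_niche_equilibrium(ref)
  if (!is.finite(E) || E >= params$K) {
    stop("reference clone has no positive monoclonal equilibrium",
         call. = FALSE)
  }
  rt <- clone_rates(params)
  N <- (params$K - E) * fractions
  A <- rt$u * N / (rt$r + rt$d_A)
  I <- ifelse(rt$d_I > 0, A * pmax(rt$r - rt$d_A, 0) / rt$d_I, 0)
  make_state(params, N, A, I, D = if (!is.null(params$downstream)) {
    params$downstream$amp * (rt$d_A * A + rt$d_I * I) /
      max(params$downstream$clear, .Machine$double.eps)
  })
}

#' Comparative statics of the homeostatic equilibrium
#'
#' Recomputes the closed-form monoclonal equilibrium after a small relative
#' increase of one parameter at a time and reports the sign of the response
#' of `N*`, `I*`, `A*` and the progenitor flux. Reproduces the model's
#' sign table: capacity, attachment and division raise all four quantities
#' (division raises `A*` only when `r` is close to `d_A`, otherwise lowers
#' it); detachment leaves `N*` unchanged while raising the unbound counts
#' and the flux; both differentiation rates lower everything.
#'
#' @param params A single-clone [system_params()] object with an existing
#'   equilibrium.
#' @param parameters Parameters to perturb; default all six.
#' @param rel_step Relative perturbation, default 1%.
#' @param deadband Absolute relative-change threshold below which the sign
#'   is declared `"0"`.
#' @return A tibble with columns `parameter`, `N`, `I`, `A`, `flux`, each
#'   sign one of `"+"`, `"-"`, `"0"`.
#' @export
comparative_statics <- function(params,
                                parameters = c("K", "u", "r", "d_A", "d_I", "b"),
                                rel_step = 0.01, deadband = 1e-9) {
  base <- monoclonal_equilibrium(params)
  if (!base$exists) stop("baseline equilibrium does not exist", call. = FALSE)
  rows <- lapply(parameters, function(pn) {
    pert <- params
    if (pn == "K") {
      pert$K <- pert$K * (1 + rel_step)
    } else {
      pert$clones[[1L]][[pn]] <- pert$clones[[1L]][[pn]] * (1 + rel_step)
    }
    eq <- monoclonal_equilibrium(pert)
    if (!eq$exists) {
      stop(sprintf("perturbing `%s` destroys the equilibrium", pn),
           call. = FALSE)
    }
    sgn <- function(new, old) {
      rel <- (new - old) / max(abs(old), .Machine$double.eps)
      if (abs(rel) < deadband) "0" else if (rel > 0) "+" else "-"
    }
    tibble::tibble(parameter = pn,
                   N = sgn(eq$N_star, base$N_star),
                   I = sgn(eq$I_star, base$I_star),
                   A = sgn(eq$A_star, base$A_star),
                   flux = sgn(eq$flux_star, base$flux_star))
  })
  dplyr::bind_rows(rows)
}
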