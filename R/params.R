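#' Per-clone stem-cell kinetic parameters
#'
#' Bundles the five rates that govern the life cycle of one stem-cell clone
#' in a finite-capacity niche: unbound inactive cells attach to an empty
#' niche space at rate `b` (per empty niche per day), niche-bound quiescent
#' cells detach and become active at rate `u` (per day), active cells divide
#' at rate `r` or differentiate at rate `d_A`, and inactive cells (the
#' post-division state) differentiate at rate `d_I` if they fail to
#' reattach.
#'
#' A clone can persist in the niche only when the gain from division
#' outweighs the loss of active cells to differentiation, i.e. `r > d_A`;
#' see [clone_fitness()].
#'
#' @param b Attachment rate, per empty niche per day. Non-negative.
#' @param u Detachment rate: proportion of niche-bound cells detaching per
#'   day. Non-negative.
#' @param r Division rate of active cells, per day. Non-negative.
#' @param d_A Differentiation rate of active cells, per day. Non-negative.
#' @param d_I Differentiation rate of inactive cells, per day. Non-negative.
#' @param label Optional clone label used in trajectory output.
#' @return An object of class `clone_params`: a named list of the five rates
#'   plus the label.
#' @examples
#' clone_params(b = 0.1, u = 0.2, r = 1, d_A = 0.5, d_I = 1)
#' @export
clone_params <- function(b, u, r, d_A, d_I, label = NULL) {
  rates <- list(b = b, u = u, r = r, d_A = d_A, d_I = d_I)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    if (v < 0) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  }
  structure(c(rates, list(label = label)), class = "clone_params")
}

#' @export
print.clone_params <- function(x, ...) {
  cat("<clone_params>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  b=%g u=%g r=%g d_A=%g d_I=%g  (%s)\n",
              x$b, x$u, x$r, x$d_A, x$d_I,
              if (is_persistent(x)) "persistent" else "non-persistent"))
  invisible(x)
}

#' Can a clone persist in the niche?
#'
#' A clone is persistent when its division rate exceeds the differentiation
#' rate of active cells (`r > d_A`), so that each activation produces on
#' average more than one surviving stem cell.
#'
#' @param clone A [clone_params()] object.
#' @return Logical scalar.
#' @export
is_persistent <- function(clone) {
  stopifnot(inherits(clone, "clone_params"))
  clone$r > clone$d_A
}

#' Niche-plus-clones system parameters
#'
#' A finite niche of capacity `K` shared by one or more clones, optionally
#' with a downstream progenitor pool per clone (amplification of the
#' differentiation outflux and first-order clearance). The progenitor pool
#' is off by default; all headline analyses work with the progenitor
#' production flux, which is fully determined by the stem-cell states.
#'
#' @param K Niche capacity (maximal number of niche-bound stem cells).
#'   Positive.
#' @param clones A single [clone_params()] or a list of them.
#' @param downstream Optional `list(amp =, clear =)` with a dimensionless
#'   amplification factor and a clearance rate (per day) for the progenitor
#'   pool.
#' @return An object of class `system_params`.
#' @examples
#' p0 <- system_params(K = 100, clone_params(0.1, 0.2, 1, 0.5, 1))
#' @export
system_params <- function(K, clones, downstream = NULL) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0) {
    stop("`K` must be a single non-negative number", call. = FALSE)
  }
  if (inherits(clones, "clone_params")) clones <- list(clones)
  if (!is.list(clones) || length(clones) == 0L ||
      !all(vapply(clones, inherits, logical(1), "clone_params"))) {
    stop("`clones` must be a non-empty list of clone_params", call. = FALSE)
  }
  for (j in seq_along(clones)) {
    if (is.null(clones[[j]]$label)) clones[[j]]$label <- paste0("clone", j)
  }
  if (!is.null(downstream)) {
    if (!is.list(downstream) || is.null(downstream$amp) || is.null(downstream$clear)) {
      stop("`downstream` must be list(amp =, clear =)", call. = FALSE)
    }
    if (downstream$amp < 0 || downstream$clear < 0) {
      stop("`downstream` rates must be non-negative", call. = FALSE)
    }
  }
  structure(list(K = K, clones = clones, downstream = downstream),
            class = "system_params")
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf("<system_params> K=%g, %d clone(s)%s\n", x$K, length(x$clones),
              if (is.null(x$downstream)) "" else ", progenitor pool on"))
  for (cl in x$clones) print(cl)
  invisible(x)
}

n_clones <- function(params) length(params$clones)

clone_rates <- function(params) {
  cl <- params$clones
  list(b = vapply(cl, `[[`, numeric(1), "b"),
       u = vapply(cl, `[[`, numeric(1), "u"),
       r = vapply(cl, `[[`, numeric(1), "r"),
       d_A = vapply(cl, `[[`, numeric(1), "d_A"),
       d_I = vapply(cl, `[[`, numeric(1), "d_I"))
}

clone_labels <- function(params) {
  vapply(params$clones, function(cl) cl$label %||% "clone", character(1))
}

#' Tabulate system parameters
#'
#' @param params A [system_params()] object.
#' @return A tibble with one row per clone and columns `clone`, `b`, `u`,
#'   `r`, `d_A`, `d_I`, `persistent`.
#' @export
param_table <- function(params) {
  stopifnot(inherits(params, "system_params"))
  rt <- clone_rates(params)
  tibble::tibble(
    clone = clone_labels(params),
    b = rt$b, u = rt$u, r = rt$r, d_A = rt$d_A, d_I = rt$d_I,
    persistent = rt$r > rt$d_A
  )
}

#' Murine-like reference parameter set
#'
#' A single-clone parameter set with realistic hematopoietic stem-cell
#' kinetics: active cells divide roughly monthly (`r` = 0.03/day),
#' differentiation is slower than division (`d_A` = 0.01/day,
#' `d_I` = 0.05/day), reattachment is fast (`b` = 0.5 per empty niche per
#' day) and detachment is rare (`u` = 0.001/day), so that the niche is
#' almost full in homeostasis (well under 1% of spaces empty) and only a few
#' percent of stem cells are unbound. This set is synthetic: it is chosen
#' for plausibility, not fitted to data.
#'
#' @param K Niche capacity, default 100 cells.
#' @return A [system_params()] object.
#' @examples
#' monoclonal_equilibrium(reference_params())
#' @export
reference_params <- function(K = 100) {
  system_params(K, clone_params(b = 0.5, u = 0.001, r = 0.03,
                                d_A = 0.01, d_I = 0.05, label = "HSC"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
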