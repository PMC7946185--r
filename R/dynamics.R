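#' Simulation settings for capped gLV integration
#'
#' @param extinction_threshold abundance below which a species is clamped
#'   to zero. Default `1e-6 * K_T`, resolved when the settings meet a
#'   parameter set (pass a number to override).
#' @param convergence_tol per-capita rate magnitude below which the system
#'   counts as settled (1/time).
#' @param convergence_window length of time (time units) the rates must
#'   stay below `convergence_tol`.
#' @param horizon maximum integration time.
#' @param rel_tol,abs_tol local error control of the adaptive integrator.
#' @param invader_density abundance at which arriving species are
#'   introduced. Default `1e-3 * K_T`, resolved like the threshold.
#' @param cap_weighted use the abundance-weighted mean per-capita rate in
#'   the cap rule (`TRUE`, default: the only choice that makes the total
#'   derivative exactly zero at the cap) or the unweighted mean.
#' @param capped apply the population cap (`FALSE` gives classical gLV).
#' @return a list of class `sim_settings`.
#' @export
sim_settings <- function(extinction_threshold = NULL,
                         convergence_tol = 1e-8,
                         convergence_window = 10,
                         horizon = 1e4,
                         rel_tol = 1e-8, abs_tol = 1e-10,
                         invader_density = NULL,
                         cap_weighted = TRUE,
                         capped = TRUE) {
  structure(list(extinction_threshold = extinction_threshold,
                 convergence_tol = convergence_tol,
                 convergence_window = convergence_window,
                 horizon = horizon, rel_tol = rel_tol, abs_tol = abs_tol,
                 invader_density = invader_density,
                 cap_weighted = cap_weighted, capped = capped),
            class = "sim_settings")
}

resolve_settings <- function(settings, params) {
  if (is.null(settings)) settings <- sim_settings()
  if (is.null(settings$extinction_threshold))
    settings$extinction_threshold <- 1e-6 * params$K_T
  if (is.null(settings$invader_density))
    settings$invader_density <- 1e-3 * params$K_T
  settings
}

check_state <- function(x, params) {
  if (length(x) != params$S)
    stop("state length does not match number of species", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and nonnegative", call. = FALSE)
  as.numeric(x)
}

#' Generalized Lotka-Volterra derivative
#'
#' Rate of change of each species:
#' `dx_i/dt = x_i * ((r_i + f) - s_i x_i + sum_{j != i} a_ij x_j)`.
#'
#' @param x abundance vector.
#' @param params a [community_parameters()] object.
#' @return vector of abundance rates (abundance/time).
#' @export
glv_derivative <- function(x, params) {
  x <- check_state(x, params)
  cpp_capped_deriv(x, params$r, params$s, params$A, params$f,
                   params$K_T, FALSE, TRUE)
}

#' Capped gLV derivative
#'
#' Below the total-population cap this equals [glv_derivative()]. Once the
#' total abundance reaches `K_T`, species compete for space zero-sum: each
#' species grows at its per-capita rate minus the community mean rate
#' (abundance-weighted by default), so the total derivative is exactly zero
#' at the cap.
#'
#' @inheritParams glv_derivative
#' @param settings a [sim_settings()] object (only `cap_weighted` is used).
#' @return vector of abundance rates (abundance/time).
#' @export
capped_derivative <- function(x, params, settings = sim_settings()) {
  x <- check_state(x, params)
  cpp_capped_deriv(x, params$r, params$s, params$A, params$f,
                   params$K_T, TRUE, isTRUE(settings$cap_weighted))
}

#' Integrate capped gLV dynamics to equilibrium
#'
#' Adaptive Runge-Kutta integration of the capped dynamics. Abundances
#' falling below the extinction threshold are clamped to zero (extinction
#' is absorbing). Integration stops once the largest per-capita rate among
#' extant species has stayed below `convergence_tol` for
#' `convergence_window` time units, or at the horizon.
#'
#' @param params a [community_parameters()] object.
#' @param x0 initial abundance vector.
#' @param settings a [sim_settings()] object.
#' @param record record a thinned trajectory.
#' @return list with `x` (final abundances), `t`, `converged`,
#'   `max_total` (largest total abundance seen) and, if `record`,
#'   `time`/`trajectory`.
#' @export
integrate_to_equilibrium <- function(params, x0, settings = sim_settings(),
                                     record = FALSE) {
  settings <- resolve_settings(settings, params)
  x0 <- check_state(x0, params)
  out <- cpp_integrate_glv(
    x0, params$r, params$s, params$A, params$f, params$K_T,
    isTRUE(settings$capped), isTRUE(settings$cap_weighted),
    settings$horizon, settings$extinction_threshold,
    settings$convergence_tol, settings$convergence_window,
    settings$rel_tol, settings$abs_tol, record,
    max(settings$horizon / 2000, 0.5))
  if (!out$ok)
    stop(sprintf(
      "integration failed (non-finite state or step underflow at t = %g)",
      out$t), call. = FALSE)
  out
}

#' Interior equilibrium of a species subset
#'
#' Solves the linear interior fixed point
#' `(diag(s) - A)[subset, subset] x = (r + f)[subset]`. When the solution
#' is strictly positive and its total is below the cap, feasibility and
#' linear asymptotic stability are judged from the gLV Jacobian
#' (`J_ij = x_i a_ij`, `J_ii = -s_i x_i`). When the interior total exceeds
#' `K_T` (or the linear system is singular), the subset is relaxed by
#' capped simulation instead and the settled state is reported with
#' `at_cap = TRUE`.
#'
#' @param params a [community_parameters()] object.
#' @param subset integer vector of species indices (1-based), nonempty.
#' @param settings a [sim_settings()] object for the cap fallback.
#' @return list of class `equilibrium_result`: `subset`, `abundances`
#'   (over the subset), `feasible`, `stable`, `max_re_eigenvalue`,
#'   `at_cap`, `marginal`.
#' @export
subset_equilibrium <- function(params, subset, settings = sim_settings()) {
  if (length(subset) == 0L) stop("subset must be nonempty", call. = FALSE)
  subset <- sort(unique(as.integer(subset)))
  settings <- resolve_settings(settings, params)
  sub <- subset_parameters(params, subset)
  n <- sub$S
  M <- diag(sub$s, n) - sub$A
  rhs <- sub$r + sub$f
  xstar <- tryCatch(solve(M, rhs), error = function(e) NULL)
  cap_tol <- 1e-9 * params$K_T

  if (!is.null(xstar) && all(is.finite(xstar))) {
    # feasibility requires every abundance to clear the extinction
    # threshold, keeping the analytic branch consistent with the
    # simulated dynamics (which clamp smaller populations to zero)
    if (any(xstar <= settings$extinction_threshold)) {
      res <- equilibrium_result(subset, pmax(xstar, 0), feasible = FALSE,
                                stable = NA, max_re = NA_real_,
                                at_cap = FALSE)
      res$method <- "interior"
      return(res)
    }
    if (sum(xstar) < params$K_T - cap_tol) {  # ties go to the cap branch
      J <- xstar * sub$A
      diag(J) <- -sub$s * xstar
      ev <- eigen(J, only.values = TRUE)$values
      mre <- max(Re(ev))
      res <- equilibrium_result(subset, xstar, feasible = TRUE,
                                stable = mre < -1e-9, max_re = mre,
                                at_cap = FALSE,
                                marginal = abs(mre) <= 1e-9)
      res$method <- "interior"
      return(res)
    }
    # interior total at or beyond the cap: fall through to capped relaxation
    # (start just below the cap so the dynamics pick the regime themselves)
    start <- xstar / sum(xstar) * 0.99 * params$K_T
  } else {
    start <- rep(params$K_T / (2 * n), n)
  }

  x0 <- numeric(params$S)
  x0[subset] <- start
  run <- integrate_to_equilibrium(params, x0, settings)
  settled <- run$x[subset]
  feas <- all(settled > settings$extinction_threshold)
  res <- equilibrium_result(subset, settled, feasible = feas,
                            stable = NA, max_re = NA_real_,
                            at_cap = sum(run$x) >= params$K_T - cap_tol,
                            converged = run$converged)
  res$method <- "simulation"
  res
}

equilibrium_result <- function(subset, abundances, feasible, stable,
                               max_re, at_cap, marginal = FALSE,
                               converged = TRUE) {
  structure(list(subset = subset, abundances = as.numeric(abundances),
                 feasible = isTRUE(feasible), stable = stable,
                 max_re_eigenvalue = max_re, at_cap = isTRUE(at_cap),
                 marginal = isTRUE(marginal), converged = isTRUE(converged)),
            class = "equilibrium_result")
}

#' Viability of a species subset
#'
#' A subcommunity is viable when it has a strictly positive equilibrium
#' that is linearly asymptotically stable. Interior equilibria (total
#' abundance below the cap) are judged by the Jacobian spectrum; marginal
#' cases (largest real part within 1e-9 of zero) are reported not viable.
#' Cap-constrained subsets are judged by capped simulation: the settled
#' state must retain every subset member and return to itself after a
#' +/-5% perturbation of each abundance. The empty set is viable by
#' convention.
#'
#' @inheritParams subset_equilibrium
#' @param subset integer vector of species indices; may be empty.
#' @return an `equilibrium_result` with an additional `viable` flag.
#' @export
assess_viability <- function(params, subset, settings = sim_settings()) {
  settings <- resolve_settings(settings, params)
  if (length(subset) == 0L) {
    res <- equilibrium_result(integer(0), numeric(0), feasible = TRUE,
                              stable = TRUE, max_re = -Inf, at_cap = FALSE)
    res$viable <- TRUE
    return(res)
  }
  res <- subset_equilibrium(params, subset, settings)
  if (!res$feasible) {
    # an infeasible interior can coexist with a stable cap state when
    # mutualism outruns self-regulation (runaway growth pinned by the
    # cap); check before declaring non-viable. Simulation-derived
    # infeasibility has already explored the capped dynamics.
    if (identical(res$method, "interior")) {
      cap_try <- cap_state_check(params, res$subset, settings)
      if (cap_try$viable) return(cap_try)
    }
    res$viable <- FALSE
    return(res)
  }
  if (!res$at_cap && !is.na(res$stable)) {
    if (res$stable && !res$marginal) {
      res$viable <- TRUE
      return(res)
    }
    # unstable (or marginal) interior: strong mutualists can still hold a
    # stable state pressed against the population cap; check it by
    # simulation from near-cap abundances before declaring non-viable.
    cap_try <- cap_state_check(params, res$subset, settings)
    if (cap_try$viable) return(cap_try)
    res$viable <- FALSE
    return(res)
  }
  # cap case from subset_equilibrium: perturbation-return test
  res2 <- perturbation_return(params, res, settings)
  res2
}

# Simulate the subset from near-cap equal shares and test the settled
# state with a perturbation-return check.
cap_state_check <- function(params, subset, settings) {
  n <- length(subset)
  x0 <- numeric(params$S)
  x0[subset] <- 0.99 * params$K_T / n
  run <- integrate_to_equilibrium(params, x0, settings)
  settled <- run$x[subset]
  cap_tol <- 1e-9 * params$K_T
  res <- equilibrium_result(subset, settled,
                            feasible = all(settled >
                                           settings$extinction_threshold),
                            stable = NA, max_re = NA_real_,
                            at_cap = sum(run$x) >= params$K_T - cap_tol,
                            converged = run$converged)
  if (!res$feasible || !res$converged) {
    res$viable <- FALSE
    return(res)
  }
  perturbation_return(params, res, settings)
}

# Species are perturbed one at a time: on the cap simplex a joint scaling
# of all abundances is undone by the cap projection and would test nothing.
perturbation_return <- function(params, res, settings) {
  viable <- res$converged && res$feasible
  if (viable) {
    subset <- res$subset
    base <- numeric(params$S)
    base[subset] <- res$abundances
    for (k in subset) {
      for (sgn in c(-0.05, 0.05)) {
        x0 <- base
        x0[k] <- max(x0[k] * (1 + sgn), 2 * settings$extinction_threshold)
        back <- integrate_to_equilibrium(params, x0, settings)
        ok <- all(back$x[subset] > settings$extinction_threshold) &&
          max(abs(back$x[subset] - base[subset]) /
                pmax(base[subset], settings$extinction_threshold)) < 1e-3
        if (!ok) { viable <- FALSE; break }
      }
      if (!viable) break
    }
  }
  res$stable <- viable
  res$viable <- viable
  res
}
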