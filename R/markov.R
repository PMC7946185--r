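#' Continuous-time Markov generator from an assembly map
#'
#' Community occupancy is modelled as a continuous-time Markov chain over
#' the viable subcommunities. Each absent pool species arrives at rate
#' `gamma`; a non-failing invasion moves the chain to the invasion target
#' (failed invasions contribute nothing). Each present species is lost at
#' rate `delta`; after a loss the remaining abundances are relaxed under
#' capped dynamics, which may cascade further extinctions, and the chain
#' moves to the settled viable state. Gain and loss events are rare enough
#' that only one occurs at a time, so rates add independently.
#'
#' @param map an `assembly_map` built with `consortium_size = 1` (arrival
#'   transitions reuse its single-species edges).
#' @param gamma per-species arrival rate (1/time), > 0.
#' @param delta per-species loss rate (1/time), > 0.
#' @param arrival_mode `"per_species"` (default: total arrival pressure
#'   scales with pool size) or `"uniform"` (total rate `gamma` split
#'   uniformly over absent species; differs only by the constant `1/n`).
#' @return list of class `transition_model`: `states` (node bitmasks),
#'   `Q`, `gamma`, `delta`, `map`.
#' @export
build_generator <- function(map, gamma, delta,
                            arrival_mode = c("per_species", "uniform")) {
  arrival_mode <- match.arg(arrival_mode)
  if (gamma <= 0 || delta <= 0)
    stop("gamma and delta must be > 0", call. = FALSE)
  params <- map$params
  settings <- resolve_settings(map$settings, params)
  S <- map$S
  states <- map$nodes
  n <- length(states)
  idx <- setNames(seq_len(n), as.character(states))
  Q <- matrix(0, n, n)

  # arrivals: single-species edges of the map
  single <- map$edges[!grepl("\\+", map$edges$arrivals), , drop = FALSE]
  for (k in seq_len(nrow(single))) {
    i <- idx[[as.character(single$from[k])]]
    j <- idx[[as.character(single$to[k])]]
    rate <- gamma
    if (arrival_mode == "uniform") {
      n_absent <- S - mask_size(single$from[k], S)
      rate <- gamma / n_absent
    }
    Q[i, j] <- Q[i, j] + rate
  }

  # losses: delete each present species, relax, cascade
  for (mask in states) {
    members <- members_from_mask(mask, S)
    if (length(members) == 0L) next
    i <- idx[[as.character(mask)]]
    eq <- map$equilibria[[as.character(mask)]]
    for (lost in members) {
      remaining <- setdiff(members, lost)
      tmask <- relax_after_loss(params, remaining, eq, members, settings)
      key <- as.character(tmask)
      if (is.na(idx[key] %||% NA))
        stop(sprintf(
          "post-loss relaxation of %s minus %s reached non-node state %s",
          mask_label(mask, params$species, S), params$species[lost],
          mask_label(tmask, params$species, S)), call. = FALSE)
      j <- idx[[key]]
      Q[i, j] <- Q[i, j] + delta
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  structure(list(states = states, Q = Q, gamma = gamma, delta = delta,
                 map = map, arrival_mode = arrival_mode),
            class = "transition_model")
}

relax_after_loss <- function(params, remaining, eq, members, settings) {
  if (length(remaining) == 0L) return(0L)
  x0 <- numeric(params$S)
  x0[members] <- eq$abundances
  x0[setdiff(members, remaining)] <- 0
  run <- integrate_to_equilibrium(params, x0, settings)
  mask_from_members(which(run$x > settings$extinction_threshold))
}

#' Stationary distribution of the assembly chain
#'
#' Restricts the chain to the set of states reachable from the
#' uncolonized state and solves `pi Q = 0`, `sum(pi) = 1` there. When the
#' reachable set splits into several closed classes the distribution is
#' conditional on the class actually reached and a warning is emitted.
#'
#' @param model a `transition_model`.
#' @return list of class `stationary_distribution`: `pi` (named by state
#'   bitmask; zero for unreachable states), `by_size`, `most_likely_size`,
#'   `size_tie`, `residual`.
#' @export
stationary_distribution <- function(model) {
  n <- length(model$states)
  Q <- model$Q
  # reachable set from the empty state
  start <- which(model$states == 0L)
  reach <- rep(FALSE, n); reach[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      out <- which(Q[i, ] > 0 & !reach)
      reach[out] <- TRUE
      nxt <- c(nxt, out)
    }
    frontier <- nxt
  }
  sub <- which(reach)
  Qr <- Q[sub, sub, drop = FALSE]
  # fix diagonals for transitions that left the reachable set (none can)
  m <- length(sub)
  # solve pi Qr = 0 with normalization: replace last column with ones
  Aeq <- t(Qr)
  Aeq[m, ] <- 1
  b <- c(rep(0, m - 1), 1)
  pi_sub <- tryCatch(solve(Aeq, b), error = function(e) NULL)
  if (is.null(pi_sub)) {
    # singular: several closed classes inside the reachable set
    warning("reducible chain: reporting a least-squares stationary vector")
    pi_sub <- qr.solve(Aeq, b)
  }
  if (any(pi_sub < -1e-8))
    warning("stationary solve produced negative mass; check the chain")
  pi_sub <- pmax(pi_sub, 0)
  pi_sub <- pi_sub / sum(pi_sub)
  pi <- setNames(numeric(n), as.character(model$states))
  pi[sub] <- pi_sub
  residual <- max(abs(as.numeric(pi[sub] %*% Qr)))

  sizes <- vapply(model$states, mask_size, 0L, S = model$map$S)
  by_size <- tapply(pi, sizes, sum)
  by_size <- setNames(as.numeric(by_size), names(by_size))
  top <- max(by_size)
  winners <- as.integer(names(by_size)[by_size >= top - 1e-12])
  structure(list(pi = pi, by_size = by_size,
                 most_likely_size = max(winners),
                 size_tie = length(winners) > 1,
                 residual = residual, states = model$states),
            class = "stationary_distribution")
}

#' Occupancy summary of a stationary distribution
#'
#' @param dist a `stationary_distribution`.
#' @return list with `most_likely_size`, `size_tie`, `by_size`,
#'   `mean_size`.
#' @export
occupancy_summary <- function(dist) {
  sizes <- as.integer(names(dist$by_size))
  list(most_likely_size = dist$most_likely_size,
       size_tie = dist$size_tie,
       by_size = dist$by_size,
       mean_size = sum(sizes * dist$by_size))
}

#' Write stationary occupancy as CSV
#'
#' @param dist a `stationary_distribution`.
#' @param map the `assembly_map` the chain was built from.
#' @param path output CSV path for the per-state table; a second file
#'   `<path>_by_size.csv` holds the size distribution.
#' @return `path`, invisibly.
#' @export
write_stationary <- function(dist, map, path) {
  df <- data.frame(
    state = vapply(map$nodes, function(m) mask_label(m, map$species, map$S),
                   ""),
    size = vapply(map$nodes, mask_size, 0L, S = map$S),
    probability = as.numeric(dist$pi))
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(size = as.integer(names(dist$by_size)),
                       probability = as.numeric(dist$by_size)),
            sub("(\\.csv)?$", "_by_size.csv", path, perl = TRUE),
            row.names = FALSE)
  invisible(path)
}
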