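# Brute-force oracles used by the property and acceptance tests. They share
# only the low-level integrator with the implementation; all viability and
# invasion-resolution logic is reimplemented from first principles.

# Viability by multi-start simulation: a subset is viable iff some random
# positive start settles with the full subset surviving and the settled
# state returns after random perturbations.
oracle_viable <- function(params, subset, n_starts = 100, seed = 1) {
  if (length(subset) == 0L) return(TRUE)
  set.seed(seed)
  st <- sim_settings(horizon = 2000)
  st <- glvmap:::resolve_settings(st, params)
  scale <- max(abs(params$r) / params$s)
  settled <- NULL
  for (k in seq_len(n_starts)) {
    x0 <- numeric(params$S)
    x0[subset] <- 10^runif(length(subset), -2, log10(2 * scale))
    run <- integrate_to_equilibrium(params, x0, st)
    if (all(run$x[subset] > st$extinction_threshold) && run$converged) {
      settled <- run$x
      break
    }
  }
  if (is.null(settled)) return(FALSE)
  for (k in 1:10) {
    x0 <- settled * runif(params$S, 0.95, 1.05)
    x0[x0 > 0 & x0 < 2 * st$extinction_threshold] <-
      2 * st$extinction_threshold
    run <- integrate_to_equilibrium(params, x0, st)
    same <- all(run$x[subset] > st$extinction_threshold) &&
      max(abs(run$x - settled) / pmax(settled, st$extinction_threshold)) < 0.01
    if (!same) return(FALSE)
  }
  TRUE
}

# Invasion outcome from randomized starts; NULL when the 20 runs disagree.
oracle_invasion <- function(params, resident, invader, n_starts = 20,
                            seed = 1) {
  set.seed(seed)
  st <- glvmap:::resolve_settings(sim_settings(horizon = 2000), params)
  # resident equilibrium by settling from a canonical start
  x_res <- numeric(params$S)
  if (length(resident) > 0) {
    x_res[resident] <- max(abs(params$r) / params$s)
    x_res <- integrate_to_equilibrium(params, x_res, st)$x
  }
  outcomes <- vapply(seq_len(n_starts), function(k) {
    x0 <- x_res * runif(params$S, 0.9, 1.1)
    x0[invader] <- runif(1, 2 * st$extinction_threshold,
                         max(4 * st$extinction_threshold,
                             0.05 * max(x_res, 1e-3 * params$K_T)))
    run <- integrate_to_equilibrium(params, x0, st)
    paste(which(run$x > st$extinction_threshold), collapse = ",")
  }, "")
  if (length(unique(outcomes)) > 1L) return(NULL)
  as.integer(strsplit(outcomes[1], ",")[[1]])
}

# Independent map construction for small S. Invasions whose 20 randomized
# runs disagree (possible when an equilibrium sits within the jitter of
# the extinction clamp) are reported as ambiguous: the oracle certifies
# only decisive outcomes.
oracle_map <- function(params, seed = 1) {
  S <- params$S
  masks <- 0:(2^S - 1L)
  viable <- vapply(masks, function(m)
    oracle_viable(params, glvmap:::members_from_mask(m, S),
                  seed = seed + m), logical(1))
  nodes <- masks[viable]
  edges <- list()
  ambiguous <- list()
  for (m in nodes) {
    members <- glvmap:::members_from_mask(m, S)
    for (inv in setdiff(seq_len(S), members)) {
      tgt <- oracle_invasion(params, members, inv, seed = seed + 31L * m + inv)
      if (is.null(tgt)) {
        ambiguous[[length(ambiguous) + 1]] <- c(from = m, inv = inv)
        next
      }
      if (setequal(tgt, members)) next
      edges[[length(edges) + 1]] <- c(from = m,
                                      to = glvmap:::mask_from_members(tgt),
                                      inv = inv)
    }
  }
  list(nodes = sort(nodes),
       edges = if (length(edges)) do.call(rbind, edges) else
         matrix(numeric(0), ncol = 3),
       ambiguous = if (length(ambiguous)) do.call(rbind, ambiguous) else
         matrix(numeric(0), ncol = 2))
}

# Compare a built map with the oracle on the oracle's decisive cases.
map_matches_oracle <- function(map, orc) {
  if (!identical(map$nodes, as.integer(orc$nodes))) return(FALSE)
  got <- map$edges[!grepl("\\+", map$edges$arrivals),
                   c("from", "to", "arrivals")]
  if (nrow(orc$ambiguous) > 0) {
    amb_key <- paste(orc$ambiguous[, "from"], orc$ambiguous[, "inv"])
    got <- got[!(paste(got$from, got$arrivals) %in% amb_key), ]
  }
  got <- got[order(got$from, as.integer(got$arrivals)), ]
  exp_e <- as.data.frame(orc$edges)
  if (nrow(exp_e) == 0) return(nrow(got) == 0)
  exp_e <- exp_e[order(exp_e$from, exp_e$inv), ]
  nrow(got) == nrow(exp_e) &&
    all(as.integer(got$from) == exp_e$from) &&
    all(as.integer(got$to) == exp_e$to) &&
    all(as.integer(got$arrivals) == exp_e$inv)
}

random_3sp_community <- function(seed) {
  set.seed(seed)
  st <- sampler_settings(S = 3, C = 0.5, sigma = 0.15, P_m = 0.3,
                         max_attempts = 500)
  sample_climax_community(st)
}
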