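#' Settings for random climax-community generation
#'
#' @param S species count.
#' @param C connectivity: probability that an unordered species pair
#'   interacts at all.
#' @param sigma half-normal scale of interaction magnitudes
#'   (per abundance per time).
#' @param P_m facilitation proportion: fraction of nonzero interaction
#'   terms switched from inhibitory to positive.
#' @param r_spec intrinsic growth-rate distribution: a function
#'   `function(n)` returning `n` draws. Default `runif(n, -0.5, 1)`, which
#'   lets a fraction of species lack the capacity for independent growth
#'   (secondary colonizers).
#' @param s_value common self-regulation constant.
#' @param K_T total population cap.
#' @param amensal_prob probability an interacting pair is one-sided
#'   (amensal/commensal) rather than bidirectional.
#' @param max_attempts rejection-sampling budget on full-community
#'   viability.
#' @return a list of class `sampler_settings`.
#' @export
sampler_settings <- function(S = 10, C = 0.5, sigma = 0.05, P_m = 0,
                             r_spec = function(n) runif(n, -0.5, 1),
                             s_value = 1, K_T = 10000,
                             amensal_prob = 0.5, max_attempts = 500) {
  stopifnot(S >= 1, C >= 0, C <= 1, sigma >= 0, P_m >= 0, P_m <= 1,
            s_value > 0, max_attempts >= 1)
  structure(list(S = S, C = C, sigma = sigma, P_m = P_m, r_spec = r_spec,
                 s_value = s_value, K_T = K_T,
                 amensal_prob = amensal_prob, max_attempts = max_attempts),
            class = "sampler_settings")
}

#' Switch a proportion of inhibitory interactions to facilitation
#'
#' Takes a purely nonpositive interaction matrix (competitive/amensal
#' community) and flips the sign of `round(P_m * n_nonzero)` nonzero
#' off-diagonal entries, chosen uniformly at random, to positive. The
#' magnitudes are untouched, so sweeps over `P_m` are
#' magnitude-controlled. At `P_m = 1` every interaction is commensal or
#' cooperative.
#'
#' @param A interaction matrix with nonpositive off-diagonal entries.
#' @param P_m proportion in `[0, 1]` of nonzero entries to flip.
#' @return the modified matrix.
#' @export
apply_facilitation <- function(A, P_m) {
  if (P_m < 0 || P_m > 1) stop("P_m must lie in [0, 1]", call. = FALSE)
  off <- which(A != 0 & row(A) != col(A))
  if (any(A[off] > 0))
    stop("input matrix must be purely inhibitory off-diagonal",
         call. = FALSE)
  n_flip <- round(P_m * length(off))
  if (n_flip > 0) {
    flip <- if (length(off) == 1L) off else sample(off, n_flip)
    A[flip] <- -A[flip]
  }
  A
}

# Draw one candidate interaction structure (before the viability filter).
draw_candidate <- function(st) {
  S <- st$S
  A <- matrix(0, S, S)
  if (S > 1) {
    pairs <- combn(S, 2)
    for (k in seq_len(ncol(pairs))) {
      if (runif(1) >= st$C) next
      i <- pairs[1, k]; j <- pairs[2, k]
      m_ij <- abs(rnorm(1, 0, st$sigma))
      m_ji <- abs(rnorm(1, 0, st$sigma))
      if (runif(1) < st$amensal_prob) {
        # one-sided: zero one direction at random
        if (runif(1) < 0.5) A[i, j] <- -m_ij else A[j, i] <- -m_ji
      } else {
        A[i, j] <- -m_ij
        A[j, i] <- -m_ji
      }
    }
    A <- apply_facilitation(A, st$P_m)
  }
  r <- st$r_spec(S)
  community_parameters(r = r, s = rep(st$s_value, S), A = A, K_T = st$K_T)
}

#' Sample a random viable climax community
#'
#' Rejection-samples candidate communities until the full S-species set is
#' viable (see [assess_viability()]). Candidates are built pair-wise: each
#' unordered pair interacts with probability `C`; interacting pairs are
#' one-sided (amensal) or bidirectional (competitive) with probability
#' `amensal_prob`; magnitudes are half-normal with scale `sigma`;
#' communities start purely inhibitory and [apply_facilitation()] then
#' switches a proportion `P_m` of terms to positive, yielding the five
#' interaction forms (+/-, -/-, +/+, +/0, -/0).
#'
#' @param settings a [sampler_settings()] object.
#' @param sim_settings a [sim_settings()] object used for viability.
#' @return a `community_parameters` object with attribute `attempts`.
#' @export
sample_climax_community <- function(settings = sampler_settings(),
                                    sim_settings = NULL) {
  for (attempt in seq_len(settings$max_attempts)) {
    cand <- draw_candidate(settings)
    via <- assess_viability(cand, seq_len(cand$S), sim_settings)
    if (via$viable) {
      attr(cand, "attempts") <- attempt
      attr(cand, "climax_equilibrium") <- via
      return(cand)
    }
  }
  stop(sprintf("no viable community found in %d attempts",
               settings$max_attempts), call. = FALSE)
}
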