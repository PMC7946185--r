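#' Archetype communities with known assembly-map structure
#'
#' Hand-constructed parameter sets realizing the qualitative regimes the
#' assembly framework distinguishes. Expected structures (asserted in the
#' test suite):
#' * `independent` - three logistic species, no interactions; every subset
#'   viable, hypercube map.
#' * `obligate_pair` - two mutualists with negative intrinsic growth whose
#'   cooperation outruns self-regulation; only the empty set and the pair
#'   (pressed against the population cap) are viable, so the map is
#'   fractured at consortium size 1.
#' * `commensal_chain` - a pioneer feeding a dependent species which feeds
#'   a third; a single forced assembly path.
#' * `competitive_exclusion` - two self-sufficient species, one of which
#'   excludes the other asymmetrically; the full pair is not viable.
#' * `mutualist_triangle` - three obligate mutualists whose pairwise
#'   support is insufficient; only the empty set and the full (cap-bound)
#'   triangle are viable, and only a consortium of all three can colonize.
#' * `humpty_dumpty` - five species: a cyclic-competition core (stable
#'   together, pairwise exclusive) plus two independents. The climax is
#'   viable but no single-arrival path reaches it: a community stable once
#'   assembled yet unable to assemble, and prone to irreversible collapse.
#'
#' @param archetype one of the names above.
#' @return a [community_parameters()] object.
#' @export
fixture_community <- function(archetype = c("independent", "obligate_pair",
                                            "commensal_chain",
                                            "competitive_exclusion",
                                            "mutualist_triangle",
                                            "humpty_dumpty")) {
  archetype <- match.arg(archetype)
  switch(archetype,
    independent = community_parameters(
      r = c(1, 0.8, 0.6), s = rep(1, 3)),
    obligate_pair = {
      A <- matrix(0, 2, 2); A[1, 2] <- 2; A[2, 1] <- 2
      community_parameters(r = c(-0.1, -0.1), s = c(1, 1), A = A)
    },
    commensal_chain = {
      A <- matrix(0, 3, 3); A[2, 1] <- 2; A[3, 2] <- 2
      community_parameters(r = c(1, -0.5, -0.5), s = rep(1, 3), A = A)
    },
    competitive_exclusion = {
      A <- matrix(0, 2, 2); A[1, 2] <- -3
      community_parameters(r = c(1, 1), s = c(1, 1), A = A)
    },
    mutualist_triangle = {
      A <- matrix(0.8, 3, 3); diag(A) <- 0
      community_parameters(r = rep(-0.1, 3), s = rep(1, 3), A = A)
    },
    humpty_dumpty = {
      # cyclic competition 1 -> 2 -> 3 -> 1 (strong -1.4, weak back -0.4)
      A <- matrix(0, 5, 5)
      A[2, 1] <- -1.4; A[3, 2] <- -1.4; A[1, 3] <- -1.4
      A[1, 2] <- -0.4; A[2, 3] <- -0.4; A[3, 1] <- -0.4
      community_parameters(r = c(1, 1, 1, 0.8, 0.6), s = rep(1, 5), A = A)
    })
}

#' Generating parameters for the synthetic preterm-infant cohort
#'
#' An eight-genus community emulating the qualitative structure reported
#' for the preterm gut: early facultative colonizers (Staphylococcus,
#' Enterococcus, Escherichia, Enterobacter), two cross-feeding-dependent
#' genera (Klebsiella benefits strongly from Staphylococcus; Veillonella
#' from Klebsiella), and later anaerobes (Bifidobacterium, Bacteroides)
#' with weak interactions. Self-regulation 1e-4 per abundance per day and
#' a cap of 1e5 put single-genus equilibria in the 1e3-1e4 absolute
#' abundance range.
#'
#' @return a [community_parameters()] object with attribute `epsilon`
#'   (per-genus antibiotic effects, 1/day).
#' @export
preterm_cohort_params <- function() {
  taxa <- c("Staphylococcus", "Enterococcus", "Escherichia",
            "Enterobacter", "Klebsiella", "Bifidobacterium",
            "Bacteroides", "Veillonella")
  r <- c(1.0, 0.9, 0.8, 0.7, -0.3, 0.5, 0.4, -0.2)
  A <- matrix(0, 8, 8, dimnames = list(taxa, taxa))
  A["Klebsiella", "Staphylococcus"] <- 1.5e-4   # strong benefit
  A["Staphylococcus", "Klebsiella"] <- -2e-5    # exploitation back-effect
  A["Veillonella", "Klebsiella"] <- 1e-4        # strong benefit
  A["Escherichia", "Enterobacter"] <- -3e-5     # competition
  A["Enterobacter", "Escherichia"] <- -3e-5
  A["Bifidobacterium", "Enterococcus"] <- -1e-5 # weak amensal
  A["Bacteroides", "Bifidobacterium"] <- 1e-5   # weak commensal
  p <- community_parameters(r = r, s = rep(1e-4, 8), A = A, K_T = 1e5,
                            species = taxa)
  # empiric ampicillin+gentamicin susceptibility: Enterobacteriaceae hit
  # hardest, gram-positives and anaerobes moderately
  eps <- setNames(rep(-0.3, 8), taxa)
  eps[c("Escherichia", "Enterobacter", "Klebsiella")] <- -0.8
  eps["Staphylococcus"] <- -0.4
  attr(p, "epsilon") <- eps
  p
}

#' Specification of a synthetic longitudinal cohort
#'
#' The defaults emulate a cohort of 13 preterm infants sampled daily for
#' 40 days with genus-level absolute abundances, staggered colonization,
#' an early empiric antibiotic course, and the known sparse interaction
#' network of [preterm_cohort_params()].
#'
#' @param n_subjects number of subjects.
#' @param params generating community (with optional `epsilon` attribute
#'   for antibiotic effects).
#' @param schedule sampling times (days).
#' @param arrival_mean,arrival_sd per-taxon mean and sd of the first
#'   exposure day (normal, truncated to `[1, max(schedule) - 5]`).
#' @param reexposure_interval days between repeated exposure events for
#'   taxa that have not yet established (propagule pressure).
#' @param noise_sd multiplicative lognormal observation noise (sdlog).
#' @param detection_limit observed abundances below this are censored
#'   to zero.
#' @param introduction_density abundance added at each exposure event.
#' @param abx_name,abx_prob,abx_window antibiotic covariate: name,
#'   per-subject probability of an empiric course at birth, and its
#'   `(start, end)` days.
#' @param abx2_prob,abx2_start_range,abx2_duration a second, late-onset
#'   course (sepsis evaluation): per-subject probability, uniform range
#'   of its start day, and its length in days. These mid-study
#'   perturbations of established taxa are what make the interaction
#'   coefficients identifiable from observational time series.
#' @param seed RNG seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13,
                        params = preterm_cohort_params(),
                        schedule = 1:40,
                        arrival_mean = NULL, arrival_sd = NULL,
                        reexposure_interval = 7,
                        noise_sd = 0.1, detection_limit = 10,
                        introduction_density = 5,
                        abx_name = "ampicillin", abx_prob = 0.7,
                        abx_window = c(1, 3),
                        abx2_prob = 0.5, abx2_start_range = c(15, 28),
                        abx2_duration = 3, seed = 1) {
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  taxa <- params$species
  if (is.null(arrival_mean)) {
    arrival_mean <- setNames(rep(10, params$S), taxa)
    defaults <- c(Staphylococcus = 2, Enterococcus = 9, Escherichia = 6,
                  Enterobacter = 8, Klebsiella = 10, Bifidobacterium = 18,
                  Bacteroides = 25, Veillonella = 21)
    hit <- intersect(names(defaults), taxa)
    arrival_mean[hit] <- defaults[hit]
  }
  if (is.null(arrival_sd)) {
    arrival_sd <- setNames(rep(2, params$S), taxa)
    if ("Enterococcus" %in% taxa) arrival_sd["Enterococcus"] <- 3
  }
  structure(list(n_subjects = n_subjects, params = params,
                 schedule = schedule, arrival_mean = arrival_mean,
                 arrival_sd = arrival_sd,
                 reexposure_interval = reexposure_interval,
                 noise_sd = noise_sd, detection_limit = detection_limit,
                 introduction_density = introduction_density,
                 abx_name = abx_name, abx_prob = abx_prob,
                 abx_window = abx_window, abx2_prob = abx2_prob,
                 abx2_start_range = abx2_start_range,
                 abx2_duration = abx2_duration, seed = seed),
            class = "cohort_spec")
}

# Integrate for a fixed duration (no early convergence exit).
integrate_for <- function(params, x0, duration, settings) {
  if (duration <= 0) return(x0)
  run <- cpp_integrate_glv(
    x0, params$r, params$s, params$A, params$f, params$K_T,
    isTRUE(settings$capped), isTRUE(settings$cap_weighted),
    duration, settings$extinction_threshold,
    0, Inf, settings$rel_tol, settings$abs_tol, FALSE, 1)
  if (!run$ok) stop("cohort integration failed", call. = FALSE)
  run$x
}

#' Simulate a longitudinal infant cohort with known ground truth
#'
#' Per subject, each taxon is first exposed at a drawn arrival day and
#' re-exposed at fixed intervals until it establishes; between events the
#' community follows capped gLV dynamics (antibiotic courses shift the
#' intrinsic growth rates by the generating `epsilon`). Samples are taken
#' on the schedule, multiplied by lognormal observation noise, and
#' censored at the detection limit.
#'
#' @param spec a [cohort_spec()].
#' @return list with `series` (long-format data.frame: `subject`,
#'   `taxon`, `time`, `abundance`, one antibiotic indicator column),
#'   `truth` (list: `arrivals` data.frame of drawn first-exposure days,
#'   `params`, `epsilon`, `abx_courses`).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  params <- spec$params
  taxa <- params$species
  S <- params$S
  eps <- attr(params, "epsilon") %||% setNames(rep(0, S), taxa)
  settings <- resolve_settings(sim_settings(), params)
  t_end <- max(spec$schedule)

  all_rows <- vector("list", spec$n_subjects)
  arrivals <- vector("list", spec$n_subjects)
  abx_courses <- vector("list", spec$n_subjects)

  for (subj in seq_len(spec$n_subjects)) {
    sid <- sprintf("infant_%02d", subj)
    arr <- pmin(pmax(rnorm(S, spec$arrival_mean[taxa],
                           spec$arrival_sd[taxa]), 1), t_end - 5)
    names(arr) <- taxa
    courses <- NULL
    if (runif(1) < spec$abx_prob)
      courses <- rbind(courses, spec$abx_window)
    start2 <- runif(1, spec$abx2_start_range[1], spec$abx2_start_range[2])
    if (runif(1) < spec$abx2_prob)
      courses <- rbind(courses, c(start2, start2 + spec$abx2_duration))
    abx_courses[[subj]] <- data.frame(
      subject = sid, antibiotic = spec$abx_name,
      start = if (is.null(courses)) NA_real_ else courses[, 1],
      end = if (is.null(courses)) NA_real_ else courses[, 2])

    # event timeline: exposures (initial + re-exposures), abx switches,
    # samples
    expo <- lapply(seq_len(S), function(i)
      seq(arr[i], t_end, by = spec$reexposure_interval))
    n_course <- if (is.null(courses)) 0L else nrow(courses)
    events <- data.frame(
      time = c(unlist(expo), spec$schedule,
               if (n_course) as.numeric(t(courses)) else numeric(0)),
      type = c(rep("expose", length(unlist(expo))),
               rep("sample", length(spec$schedule)),
               rep(c("abx_on", "abx_off"), n_course)),
      taxon = c(rep(seq_len(S), vapply(expo, length, 0L)),
                rep(NA_integer_, length(spec$schedule)),
                rep(NA_integer_, 2L * n_course)))
    events <- events[order(events$time,
                           match(events$type,
                                 c("abx_on", "abx_off", "expose",
                                   "sample"))), ]
    x <- numeric(S)
    t_now <- 0
    abx_on <- FALSE
    p_now <- params
    obs <- matrix(NA_real_, length(spec$schedule), S)
    abx_at_sample <- logical(length(spec$schedule))
    samp_i <- 0L
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      x <- integrate_for(p_now, x, ev$time - t_now, settings)
      t_now <- ev$time
      if (ev$type == "expose") {
        x[ev$taxon] <- x[ev$taxon] + spec$introduction_density
      } else if (ev$type == "abx_on") {
        abx_on <- TRUE
        p_now$r <- params$r + eps[taxa]
      } else if (ev$type == "abx_off") {
        abx_on <- FALSE
        p_now$r <- params$r
      } else {
        samp_i <- samp_i + 1L
        noisy <- x * rlnorm(S, 0, spec$noise_sd)
        noisy[noisy < spec$detection_limit] <- 0
        obs[samp_i, ] <- noisy
        abx_at_sample[samp_i] <- abx_on
      }
    }
    rows <- data.frame(
      subject = sid,
      taxon = rep(taxa, each = length(spec$schedule)),
      time = rep(spec$schedule, S),
      abundance = as.numeric(obs),
      abx = rep(abx_at_sample, S))
    names(rows)[names(rows) == "abx"] <- spec$abx_name
    all_rows[[subj]] <- rows
    arrivals[[subj]] <- data.frame(subject = sid, taxon = taxa,
                                   arrival = unname(arr))
  }
  series <- do.call(rbind, all_rows)
  series[[spec$abx_name]] <- as.numeric(series[[spec$abx_name]])
  rownames(series) <- NULL
  list(series = series,
       truth = list(arrivals = do.call(rbind, arrivals),
                    params = params, epsilon = eps,
                    abx_courses = do.call(rbind, abx_courses)))
}

#' Write a simulated cohort to disk
#'
#' @param cohort output of [simulate_cohort()].
#' @param csv_path long-format CSV the `analyze` pipeline reads.
#' @param truth_path optional ground-truth JSON.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, csv_path, truth_path = NULL) {
  write.csv(cohort$series, csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(arrivals = tr$arrivals,
           species = tr$params$species, r = tr$params$r,
           s = tr$params$s, A = unname(tr$params$A),
           K_T = tr$params$K_T, epsilon = as.list(tr$epsilon)),
      truth_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(csv_path)
}
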