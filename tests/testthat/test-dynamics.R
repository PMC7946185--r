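params_2sp <- function(a12 = 0, a21 = 0, r = c(1, 1), s = c(1, 1), ...) {
  A <- matrix(0, 2, 2); A[1, 2] <- a12; A[2, 1] <- a21
  community_parameters(r = r, s = s, A = A, ...)
}

test_that("gLV derivative matches closed-form arithmetic", {
  p <- community_parameters(r = 1, s = 1)
  expect_equal(glv_derivative(0.5, p), 0.25)
  expect_equal(glv_derivative(0, p), 0)

  p2 <- params_2sp(a12 = 0.5)
  expect_equal(glv_derivative(c(1, 1), p2), c(0.5, 0))
  # extinction is absorbing for any parameters
  expect_equal(glv_derivative(c(0, 1), p2)[1], 0)
  # feeding adds f to every intrinsic rate
  p3 <- community_parameters(r = 1, s = 1, f = 0.25)
  expect_equal(glv_derivative(0.5, p3), 0.5 * (1.25 - 0.5))
  expect_error(glv_derivative(c(1, 2, 3), p2), "match")
})

test_that("capped derivative is zero-sum at the cap", {
  # hand-computed: negligible self-regulation, x = (5000, 5000) at cap,
  # r = (1, 0.5): weighted mean rate 0.75, so rates are +/-1250
  p <- params_2sp(r = c(1, 0.5), s = c(1e-9, 1e-9))
  d <- capped_derivative(c(5000, 5000), p)
  expect_equal(d, c(1250, -1250), tolerance = 1e-4)

  # identical species at the cap: both rates zero by symmetry
  psym <- params_2sp(r = c(1, 1))
  expect_equal(capped_derivative(c(5000, 5000), psym), c(0, 0))

  # property: total derivative is exactly zero at/above the cap
  set.seed(11)
  for (k in 1:50) {
    S <- sample(2:6, 1)
    A <- matrix(rnorm(S * S, 0, 0.3), S, S); diag(A) <- 0
    p <- community_parameters(r = runif(S, -1, 1), s = runif(S, 0.5, 2),
                              A = A, K_T = 1e4)
    x <- runif(S); x <- x / sum(x) * p$K_T * runif(1, 1, 1.2)
    expect_lt(abs(sum(capped_derivative(x, p))),
              1e-10 * sum(abs(capped_derivative(x, p)) + 1))
  }
  # below the cap it equals the plain derivative
  p <- params_2sp(a12 = 0.3, a21 = -0.2)
  x <- c(0.4, 0.7)
  expect_equal(capped_derivative(x, p), glv_derivative(x, p))
})

test_that("integration reaches fixed points and respects the cap", {
  p <- community_parameters(r = 1, s = 0.01, K_T = 1e6)
  run <- integrate_to_equilibrium(p, 1)
  expect_true(run$converged)
  expect_equal(run$x, 100, tolerance = 1e-6)

  # obligate mutualist invading alone goes extinct
  ob <- fixture_community("obligate_pair")
  run <- integrate_to_equilibrium(ob, c(1e-3 * ob$K_T, 0))
  expect_equal(run$x, c(0, 0))

  # cap invariant along a growing trajectory
  strong <- params_2sp(r = c(2, 2), s = c(1e-4, 1e-4), K_T = 1e4)
  run <- integrate_to_equilibrium(strong, c(10, 10), record = TRUE)
  expect_lte(run$max_total, strong$K_T * (1 + 1e-10))
  expect_lte(max(rowSums(run$trajectory)), strong$K_T * (1 + 1e-10))
})

test_that("capped and uncapped dynamics agree below the cap", {
  set.seed(21)
  for (k in 1:5) {
    comm <- sample_climax_community(
      sampler_settings(S = 4, sigma = 0.05, P_m = 0.5))
    x0 <- runif(4, 0.05, 0.5)
    capped <- integrate_to_equilibrium(comm, x0, sim_settings(capped = TRUE))
    plain <- integrate_to_equilibrium(comm, x0, sim_settings(capped = FALSE))
    expect_lt(sum(capped$x), comm$K_T)  # interior regime
    expect_equal(capped$x, plain$x, tolerance = 1e-5)
  }
})

test_that("subset equilibria solve the linear system", {
  p <- community_parameters(r = 1, s = 2)
  eq <- subset_equilibrium(p, 1)
  expect_equal(eq$abundances, 0.5)
  expect_true(eq$feasible && eq$stable)

  pc <- params_2sp(a12 = -0.5, a21 = -0.5)
  eq <- subset_equilibrium(pc, 1:2)
  expect_equal(eq$abundances, c(2, 2) / 3)
  expect_true(eq$stable)

  # hand-solved: x2 = (-2 + 0.1 x1), system gives a negative component
  pn <- params_2sp(a12 = 0.1, a21 = 0.1, r = c(1, -2))
  eq <- subset_equilibrium(pn, 1:2)
  expect_false(eq$feasible)
  expect_error(subset_equilibrium(p, integer(0)), "nonempty")
})

test_that("viability matches sign(r + f) for single species, exactly", {
  set.seed(31)
  for (r in c(-1, -0.02, 0, 0.02, 1)) {
    for (f in c(0, 0.05)) {
      p <- community_parameters(r = r, s = 1, f = f)
      expect_identical(assess_viability(p, 1)$viable, r + f > 0,
                       label = sprintf("r=%g f=%g", r, f))
    }
  }
  # empty set is viable by convention
  expect_true(assess_viability(community_parameters(1, 1), integer(0))$viable)
})

test_that("viability agrees with the multi-start oracle on random systems", {
  for (k in 1:8) {
    comm <- random_3sp_community(seed = 400 + k)
    for (mask in 1:7) {
      subset <- glvmap:::members_from_mask(mask, 3)
      expect_identical(
        assess_viability(comm, subset)$viable,
        oracle_viable(comm, subset, n_starts = 40, seed = 400 + k + mask),
        label = sprintf("community %d subset {%s}", k,
                        paste(subset, collapse = ",")))
    }
  }
})

test_that("cap-bound states are viable only if they survive perturbation", {
  ob <- fixture_community("obligate_pair")
  v <- assess_viability(ob, 1:2)
  expect_true(v$viable)
  expect_true(v$at_cap)
  expect_equal(sum(v$abundances), ob$K_T, tolerance = 1e-6)
  # singletons of the pair cannot persist
  expect_false(assess_viability(ob, 1)$viable)
})
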