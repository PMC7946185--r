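# a chain where the pioneer itself needs feeding: species 1 has r < 0 but
# r + f > 0, species 2 is an obligate commensal of 1, and the full pair is
# stable without feeding thanks to the benefit flowing back from 2.
feed_rescued_chain <- function() {
  A <- matrix(0, 2, 2)
  A[2, 1] <- 10   # 2 feeds on 1, strongly
  A[1, 2] <- 0.3  # 1 gains a little back (cross-feeding)
  community_parameters(r = c(-0.05, -0.5), s = c(1, 1), A = A)
}

test_that("consortium arrivals bridge gaps monotonically", {
  ob <- build_assembly_map(fixture_community("obligate_pair"))
  expect_false(map_metrics(ob)$can_assemble)
  ob2 <- augment_with_consortia(ob, 2)
  m2 <- map_metrics(ob2)
  expect_true(m2$can_assemble)
  expect_true(all(ob$nodes %in% ob2$nodes))
  expect_gte(nrow(ob2$edges), nrow(ob$edges))

  # a fully assemblable diamond gains edges and paths
  p <- community_parameters(r = c(1, 0.8), s = c(1, 1))
  d1 <- build_assembly_map(p)
  d2 <- augment_with_consortia(d1, 2)
  expect_gt(nrow(d2$edges), nrow(d1$edges))
  expect_gt(map_metrics(d2)$n_paths, map_metrics(d1)$n_paths)

  # the triangle needs all three members at once
  tri <- build_assembly_map(fixture_community("mutualist_triangle"))
  expect_false(map_metrics(augment_with_consortia(tri, 2))$can_assemble)
  expect_true(map_metrics(augment_with_consortia(tri, 3))$can_assemble)

  expect_error(augment_with_consortia(ob, 1), ">= 2")
  expect_error(augment_with_consortia(ob, 2, max_invasions = 0), "budget")
})

test_that("multilayer feeding maps validate input and classify layers", {
  p <- community_parameters(r = c(1, 0.8), s = c(1, 1))
  expect_error(build_multilayer_feeding_map(p, 0), "f = 0")

  # a species viable only when fed is not an interlayer node
  ps <- community_parameters(r = -0.05, s = 1)
  mm <- build_multilayer_feeding_map(ps, 0.1, require_viable_climax = FALSE)
  expect_false(1L %in% mm$unfed$nodes)
  expect_true(1L %in% mm$fed$nodes)
  expect_identical(mm$interlayer, 0L)

  # independent growers: feeding preserves viability of every subset
  mi <- build_multilayer_feeding_map(p, 0.1)
  expect_identical(mi$interlayer, mi$unfed$nodes)
  expect_identical(sort(mi$fed$nodes), sort(mi$unfed$nodes))
})

test_that("feed-early-then-wean paths are found and validated", {
  # assemblable unfed: path stays in the unfed layer
  p <- community_parameters(r = c(1, 0.8), s = c(1, 1))
  res <- multilayer_can_assemble(build_multilayer_feeding_map(p, 0.1))
  expect_true(res$can_assemble)
  expect_identical(res$n_switches, 0L)
  expect_true(all(res$path$layer == "unfed"))

  # pioneer needs feeding, climax stands unfed: at least one switch
  ch <- feed_rescued_chain()
  expect_true(assess_viability(ch, 1:2)$viable)       # unfed climax ok
  expect_false(assess_viability(ch, 1)$viable)        # pioneer not alone
  base <- map_metrics(build_assembly_map(ch))
  expect_false(base$can_assemble)                     # fractured unfed
  mm <- build_multilayer_feeding_map(ch, 0.1)
  res <- multilayer_can_assemble(mm)
  expect_true(res$can_assemble)
  expect_gte(res$n_switches, 1L)
  # witness path is consistent edge-by-edge with the layer maps
  for (k in seq_len(nrow(res$path) - 1)) {
    a <- res$path[k, ]; b <- res$path[k + 1, ]
    if (a$layer != b$layer) {
      expect_identical(a$mask, b$mask)
      expect_true(a$mask %in% mm$interlayer)
    } else {
      lm <- if (a$layer == "unfed") mm$unfed else mm$fed
      expect_true(any(lm$edges$from == a$mask & lm$edges$to == b$mask))
    }
  }
  expect_identical(res$path$mask[nrow(res$path)], mm$unfed$climax)
  expect_identical(res$path$layer[nrow(res$path)], "unfed")

  # climax viable only when fed: cannot count as assembled
  pf <- community_parameters(r = -0.05, s = 1)
  resf <- multilayer_can_assemble(
    build_multilayer_feeding_map(pf, 0.1, require_viable_climax = FALSE))
  expect_false(resf$can_assemble)
})

test_that("feasibility profiles show the early-boost / late-harm pattern", {
  p <- community_parameters(r = c(1, 0.8), s = c(1, 1))
  pr <- feeding_feasibility_profile(p, 0.1)
  expect_equal(pr$frac_unfed, rep(1, 3))
  expect_equal(pr$frac_fed, rep(1, 3))
  expect_equal(pr$n_subsets, choose(2, 0:2))

  # an r < 0 commensal is rescued at size 1 only when fed
  A <- matrix(0, 2, 2); A[2, 1] <- 2
  pc <- community_parameters(r = c(1, -0.1), s = c(1, 1), A = A)
  prc <- feeding_feasibility_profile(pc, 0.2)
  expect_gt(prc$frac_fed[2], prc$frac_unfed[2])

  # feeding can destroy coexistence: with a superlinear competitive hit
  # (a21 < -1) the uniform boost shifts the interior equilibrium of the
  # weaker species negative (x2* ~ (r2 + f) + a21 (r1 + f), slope 1 + a21
  # < 0 in f), excluding it
  Ax <- matrix(0, 2, 2); Ax[1, 2] <- -0.5; Ax[2, 1] <- -1.2
  px <- community_parameters(r = c(0.7, 0.9), s = c(1, 1), A = Ax)
  expect_true(assess_viability(px, 1:2)$viable)
  pxf <- px; pxf$f <- 0.6
  expect_false(assess_viability(pxf, 1:2)$viable)
  prx <- feeding_feasibility_profile(px, 0.6)
  expect_lt(prx$frac_fed[3], prx$frac_unfed[3])
  expect_error(feeding_feasibility_profile(p, 0), "f must be")
})
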