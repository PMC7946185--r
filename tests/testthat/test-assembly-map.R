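test_that("invasion outcomes cover all transition categories", {
  # empty set invaded by an independent grower
  ind <- fixture_community("independent")
  out <- invasion_outcome(ind, integer(0), 1)
  expect_identical(out$target, 1L)
  expect_identical(out$category, "augment")

  # empty set invaded by an obligate mutualist fails
  ob <- fixture_community("obligate_pair")
  out <- invasion_outcome(ob, integer(0), 1)
  expect_identical(out$category, "fail")

  # competitive exclusion: 2 invades {1} and replaces it
  ce <- fixture_community("competitive_exclusion")
  out <- invasion_outcome(ce, 1, 2)
  expect_identical(out$target, 2L)
  expect_identical(out$category, "replace")

  expect_error(invasion_outcome(ind, 1, integer(0)), "nonempty")
  expect_error(invasion_outcome(ind, 1, 1), "disjoint")
})

test_that("archetype maps have their designed structure", {
  # two independent species: the diamond
  p <- community_parameters(r = c(1, 0.8), s = c(1, 1))
  map <- build_assembly_map(p)
  met <- map_metrics(map)
  expect_identical(length(map$nodes), 4L)
  expect_identical(met$n_edges, 4L)
  expect_identical(met$n_paths, 2)
  expect_equal(met$predictability, 0.5)
  expect_identical(met$secondary_colonizers, 0L)

  # obligate pair: fractured at single arrivals
  ob <- build_assembly_map(fixture_community("obligate_pair"))
  expect_identical(ob$nodes, c(0L, 3L))
  mob <- map_metrics(ob)
  expect_false(mob$can_assemble)
  expect_equal(mob$predictability, 0)
  expect_identical(mob$secondary_colonizers, 2L)

  # commensal chain: one forced path
  ch <- map_metrics(build_assembly_map(fixture_community("commensal_chain")))
  expect_identical(ch$n_paths, 1)
  expect_equal(ch$predictability, 1)
  expect_identical(ch$secondary_colonizers, 2L)

  # humpty dumpty: viable climax, no assembly path
  hd <- build_assembly_map(fixture_community("humpty_dumpty"))
  mhd <- map_metrics(hd)
  expect_true(hd$climax %in% hd$nodes)
  expect_false(mhd$can_assemble)
  expect_identical(mhd$n_viable, 20L)
})

test_that("augment edges land on viable nodes and purely competitive
           communities with positive growth have no secondary colonizers", {
  set.seed(55)
  for (k in 1:3) {
    comm <- sample_climax_community(
      sampler_settings(S = 4, sigma = 0.15, P_m = 0,
                       r_spec = function(n) runif(n, 0.2, 1)))
    map <- build_assembly_map(comm, check_climax = FALSE)
    met <- map_metrics(map)
    expect_identical(met$secondary_colonizers, 0L)
    aug <- map$edges[map$edges$category == "augment", ]
    for (tmask in unique(aug$to)) {
      expect_true(tmask %in% map$nodes)
      expect_true(assess_viability(
        comm, glvmap:::members_from_mask(tmask, comm$S))$viable)
    }
  }
})

test_that("map construction matches the brute-force oracle", {
  for (k in 1:5) {
    comm <- random_3sp_community(seed = 700 + k)
    map <- build_assembly_map(comm, check_climax = FALSE)
    orc <- oracle_map(comm, seed = 700 + k)
    expect_true(map_matches_oracle(map, orc),
                label = sprintf("community %d matches oracle", k))
  }
})

test_that("enumeration limit and non-viable climax are refused", {
  p <- community_parameters(r = rep(1, 17), s = rep(1, 17))
  expect_error(build_assembly_map(p), "enumeration limit")
  ce <- fixture_community("competitive_exclusion")
  expect_error(build_assembly_map(ce), "not viable")
  # without the check the climax is simply absent and metrics degrade
  m <- build_assembly_map(ce, check_climax = FALSE)
  met <- map_metrics(m)
  expect_false(met$can_assemble)
  expect_equal(met$predictability, 0)
})

test_that("maps serialize to JSON, CSV and GraphML", {
  map <- build_assembly_map(fixture_community("commensal_chain"))
  js <- file.path(tempdir(), "map.json")
  write_assembly_map(map, js)
  obj <- jsonlite::read_json(js)
  expect_length(obj$nodes, length(map$nodes))
  expect_length(obj$edges, nrow(map$edges))

  cs <- file.path(tempdir(), "map.csv")
  write_assembly_map(map, cs)
  df <- read.csv(cs)
  expect_identical(nrow(df), nrow(map$edges))
  expect_true(all(c("from", "to", "category") %in% names(df)))

  gm <- file.path(tempdir(), "map.graphml")
  write_assembly_map(map, gm)
  g <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::gorder(g), length(map$nodes))
})
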