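#' Resolve the outcome of an invasion
#'
#' Residents start at their equilibrium abundances, each invader at a low
#' density (default `1e-3 * K_T`), and the capped dynamics are integrated
#' to convergence. The surviving species set is the target state.
#' Categories: `augment` (all arrivals join, nobody lost), `replace`
#' (community size maintained but membership changed), `crash` (diversity
#' reduced), `fail` (the resident set is unchanged).
#'
#' @param params a [community_parameters()] object.
#' @param resident integer vector of resident species (may be empty);
#'   must be a viable subcommunity.
#' @param invaders nonempty integer vector of arriving species, disjoint
#'   from the residents.
#' @param settings a [sim_settings()] object.
#' @param resident_equilibrium optional precomputed `equilibrium_result`
#'   for the residents (skips one viability check).
#' @return list with `target` (surviving species indices), `category`,
#'   `converged`.
#' @export
invasion_outcome <- function(params, resident, invaders,
                             settings = sim_settings(),
                             resident_equilibrium = NULL) {
  settings <- resolve_settings(settings, params)
  invaders <- sort(unique(as.integer(invaders)))
  resident <- sort(unique(as.integer(resident)))
  if (length(invaders) == 0L) stop("invaders must be nonempty", call. = FALSE)
  if (length(intersect(resident, invaders)) > 0L)
    stop("invaders must be disjoint from residents", call. = FALSE)
  if (is.null(resident_equilibrium)) {
    resident_equilibrium <- assess_viability(params, resident, settings)
    if (!resident_equilibrium$viable)
      stop("resident subcommunity is not viable", call. = FALSE)
  }
  x0 <- numeric(params$S)
  x0[resident] <- resident_equilibrium$abundances
  dens <- settings$invader_density
  if (length(resident) > 0) {
    # keep propagules genuinely rare relative to the residents (but above
    # the extinction clamp), whatever the community's abundance scale
    dens <- max(2 * settings$extinction_threshold,
                min(dens, 0.01 * min(resident_equilibrium$abundances)))
  }
  x0[invaders] <- dens
  run <- integrate_to_equilibrium(params, x0, settings)
  target <- which(run$x > settings$extinction_threshold)
  category <- classify_transition(resident, invaders, target)
  list(target = target, category = category, converged = run$converged,
       final_state = run$x)
}

classify_transition <- function(resident, invaders, target) {
  if (setequal(target, resident)) return("fail")
  joined <- sort(union(resident, invaders))
  if (setequal(target, joined)) return("augment")
  if (length(target) >= length(resident)) return("replace")
  "crash"
}

#' Build the assembly map of a climax community
#'
#' Enumerates all `2^S` subsets, keeps the viable ones (the empty set is
#' always a node), and resolves every invasion of up to `consortium_size`
#' absent species into each viable node. Non-failing invasions become
#' directed, category-labelled edges. Invasion outcomes that settle on a
#' state not in the viable-node list are re-integrated with a 10x horizon;
#' if the mismatch persists an error is raised rather than silently
#' coercing the outcome.
#'
#' @param params a [community_parameters()] object whose full community is
#'   viable.
#' @param consortium_size maximum number of species arriving together
#'   (1 = the base map).
#' @param settings a [sim_settings()] object.
#' @param max_S enumeration refusal limit (default 16).
#' @param check_climax verify full-community viability first.
#' @return an object of class `assembly_map`: `S`, `species`, `climax`
#'   (bitmask), `nodes` (integer bitmasks, sorted), `edges` (data.frame
#'   `from`, `to`, `arrivals`, `category`), `equilibria` (list keyed by
#'   bitmask as character), `params`, `consortium_size`.
#' @export
build_assembly_map <- function(params, consortium_size = 1,
                               settings = sim_settings(), max_S = 16,
                               check_climax = TRUE) {
  S <- params$S
  if (S > max_S)
    stop(sprintf(paste0(
      "S = %d exceeds the exhaustive enumeration limit (%d); assembly ",
      "maps require 2^S viability tests. Reduce the pool or raise max_S ",
      "explicitly if you accept the cost."), S, max_S), call. = FALSE)
  settings <- resolve_settings(settings, params)

  if (check_climax) {
    clim <- assess_viability(params, seq_len(S), settings)
    if (!clim$viable)
      stop("full community is not viable; no climax to map", call. = FALSE)
  }

  # enumerate viable subsets
  masks <- 0:(2^S - 1L)
  nodes <- integer(0)
  equilibria <- list()
  for (mask in masks) {
    members <- members_from_mask(mask, S)
    res <- assess_viability(params, members, settings)
    if (res$viable) {
      nodes <- c(nodes, mask)
      equilibria[[as.character(mask)]] <- res
    }
  }
  node_set <- new.env(parent = emptyenv())
  for (nd in nodes) assign(as.character(nd), TRUE, envir = node_set)

  edges <- resolve_edges(params, nodes, equilibria, node_set,
                         consortium_size, settings, S)
  structure(list(S = S, species = params$species,
                 climax = mask_from_members(seq_len(S)),
                 nodes = sort(nodes), edges = edges,
                 equilibria = equilibria, params = params,
                 consortium_size = consortium_size, settings = settings),
            class = "assembly_map")
}

resolve_edges <- function(params, nodes, equilibria, node_set,
                          consortium_size, settings, S,
                          min_arrivals = 1) {
  from <- integer(0); to <- integer(0)
  arrivals_l <- list(); category <- character(0)
  for (mask in nodes) {
    members <- members_from_mask(mask, S)
    absent <- setdiff(seq_len(S), members)
    if (length(absent) == 0L) next
    eq <- equilibria[[as.character(mask)]]
    for (m in seq(min_arrivals, consortium_size)) {
      if (m > length(absent)) break
      combos <- if (m == 1) matrix(absent, nrow = 1) else combn(absent, m)
      for (ci in seq_len(ncol(combos))) {
        inv <- combos[, ci]
        out <- invasion_outcome(params, members, inv, settings,
                                resident_equilibrium = eq)
        if (out$category == "fail") next
        tmask <- mask_from_members(out$target)
        if (!exists(as.character(tmask), envir = node_set)) {
          # settled on a non-viable-looking state: retry with longer horizon
          longer <- settings; longer$horizon <- settings$horizon * 10
          out <- invasion_outcome(params, members, inv, longer,
                                  resident_equilibrium = eq)
          tmask <- mask_from_members(out$target)
          if (out$category == "fail") next
          if (!exists(as.character(tmask), envir = node_set))
            stop(sprintf(
              "invasion of %s into %s settled on non-viable state %s",
              paste(params$species[inv], collapse = "+"),
              mask_label(mask, params$species, S),
              mask_label(tmask, params$species, S)), call. = FALSE)
        }
        from <- c(from, mask); to <- c(to, tmask)
        arrivals_l <- c(arrivals_l, list(inv))
        category <- c(category, out$category)
      }
    }
  }
  data.frame(from = from, to = to,
             arrivals = vapply(arrivals_l, paste, "", collapse = "+"),
             category = category, stringsAsFactors = FALSE)
}

#' @export
print.assembly_map <- function(x, ...) {
  cat(sprintf(
    "assembly_map: S = %d, %d viable subcommunities, %d edges (m <= %d)\n",
    x$S, length(x$nodes), nrow(x$edges), x$consortium_size))
  invisible(x)
}

#' Summary metrics of an assembly map
#'
#' Counts viable subcommunities and edges, decides whether the climax can
#' assemble from the uncolonized state, counts the distinct directed simple
#' paths from the empty set to the climax, and derives a predictability
#' score `1 / n_paths` (0 when no path exists). Also reports the path
#' entropy alternative (`log(n_paths)`), the number of secondary
#' colonizers (climax species whose singleton community is not viable),
#' and their fraction of the pool.
#'
#' @param map an `assembly_map`.
#' @param path_cap stop counting paths beyond this many (flag set).
#' @return list of class `map_metrics`.
#' @export
map_metrics <- function(map, path_cap = 1e7) {
  idx <- setNames(seq_along(map$nodes), as.character(map$nodes))
  src <- idx[["0"]]
  tgt <- unname(idx[as.character(map$climax)])
  if (is.na(tgt)) {
    # climax itself not viable (map built with check_climax = FALSE)
    cnt <- list(count = 0, capped = FALSE)
  } else if (nrow(map$edges) > 0) {
    cnt <- cpp_count_simple_paths(
      as.integer(idx[as.character(map$edges$from)]) - 1L,
      as.integer(idx[as.character(map$edges$to)]) - 1L,
      length(map$nodes), src - 1L, tgt - 1L, path_cap)
  } else {
    cnt <- list(count = 0, capped = FALSE)
  }
  n_paths <- cnt$count
  singleton_viable <- vapply(seq_len(map$S), function(i)
    mask_from_members(i) %in% map$nodes, logical(1))
  structure(list(
    n_viable = length(map$nodes),
    n_edges = nrow(map$edges),
    can_assemble = n_paths >= 1,
    n_paths = n_paths,
    paths_capped = isTRUE(cnt$capped),
    predictability = if (n_paths >= 1) 1 / n_paths else 0,
    path_entropy = if (n_paths >= 1) log(n_paths) else NA_real_,
    secondary_colonizers = sum(!singleton_viable),
    secondary_fraction = mean(!singleton_viable)),
    class = "map_metrics")
}

#' @export
print.map_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("map_metrics: %d viable subcommunities, %d edges, ",
           "can_assemble = %s\n  n_paths = %g, predictability = %.4g, ",
           "secondary colonizers = %d\n"),
    x$n_viable, x$n_edges, x$can_assemble, x$n_paths, x$predictability,
    x$secondary_colonizers))
  invisible(x)
}

#' Serialize an assembly map
#'
#' JSON keeps nodes as sorted species-name lists and edges with category
#' labels; the CSV dialect writes an edge list. GraphML export (via
#' igraph) is provided for external viewers.
#'
#' @param map an `assembly_map`.
#' @param path output file; format chosen by extension
#'   (`.json`, `.csv`, `.graphml`).
#' @return the path, invisibly.
#' @export
write_assembly_map <- function(map, path) {
  lab <- function(mask) as.list(map$species[members_from_mask(mask, map$S)])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      species = map$species,
      climax = lab(map$climax),
      nodes = lapply(map$nodes, lab),
      edges = lapply(seq_len(nrow(map$edges)), function(k) list(
        from = lab(map$edges$from[k]), to = lab(map$edges$to[k]),
        arrivals = as.list(map$species[as.integer(
          strsplit(map$edges$arrivals[k], "\\+")[[1]])]),
        category = map$edges$category[k]))),
      path, digits = NA, auto_unbox = TRUE)
  } else if (grepl("\\.graphml$", path)) {
    g <- assembly_map_igraph(map)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- map$edges
    df$from <- vapply(df$from, function(m) mask_label(m, map$species, map$S), "")
    df$to <- vapply(df$to, function(m) mask_label(m, map$species, map$S), "")
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# igraph view of the map (node names are bitmask strings).
assembly_map_igraph <- function(map) {
  g <- igraph::make_empty_graph(n = length(map$nodes), directed = TRUE)
  igraph::V(g)$name <- as.character(map$nodes)
  igraph::V(g)$label <- vapply(map$nodes, function(m)
    mask_label(m, map$species, map$S), "")
  if (nrow(map$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(as.character(map$edges$from), as.character(map$edges$to)),
      category = map$edges$category)
  }
  g
}
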