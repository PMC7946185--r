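#' Add consortium-arrival edges to an assembly map
#'
#' Extends a base map by resolving every simultaneous arrival of 2..`m`
#' absent species into every viable node. Joint arrivals let communities
#' jump gaps in their assembly map, so `can_assemble` can flip from
#' `FALSE` to `TRUE` but never the reverse: base nodes and edges are
#' preserved.
#'
#' @param map a base `assembly_map`.
#' @param m maximum consortium size (>= 2).
#' @param max_invasions refusal bound on the number of extra invasion
#'   simulations.
#' @return a new `assembly_map` with `consortium_size = m`.
#' @export
augment_with_consortia <- function(map, m, max_invasions = 2e5) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (m <= map$consortium_size) return(map)
  params <- map$params
  settings <- resolve_settings(map$settings, params)
  S <- map$S
  # combinatorial budget
  n_new <- 0
  for (mask in map$nodes) {
    n_abs <- S - mask_size(mask, S)
    for (k in seq(max(2, map$consortium_size + 1), min(m, n_abs)))
      n_new <- n_new + choose(n_abs, k)
  }
  if (n_new > max_invasions)
    stop(sprintf(
      "consortium augmentation needs %g invasion simulations (> %g budget)",
      n_new, max_invasions), call. = FALSE)
  node_set <- new.env(parent = emptyenv())
  for (nd in map$nodes) assign(as.character(nd), TRUE, envir = node_set)
  extra <- resolve_edges(params, map$nodes, map$equilibria, node_set,
                         consortium_size = m, settings = settings, S = S,
                         min_arrivals = map$consortium_size + 1)
  map$edges <- rbind(map$edges, extra)
  map$consortium_size <- m
  map
}

#' Multilayer assembly map under host feeding
#'
#' Builds two assembly maps for the same community: an unfed layer
#' (`f = 0`) and a fed layer in which every intrinsic growth rate is
#' boosted by `f`. Subcommunities viable in both layers are interlayer
#' nodes: the host can switch feeding on or off there without losing any
#' member.
#'
#' @param params a [community_parameters()] object (its `f` is ignored;
#'   the unfed layer uses `f = 0`).
#' @param f feeding constant (1/time), > 0.
#' @param settings a [sim_settings()] object.
#' @param require_viable_climax require the unfed climax to be viable
#'   (the usual case: the final community must stand without feeding).
#' @return list of class `multilayer_map`: `unfed`, `fed`, `interlayer`
#'   (bitmask vector), `f`.
#' @export
build_multilayer_feeding_map <- function(params, f,
                                         settings = sim_settings(),
                                         require_viable_climax = TRUE) {
  if (f <= 0)
    stop("f must be > 0 (f = 0 would make the layers identical)",
         call. = FALSE)
  unfed_params <- params; unfed_params$f <- 0
  fed_params <- params; fed_params$f <- f
  unfed <- build_assembly_map(unfed_params, settings = settings,
                              check_climax = require_viable_climax)
  fed <- build_assembly_map(fed_params, settings = settings,
                            check_climax = FALSE)
  structure(list(unfed = unfed, fed = fed,
                 interlayer = intersect(unfed$nodes, fed$nodes), f = f),
            class = "multilayer_map")
}

#' Can a community assemble across the feeding multilayer network?
#'
#' Searches for a directed path from the uncolonized state to the climax
#' node *of the unfed layer* (the final community must persist without
#' feeding), using intra-layer assembly edges plus free layer switches at
#' any subcommunity viable in both layers. The witness path annotates
#' where feeding is switched on and off.
#'
#' @param mm a `multilayer_map`.
#' @return list with `can_assemble`, `path` (data.frame `state`, `layer`)
#'   or `NULL`, `n_switches`.
#' @export
multilayer_can_assemble <- function(mm) {
  S <- mm$unfed$S
  climax <- mm$unfed$climax
  inter <- mm$interlayer
  # node ids: "<mask>.<layer>" with layer u/f
  adj <- list()
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (layer in c("u", "f")) {
    lm <- if (layer == "u") mm$unfed else mm$fed
    for (k in seq_len(nrow(lm$edges)))
      add_edge(paste0(lm$edges$from[k], ".", layer),
               paste0(lm$edges$to[k], ".", layer))
  }
  for (nd in inter) {
    add_edge(paste0(nd, ".u"), paste0(nd, ".f"))
    add_edge(paste0(nd, ".f"), paste0(nd, ".u"))
  }
  # BFS from both starts (empty state is an interlayer node by convention)
  target <- paste0(climax, ".u")
  starts <- c("0.u", "0.f")
  prev <- list()
  seen <- new.env(parent = emptyenv())
  queue <- character(0)
  for (st in starts) {
    assign(st, TRUE, envir = seen)
    queue <- c(queue, st)
  }
  found <- FALSE
  while (length(queue) > 0 && !found) {
    v <- queue[1]; queue <- queue[-1]
    if (v == target) { found <- TRUE; break }
    for (w in adj[[v]] %||% character(0)) {
      if (!exists(w, envir = seen)) {
        assign(w, TRUE, envir = seen)
        prev[[w]] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!found)
    return(list(can_assemble = FALSE, path = NULL, n_switches = NA_integer_))
  # reconstruct
  node <- target; chain <- character(0)
  while (!is.null(node)) {
    chain <- c(node, chain)
    node <- prev[[node]]
  }
  parts <- strsplit(chain, ".", fixed = TRUE)
  path <- data.frame(
    state = vapply(parts, function(p)
      mask_label(as.integer(p[1]), mm$unfed$species, S), ""),
    mask = vapply(parts, function(p) as.integer(p[1]), 0L),
    layer = vapply(parts, function(p) ifelse(p[2] == "u", "unfed", "fed"),
                   ""))
  n_switch <- sum(path$layer[-1] != path$layer[-nrow(path)])
  list(can_assemble = TRUE, path = path, n_switches = n_switch)
}

#' Per-size feasibility profile with and without feeding
#'
#' For each community size k, the fraction of the `choose(S, k)` subsets
#' that are viable, in the fed and the unfed layer. Feeding typically
#' raises the feasibility of small subcommunities (rescuing dependent
#' pioneers) but can lower it for large ones (boosted growth drives
#' competitive exclusion).
#'
#' @param params a [community_parameters()] object.
#' @param f feeding constant, > 0.
#' @param settings a [sim_settings()] object.
#' @return data.frame of class `feasibility_profile` with columns `size`,
#'   `n_subsets`, `frac_unfed`, `frac_fed`.
#' @export
feeding_feasibility_profile <- function(params, f,
                                        settings = sim_settings()) {
  if (f <= 0) stop("f must be > 0", call. = FALSE)
  S <- params$S
  counts <- matrix(0, nrow = S + 1, ncol = 2,
                   dimnames = list(0:S, c("unfed", "fed")))
  for (layer in c("unfed", "fed")) {
    p <- params
    p$f <- if (layer == "fed") f else 0
    for (mask in 0:(2^S - 1L)) {
      members <- members_from_mask(mask, S)
      if (assess_viability(p, members, settings)$viable)
        counts[length(members) + 1, layer] <-
          counts[length(members) + 1, layer] + 1
    }
  }
  denom <- choose(S, 0:S)
  out <- data.frame(size = 0:S, n_subsets = denom,
                    frac_unfed = counts[, "unfed"] / denom,
                    frac_fed = counts[, "fed"] / denom)
  class(out) <- c("feasibility_profile", class(out))
  out
}
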