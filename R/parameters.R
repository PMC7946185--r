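#' Community parameters for capped generalized Lotka-Volterra dynamics
#'
#' Bundles everything that defines one community: intrinsic growth rates
#' `r`, self-regulation `s`, the interspecies interaction matrix `A`
#' (`A[i, j]` is the per-abundance effect of species `j` on species `i`;
#' the diagonal is zero because self-regulation lives in `s`), a total
#' population cap `K_T` above which growth becomes zero-sum competition
#' for space, and an optional host-feeding supplement `f` added to every
#' intrinsic growth rate.
#'
#' @param r numeric vector of intrinsic growth rates (1/time).
#' @param s numeric vector of self-regulation coefficients
#'   (per abundance per time); all entries must be strictly positive.
#' @param A square interaction matrix with zero diagonal
#'   (per abundance per time). Defaults to no interactions.
#' @param K_T total population cap (abundance units). Default 10000.
#' @param f host-feeding supplement added to every `r[i]` (1/time).
#' @param species optional character vector of species names.
#'
#' @return An object of class `community_parameters` with fields
#'   `S`, `r`, `s`, `A`, `K_T`, `f`, `species`.
#' @examples
#' p <- community_parameters(r = c(1, 0.5), s = c(1, 1))
#' p$S
#' @export
community_parameters <- function(r, s, A = NULL, K_T = 10000, f = 0,
                                 species = NULL) {
  S <- length(r)
  if (S < 1L) stop("need at least one species", call. = FALSE)
  if (length(s) != S) stop("length(s) must equal length(r)", call. = FALSE)
  if (any(!is.finite(r)) || any(!is.finite(s)))
    stop("r and s must be finite", call. = FALSE)
  if (any(s <= 0)) stop("self-regulation s must be strictly positive",
                        call. = FALSE)
  if (is.null(A)) A <- matrix(0, S, S)
  A <- as.matrix(A)
  if (!all(dim(A) == c(S, S)))
    stop(sprintf("A must be %d x %d", S, S), call. = FALSE)
  if (any(diag(A) != 0)) {
    bad <- which(diag(A) != 0)[1]
    stop(sprintf("diagonal of A must be zero (cell [%d,%d] is %g)",
                 bad, bad, A[bad, bad]), call. = FALSE)
  }
  if (!is.finite(K_T) || K_T <= 0) stop("K_T must be > 0", call. = FALSE)
  if (is.null(species)) species <- paste0("sp", seq_len(S))
  if (length(species) != S) stop("species names must have length S",
                                 call. = FALSE)
  dimnames(A) <- list(species, species)
  structure(
    list(S = S, r = as.numeric(r), s = as.numeric(s), A = A,
         K_T = as.numeric(K_T), f = as.numeric(f),
         species = as.character(species)),
    class = "community_parameters")
}

#' @export
print.community_parameters <- function(x, ...) {
  n_int <- sum(x$A != 0)
  cat(sprintf(
    "community_parameters: S = %d, K_T = %g, f = %g, %d nonzero interactions\n",
    x$S, x$K_T, x$f, n_int))
  invisible(x)
}

# Restrict parameters to a subset of species (1-based indices).
subset_parameters <- function(params, subset) {
  subset <- sort(as.integer(subset))
  community_parameters(
    r = params$r[subset], s = params$s[subset],
    A = params$A[subset, subset, drop = FALSE],
    K_T = params$K_T, f = params$f, species = params$species[subset])
}

#' Read or write community parameters
#'
#' JSON holds all fields in one file. The CSV dialect uses a pair of
#' files: `<stem>_species.csv` with columns `species, r, s` and
#' `<stem>_matrix.csv` holding the square interaction matrix with species
#' names as header row and first column. Species-name order is preserved.
#'
#' @param path for JSON, a file path ending in `.json`; for CSV, the stem
#'   to which `_species.csv` / `_matrix.csv` are appended.
#' @param params a `community_parameters` object to write, or `NULL` to read.
#' @return the written path (invisibly) when writing; a
#'   `community_parameters` object when reading.
#' @export
read_write_parameters <- function(path, params = NULL) {
  is_json <- grepl("\\.json$", path)
  if (!is.null(params)) {
    if (is_json) {
      jsonlite::write_json(
        list(species = params$species, r = params$r, s = params$s,
             A = unname(params$A), K_T = params$K_T, f = params$f),
        path, digits = NA, auto_unbox = TRUE)
    } else {
      write.csv(data.frame(species = params$species, r = params$r,
                           s = params$s, K_T = params$K_T, f = params$f),
                paste0(path, "_species.csv"), row.names = FALSE)
      write.csv(as.data.frame(params$A),
                paste0(path, "_matrix.csv"), row.names = TRUE)
    }
    return(invisible(path))
  }
  if (is_json) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (fld in c("species", "r", "s", "A", "K_T"))
      if (is.null(obj[[fld]]))
        stop(sprintf("parameter file missing field '%s'", fld), call. = FALSE)
    community_parameters(r = obj$r, s = obj$s, A = as.matrix(obj$A),
                         K_T = obj$K_T, f = obj$f %||% 0,
                         species = obj$species)
  } else {
    vec <- read.csv(paste0(path, "_species.csv"))
    mat <- read.csv(paste0(path, "_matrix.csv"), row.names = 1,
                    check.names = FALSE)
    mat <- as.matrix(mat)
    if (nrow(mat) != ncol(mat))
      stop("interaction matrix is not square", call. = FALSE)
    mat <- mat[vec$species, vec$species, drop = FALSE]
    community_parameters(r = vec$r, s = vec$s, A = mat,
                         K_T = if ("K_T" %in% names(vec)) vec$K_T[1] else 10000,
                         f = if ("f" %in% names(vec)) vec$f[1] else 0,
                         species = vec$species)
  }
}
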