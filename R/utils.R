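#' @keywords internal
"_PACKAGE"

## Shared numerical helpers: fractional-polynomial powers, restricted cubic
## spline bases, cumulative quadrature, and small plumbing used across modules.

#' Fractional-polynomial power transform
#'
#' Evaluates \code{t^p} with the conventional substitution \code{log(t)} at
#' \code{p = 0}. Times at or below \code{eps} are floored at \code{eps} so
#' that negative powers stay finite near the origin.
#'
#' @param t vector of times (months).
#' @param p fractional-polynomial power.
#' @param eps floor applied to \code{t} before the transform (months).
#' @return numeric vector, same length as \code{t}.
#' @export
fp_power <- function(t, p, eps = 0.01) {
  t <- pmax(t, eps)
  if (p == 0) log(t) else t^p
}

## Restricted cubic spline (natural cubic, Harrell's truncated-power form).
## Returns a matrix with (k - 1) columns for k knots: x plus k - 2 nonlinear
## terms, linear beyond the boundary knots.
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  kd <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      pos3(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])) / kd
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  out
}

## Cumulative integral of f over an increasing grid by composite
## Gauss-Legendre quadrature (n nodes per grid interval). Returns the
## cumulative integral at each grid point, starting at 0.
gauss_legendre_nodes <- function(n) {
  ## Golub-Welsch on the Jacobi matrix for Legendre polynomials.
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

cum_quadrature <- function(f, grid, n_nodes = 15) {
  stopifnot(!is.unsorted(grid), all(diff(grid) > 0) || length(grid) == 1)
  gl <- gauss_legendre_nodes(n_nodes)
  ng <- length(grid)
  if (ng == 1) return(0)
  a <- grid[-ng]; b <- grid[-1]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  ## evaluate f at all nodes of all intervals in one call
  tt <- as.vector(outer(gl$nodes, half) + rep(mid, each = n_nodes))
  fv <- matrix(f(tt), nrow = n_nodes)
  pieces <- half * colSums(fv * gl$weights)
  c(0, cumsum(pieces))
}

## Nested list access by "a.b.c" path strings (DSA/PSA parameter handles).
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (is.null(params[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
    params <- params[[k]]
  }
  params
}

param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    params[[keys]] <- value
    return(params)
  }
  params[[keys[1]]] <- param_set(params[[keys[1]]],
                                 paste(keys[-1], collapse = "."), value)
  params
}

## Derive a per-stage 32-bit seed from a global seed and a stage label so
## pipeline stages can be rerun in isolation.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
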