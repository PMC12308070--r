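# Sparse canonical correlation via penalized matrix decomposition (PMD):
# L1-constrained rank-1 decompositions of the cross-product matrix with
# soft thresholding, plus permutation-based penalty tuning.

#' Soft-thresholding operator
#'
#' `sign(a) * max(|a| - c, 0)`, the proximal operator of the L1 penalty.
#'
#' @param a numeric vector.
#' @param c threshold, >= 0.
#' @return thresholded vector.
#' @export
soft_threshold <- function(a, c) {
  if (c < 0) stop("threshold must be non-negative")
  sign(a) * pmax(abs(a) - c, 0)
}

# Given a vector a and an L1 bound c (with ||.||2 normalized to 1), find
# delta >= 0 by bisection such that u = S(a, delta)/||S(a, delta)||2
# satisfies ||u||1 <= c, binding when the unconstrained solution violates
# it. Standard PMD binary search.
l1_project <- function(a, c) {
  norm2 <- sqrt(sum(a^2))
  if (norm2 == 0) return(a)
  u <- a / norm2
  if (sum(abs(u)) <= c) return(u)
  lo <- 0
  hi <- max(abs(a))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(a, mid)
    n2 <- sqrt(sum(su^2))
    l1 <- if (n2 > 0) sum(abs(su)) / n2 else 0
    if (l1 > c) lo <- mid else hi <- mid
  }
  su <- soft_threshold(a, hi)
  # entries indistinguishable from zero at the bisection's resolution are
  # exact zeros (guards the active set when the constraint binds at a tie)
  su[abs(su) < 1e-9 * max(abs(su))] <- 0
  su / sqrt(sum(su^2))
}

# One rank-1 PMD component on M: alternate u <- P(Mv), v <- P(M'u) until
# the iterates stabilize. Returns u, v, d = u'Mv and a convergence flag.
pmd_rank1 <- function(M, c1, c2, tol = 1e-6, max_iter = 200L, v_init = NULL) {
  v <- if (is.null(v_init)) {
    sv <- svd(M, nu = 0L, nv = 1L)
    sv$v[, 1L]
  } else {
    v_init / sqrt(sum(v_init^2))
  }
  converged <- FALSE
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    u <- l1_project(drop(M %*% v), c1)
    v_new <- l1_project(drop(crossprod(M, u)), c2)
    obj <- drop(crossprod(u, M %*% v_new))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
    obj_prev <- obj
  }
  u <- l1_project(drop(M %*% v), c1)
  d <- drop(crossprod(u, M %*% v))
  # sign convention: first nonzero element of u positive
  nz <- which(u != 0)
  if (length(nz) && u[nz[1L]] < 0) {
    u <- -u
    v <- -v
  }
  list(u = u, v = v, d = d, converged = converged, iterations = it)
}

#' Sparse CCA by penalized matrix decomposition
#'
#' Computes `K` L1-constrained rank-1 components of the cross-product
#' matrix `M = X'Z` of two column-standardized data matrices, by
#' alternating soft-thresholded power iterations with rank-1 deflation
#' (`M <- M - d u v'`). With the penalties at their maxima (`sqrt(p)`,
#' `sqrt(q)`) the components coincide with the truncated SVD of `M`.
#'
#' @param X samples x p matrix (e.g. region values).
#' @param Z samples x q matrix (e.g. brain measures), same samples.
#' @param c1,c2 L1 bounds on the unit-norm weight vectors, in
#'   `[1, sqrt(p)]` and `[1, sqrt(q)]`.
#' @param K number of components (default 3).
#' @param tol,max_iter convergence control for each component.
#' @param standardize column-standardize `X` and `Z` first (default TRUE).
#' @return object of class `scca_result`: `u` (p x K), `v` (q x K), `d`
#'   (length K), `cors` (canonical correlations `cor(Xu, Zv)` per
#'   component), `c1`, `c2`, `converged`, `active_x`, `active_z` (names or
#'   indices with nonzero weight in any component).
#' @export
pmd_scca <- function(X, Z, c1 = sqrt(ncol(X)), c2 = sqrt(ncol(Z)),
                     K = 3L, tol = 1e-6, max_iter = 200L,
                     standardize = TRUE) {
  stopifnot(nrow(X) == nrow(Z))
  p <- ncol(X)
  q <- ncol(Z)
  if (c1 < 1 || c1 > sqrt(p) + 1e-12) stop("c1 must lie in [1, sqrt(p)]")
  if (c2 < 1 || c2 > sqrt(q) + 1e-12) stop("c2 must lie in [1, sqrt(q)]")
  std <- function(A) {
    A <- scale(A)
    A[, attr(A, "scaled:scale") == 0] <- 0
    A
  }
  Xs <- if (standardize) std(X) else as.matrix(X)
  Zs <- if (standardize) std(Z) else as.matrix(Z)
  M <- crossprod(Xs, Zs)
  U <- matrix(0, p, K)
  V <- matrix(0, q, K)
  d <- numeric(K)
  cors <- numeric(K)
  converged <- logical(K)
  for (k in seq_len(K)) {
    comp <- pmd_rank1(M, c1, c2, tol = tol, max_iter = max_iter)
    U[, k] <- comp$u
    V[, k] <- comp$v
    d[k] <- comp$d
    converged[k] <- comp$converged
    xs <- drop(Xs %*% comp$u)
    zs <- drop(Zs %*% comp$v)
    cors[k] <- if (stats::sd(xs) > 0 && stats::sd(zs) > 0) {
      stats::cor(xs, zs)
    } else {
      NA_real_
    }
    M <- M - comp$d * tcrossprod(comp$u, comp$v)
  }
  rownames(U) <- colnames(X)
  rownames(V) <- colnames(Z)
  act <- function(W, nms) {
    idx <- which(rowSums(W != 0) > 0L)
    if (is.null(nms)) idx else nms[idx]
  }
  structure(
    list(
      u = U, v = V, d = d, cors = cors, c1 = c1, c2 = c2,
      converged = converged,
      active_x = act(U, colnames(X)), active_z = act(V, colnames(Z))
    ),
    class = "scca_result"
  )
}

#' @export
print.scca_result <- function(x, ...) {
  cat(sprintf(
    "sparse CCA (PMD): %d component(s), penalties c1=%.2f c2=%.2f\n",
    length(x$d), x$c1, x$c2
  ))
  cat(sprintf(
    "  d = %s | canonical cor = %s\n",
    paste(sprintf("%.3f", x$d), collapse = ", "),
    paste(sprintf("%.3f", x$cors), collapse = ", ")
  ))
  cat(sprintf(
    "  active: %d of %d X variables, %d of %d Z variables\n",
    length(x$active_x), nrow(x$u), length(x$active_z), nrow(x$v)
  ))
  invisible(x)
}

#' Permutation tuning of sCCA penalties
#'
#' For each grid point, the first-component canonical correlation is
#' computed on the real data and on `n_perm` row-permutations of `X`; the
#' selected penalties maximize the z-score of the Fisher-transformed real
#' correlation against the permuted distribution. A best z below 2 flags
#' the data as having no detectable shared signal.
#'
#' @param seed integer seed for the permutations.
#' @param X,Z data matrices as in [pmd_scca()].
#' @param grid data.frame with columns `c1`, `c2` (non-empty).
#' @param n_perm permutations per grid point (default 25).
#' @return list: `c1`, `c2`, `z` (best z-score), `no_signal` (logical),
#'   `table` (per-grid-point summary).
#' @export
scca_tune <- function(seed, X, Z, grid = NULL, n_perm = 25L) {
  p <- ncol(X)
  q <- ncol(Z)
  if (is.null(grid)) {
    fr <- c(0.2, 0.4, 0.6, 0.8)
    grid <- expand.grid(
      c1 = pmax(1, fr * sqrt(p)),
      c2 = pmax(1, fr * sqrt(q))
    )
  }
  if (nrow(grid) == 0L) stop("penalty grid is empty")
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(nrow(X)), simplify = FALSE)
    zscore <- real_cor <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fit <- pmd_scca(X, Z, grid$c1[g], grid$c2[g], K = 1L)
      r <- fit$cors[1L]
      rp <- vapply(perms, function(ix) {
        pf <- pmd_scca(X[ix, , drop = FALSE], Z, grid$c1[g], grid$c2[g], K = 1L)
        pf$cors[1L]
      }, numeric(1))
      ftr <- atanh(pmin(pmax(c(r, rp), -0.999999), 0.999999))
      sdp <- stats::sd(ftr[-1L])
      zscore[g] <- if (is.finite(sdp) && sdp > 0) {
        (ftr[1L] - mean(ftr[-1L])) / sdp
      } else {
        0
      }
      real_cor[g] <- r
    }
    best <- which.max(zscore)
    list(
      c1 = grid$c1[best], c2 = grid$c2[best], z = zscore[best],
      no_signal = zscore[best] < 2,
      table = cbind(grid, cor = real_cor, z = zscore)
    )
  })
}
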