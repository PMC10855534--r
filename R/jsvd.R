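# Joint singular value decomposition with a shared sample factor:
#   A_i ~ U diag(sigma_i) V_i^T,  U and every V_i orthonormal,
# minimizing the summed squared Frobenius reconstruction error over the
# product of Stiefel manifolds St(n, k) x St(N_1, k) x ... The shared U is
# the fused patient embedding. Given (U, V_i), each sigma_i has the closed
# form diag(U^T A_i V_i); the solvers work on the reduced objective
#   F(U, V) = sum_i ||A_i||_F^2 - sum_{i,j} (u_j^T A_i v_ij)^2.

# Polar factor of a tall matrix: the nearest matrix with orthonormal columns.
# A rank-deficient input keeps the fallback's columns for the null directions.
polar_factor <- function(m, fallback = NULL) {
  s <- svd(m)
  if (!is.null(fallback) && any(s$d < 1e-14 * max(s$d, 1))) {
    # complete the basis deterministically from the fallback
    q <- qr.Q(qr(cbind(m, fallback)))[, seq_len(ncol(m)), drop = FALSE]
    return(q)
  }
  s$u %*% t(s$v)
}

# Riemannian (projected) gradient on the Stiefel manifold at point x,
# Euclidean gradient g: g - x sym(x^T g).
stiefel_project <- function(x, g) {
  xtg <- crossprod(x, g)
  g - x %*% ((xtg + t(xtg)) / 2)
}

jsvd_objective <- function(A, U, V, Sigma) {
  sum(vapply(seq_along(A), function(i) {
    R <- A[[i]] - U %*% (Sigma[[i]] * t(V[[i]]))
    sum(R^2)
  }, numeric(1)))
}

jsvd_sigma <- function(A, U, V) {
  lapply(seq_along(A), function(i) diag(crossprod(U, A[[i]] %*% V[[i]])))
}

# Euclidean gradients of the reduced objective (envelope theorem: sigma at
# its closed form contributes no extra term).
jsvd_gradients <- function(A, U, V, Sigma) {
  gU <- matrix(0, nrow(U), ncol(U))
  gV <- vector("list", length(A))
  for (i in seq_along(A)) {
    AVS <- A[[i]] %*% sweep(V[[i]], 2, Sigma[[i]], "*")
    gU <- gU - 2 * AVS
    gV[[i]] <- -2 * sweep(crossprod(A[[i]], U), 2, Sigma[[i]], "*")
  }
  list(U = gU, V = gV)
}

jsvd_gradnorm <- function(A, U, V, Sigma) {
  g <- jsvd_gradients(A, U, V, Sigma)
  pU <- stiefel_project(U, g$U)
  tot <- sum(pU^2)
  for (i in seq_along(V)) tot <- tot + sum(stiefel_project(V[[i]], g$V[[i]])^2)
  sqrt(tot)
}

#' Joint singular value decomposition of coupled omics matrices
#'
#' Factorizes K matrices sharing the same samples as
#' `A_i = U diag(sigma_i) V_i'` with a single orthonormal sample factor `U`
#' (the fused patient embedding) and per-domain orthonormal right factors,
#' minimizing the total squared Frobenius reconstruction error over the
#' product of Stiefel manifolds. Each input (features x samples) is
#' transposed to samples x features before the solve, so samples are rows
#' of `U`.
#'
#' Two solvers are provided and agree at stationary points: `"als"`
#' (default) alternates the exact per-block minimizers — `sigma_i` by its
#' closed form, `V_i` and `U` by polar factors — and `"rgd"` runs Riemannian
#' projected-gradient descent with QR retraction and Armijo backtracking.
#' Both stop when the norm of the projected gradient falls below `grad_tol`.
#'
#' On return the factors are canonicalized: signs are absorbed into `V_i` so
#' every `sigma_i >= 0`, and columns are sorted by total explained
#' `sum_i sigma_i^2` descending.
#'
#' @param matrices list of [omics_matrix()] (or plain features-x-samples
#'   matrices) sharing sample IDs; sample order is reconciled by ID against
#'   the first matrix before the solve.
#' @param k embedding dimension (default 3).
#' @param grad_tol projected-gradient-norm stopping tolerance (default 1e-12).
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising an error.
#' @param seed integer seed used only when `init = "random"`.
#' @param method `"als"` or `"rgd"`.
#' @param init `"svd"` (deterministic: `U` from the top-k left singular
#'   vectors of the column-concatenation of the inputs) or `"random"`.
#' @param rescale if TRUE, rescale each input to unit Frobenius norm before
#'   the solve (off by default: inputs are used as preprocessing produced
#'   them).
#' @return object of class `joint_factors`: `U` (samples x k, orthonormal,
#'   sample IDs as rownames), `Sigma` (list of k-vectors), `V` (list of
#'   N_i x k orthonormal matrices), `k`, `objective`, `grad_norm`, `n_iter`,
#'   `converged`, `objective_trace`.
#' @export
joint_svd <- function(matrices, k = 3, grad_tol = 1e-12, max_iter = 10000,
                      seed = NULL, method = c("als", "rgd"),
                      init = c("svd", "random"), rescale = FALSE) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (length(matrices) < 1) stop("need at least one matrix")
  vals <- lapply(matrices, function(m)
    if (inherits(m, "omics_matrix")) m$values else as.matrix(m))
  if (any(!vapply(vals, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite values in input matrices")
  sids <- colnames(vals[[1]])
  if (is.null(sids)) sids <- paste0("s", seq_len(ncol(vals[[1]])))
  A <- lapply(vals, function(v) {
    if (!is.null(colnames(v))) {
      if (!setequal(colnames(v), sids))
        stop("matrices do not share the same sample IDs")
      v <- v[, sids, drop = FALSE]
    } else if (ncol(v) != length(sids)) {
      stop("matrices do not share the same number of samples")
    }
    t(v)  # samples x features
  })
  n <- nrow(A[[1]])
  Ns <- vapply(A, ncol, integer(1))
  if (k > min(n, min(Ns)))
    stop("k = ", k, " exceeds min(n_samples, min feature count) = ",
         min(n, min(Ns)))
  if (rescale) A <- lapply(A, function(a) {
    f <- sqrt(sum(a^2)); if (f > 0) a / f else a
  })

  if (init == "random") {
    if (!is.null(seed)) set.seed(seed)
    U <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  } else {
    U <- svd(do.call(cbind, A), nu = k, nv = 0)$u
    if (ncol(U) < k)  # degenerate (e.g. all-zero) input: any feasible basis
      U <- qr.Q(qr(diag(n)[, seq_len(k), drop = FALSE]))
  }
  V <- lapply(A, function(a) polar_factor(crossprod(a, U),
                                          fallback = diag(ncol(a))[, seq_len(k)]))
  Sigma <- jsvd_sigma(A, U, V)

  obj <- jsvd_objective(A, U, V, Sigma)
  trace <- obj
  gnorm <- jsvd_gradnorm(A, U, V, Sigma)
  iter <- 0L

  if (method == "als") {
    while (gnorm > grad_tol && iter < max_iter) {
      iter <- iter + 1L
      Sigma <- jsvd_sigma(A, U, V)
      for (i in seq_along(A))
        V[[i]] <- polar_factor(crossprod(A[[i]], U) %*% diag(Sigma[[i]], k),
                               fallback = V[[i]])
      M <- matrix(0, n, k)
      for (i in seq_along(A))
        M <- M + A[[i]] %*% sweep(V[[i]], 2, Sigma[[i]], "*")
      U <- polar_factor(M, fallback = U)
      Sigma <- jsvd_sigma(A, U, V)
      obj <- jsvd_objective(A, U, V, Sigma)
      trace <- c(trace, obj)
      gnorm <- jsvd_gradnorm(A, U, V, Sigma)
    }
  } else {
    step <- 1 / max(1, sum(vapply(A, function(a) sum(a^2), numeric(1))))
    while (gnorm > grad_tol && iter < max_iter) {
      iter <- iter + 1L
      g <- jsvd_gradients(A, U, V, Sigma)
      pU <- stiefel_project(U, g$U)
      pV <- lapply(seq_along(V), function(i)
        stiefel_project(V[[i]], g$V[[i]]))
      gn2 <- sum(pU^2) + sum(vapply(pV, function(p) sum(p^2), numeric(1)))
      alpha <- step
      repeat {  # Armijo backtracking on the retracted iterate
        U2 <- qr_retract(U, -alpha * pU)
        V2 <- lapply(seq_along(V), function(i)
          qr_retract(V[[i]], -alpha * pV[[i]]))
        S2 <- jsvd_sigma(A, U2, V2)
        obj2 <- jsvd_objective(A, U2, V2, S2)
        if (obj2 <= obj - 1e-4 * alpha * gn2 || alpha < 1e-20) break
        alpha <- alpha / 2
      }
      if (obj2 < obj) step <- alpha * 2  # adapt the initial step
      U <- U2; V <- V2; Sigma <- S2; obj <- obj2
      trace <- c(trace, obj)
      gnorm <- jsvd_gradnorm(A, U, V, Sigma)
    }
  }

  # canonicalize: sigma >= 0 (signs into V), columns by explained sigma^2
  for (i in seq_along(V)) {
    neg <- Sigma[[i]] < 0
    V[[i]][, neg] <- -V[[i]][, neg, drop = FALSE]
    Sigma[[i]][neg] <- -Sigma[[i]][neg]
  }
  expl <- Reduce(`+`, lapply(Sigma, function(s) s^2))
  ord <- order(-expl)
  U <- U[, ord, drop = FALSE]
  V <- lapply(V, function(v) v[, ord, drop = FALSE])
  Sigma <- lapply(Sigma, function(s) s[ord])
  rownames(U) <- sids

  structure(list(U = U, Sigma = Sigma, V = V, k = k,
                 objective = jsvd_objective(A, U, V, Sigma),
                 grad_norm = jsvd_gradnorm(A, U, V, Sigma),
                 n_iter = iter, converged = gnorm <= grad_tol,
                 objective_trace = trace, method = method),
            class = "joint_factors")
}

qr_retract <- function(x, dx) {
  q <- qr(x + dx)
  Q <- qr.Q(q)
  # fix signs so the retraction is continuous (positive diagonal of R)
  d <- sign(diag(qr.R(q)))
  d[d == 0] <- 1
  sweep(Q, 2, d, "*")
}

#' @export
print.joint_factors <- function(x, ...) {
  cat(sprintf(
    "<joint_factors> k = %d, %d samples, %d domain(s)\n  objective = %.6g, grad_norm = %.3g, %d iterations (%s)%s\n",
    x$k, nrow(x$U), length(x$V), x$objective, x$grad_norm, x$n_iter,
    x$method, if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Fused sample embedding
#'
#' Returns the shared factor `U` as a per-sample coordinate table. Columns
#' are ordered by total explained `sum_i sigma_i^2` descending (the
#' canonical order [joint_svd()] returns).
#'
#' @param f a [joint_svd()] result.
#' @return data.frame with `sample_id` and coordinate columns `U1..Uk`.
#' @export
embed_samples <- function(f) {
  stopifnot(inherits(f, "joint_factors"))
  expl <- Reduce(`+`, lapply(f$Sigma, function(s) s^2))
  ord <- order(-expl)  # already canonical; recompute for robustness
  U <- f$U[, ord, drop = FALSE]
  out <- data.frame(sample_id = rownames(f$U), U, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("U", seq_len(f$k)))
  rownames(out) <- NULL
  out
}
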