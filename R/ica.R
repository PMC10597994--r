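#' Subject-level PCA reduction for group ICA
#'
#' Voxel time-series inside the analysis mask are variance-normalised and
#' temporally centred, then projected onto their top temporal
#' eigenvectors — the standard first reduction stage of temporally
#' concatenated group spatial ICA.
#'
#' @param v a [volume_series()] (registered and cropped).
#' @param mask logical 3D analysis mask.
#' @param p1 temporal dimensions to retain (default
#'   `min(75, n_volumes - 1)`).
#' @return an `n_voxels_in_mask x p1` matrix with attributes `explained`
#'   (eigenvalue fractions) and `mask`.
#' @export
subject_pca_reduce <- function(v, mask, p1 = NULL) {
  d <- dim(v$data)
  if (!all(dim(mask) == d[1:3]))
    stop("mask grid does not match series", call. = FALSE)
  sel <- which(as.vector(mask))
  if (!length(sel)) stop("analysis mask is empty", call. = FALSE)
  nt <- d[4]
  if (is.null(p1)) p1 <- min(75L, nt - 1L)
  if (p1 > nt) stop("p1 exceeds the number of volumes", call. = FALSE)
  X <- matrix(v$data, prod(d[1:3]), nt)[sel, , drop = FALSE]
  X <- X - rowMeans(X)
  sdv <- sqrt(rowMeans(X^2))
  sdv[sdv < 1e-12] <- 1
  X <- X / sdv                              # nvox x nt, unit-variance rows
  X <- sweep(X, 2, colMeans(X))             # temporal centring
  e <- eigen(crossprod(X), symmetric = TRUE)
  evals <- pmax(e$values, 0)
  R <- X %*% e$vectors[, seq_len(p1), drop = FALSE]
  attr(R, "explained") <- evals[seq_len(p1)] / sum(evals)
  attr(R, "basis") <- e$vectors[, seq_len(p1), drop = FALSE]
  attr(R, "mask") <- mask
  R
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity on whitened
#' data: `W <- W + lrate * (I - (1 - 2 g(u)) u^T / block) W`. The learning
#' rate is annealed when the weight update direction oscillates, and
#' iteration stops when the weight change falls below `tol`. Used here as
#' spatial ICA: columns of `X` are samples (voxels), rows are reduced
#' feature channels.
#'
#' @param X data matrix (channels x samples); reduced to `n_components`
#'   by PCA and whitened internally.
#' @param n_components number of independent components.
#' @param seed integer seed controlling initial weights and sample
#'   permutation; identical seeds give identical results.
#' @param lrate0 initial learning rate (default `0.01 / log(n_components)`
#'   capped at 0.01).
#' @param max_iter,tol stopping rules.
#' @param anneal learning-rate multiplier applied on oscillation.
#' @param decay multiplicative learning-rate decay per iteration,
#'   guaranteeing the stochastic update noise floor shrinks below `tol`.
#' @return a list with `sources` (n_components x samples), `unmixing`
#'   (applied to whitened data), `whitening`/`dewhitening` matrices,
#'   `iterations`, `final_change` and `converged`.
#' @export
infomax_ica <- function(X, n_components, seed = 1L, lrate0 = NULL,
                        max_iter = 512L, tol = 1e-6, anneal = 0.9,
                        decay = 0.99) {
  X <- as.matrix(X)
  k0 <- nrow(X); n <- ncol(X)
  if (n_components > k0)
    stop("n_components exceeds data rank (", k0, ")", call. = FALSE)
  if (n_components > n)
    stop("n_components exceeds number of samples", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  X <- X - rowMeans(X)
  e <- eigen(tcrossprod(X) / n, symmetric = TRUE)
  evals <- pmax(e$values[seq_len(n_components)], 1e-12)
  E <- e$vectors[, seq_len(n_components), drop = FALSE]
  K <- diag(1 / sqrt(evals), n_components) %*% t(E)     # whitening
  Kinv <- E %*% diag(sqrt(evals), n_components)
  Z <- K %*% X
  k <- n_components
  if (is.null(lrate0)) lrate0 <- min(0.01, 0.01 / log(max(k, 2)))
  W <- diag(k) + 0.01 * matrix(stats::rnorm(k * k), k, k)
  lrate <- lrate0
  block <- max(8L, as.integer(floor(sqrt(n / 3))))
  oldW <- W; old_dW <- NULL
  change <- Inf; it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    perm <- sample.int(n)
    blow <- FALSE
    for (s in seq(1L, n - block + 1L, by = block)) {
      u <- W %*% Z[, perm[s:(s + block - 1L)], drop = FALSE]
      g <- logistic(u)
      W <- W + lrate * ((diag(k) + (1 - 2 * g) %*% t(u) / block) %*% W)
      if (max(abs(W)) > 1e8) { blow <- TRUE; break }
    }
    if (blow) {                      # restart colder
      W <- diag(k) + 0.01 * matrix(stats::rnorm(k * k), k, k)
      lrate <- lrate * 0.5
      oldW <- W; old_dW <- NULL
      next
    }
    dW <- W - oldW
    change <- sqrt(sum(dW^2))
    if (!is.null(old_dW)) {
      cosang <- sum(dW * old_dW) /
        sqrt(max(sum(dW^2) * sum(old_dW^2), 1e-300))
      if (cosang < 0.5) lrate <- lrate * anneal
    }
    old_dW <- dW; oldW <- W
    lrate <- lrate * decay
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Infomax did not converge in ", max_iter,
            " iterations (final weight change ", signif(change, 3), ")")
  S <- W %*% Z
  # fix each component's sign so its peak-magnitude sample is positive
  for (i in seq_len(k)) {
    pk <- which.max(abs(S[i, ]))
    if (S[i, pk] < 0) { S[i, ] <- -S[i, ]; W[i, ] <- -W[i, ] }
  }
  list(sources = S, unmixing = W, whitening = K, dewhitening = Kinv,
       iterations = it, final_change = change, converged = converged)
}

#' Group spatial ICA over a set of reduced subjects
#'
#' Concatenates subject PCA reductions, performs the group PCA to
#' `n_components` and runs spatial Infomax ICA, returning z-scored spatial
#' maps on the analysis mask together with group-level mixing
#' time-courses.
#'
#' @param reductions list of matrices from [subject_pca_reduce()] (all on
#'   the same mask).
#' @param mask logical 3D analysis mask.
#' @param n_components ICA model order.
#' @param seed integer seed passed to [infomax_ica()].
#' @param ... further arguments to [infomax_ica()].
#' @return an object of class `group_ica_result`: `zmaps` (n_components x
#'   n_voxels, zero mean unit variance within the mask), `mask`, `mixing`
#'   (stacked reduced time-dimension x n_components), `explained_var`,
#'   and a `convergence` log.
#' @export
group_spatial_ica <- function(reductions, mask, n_components, seed = 1L,
                              ...) {
  nvox <- sum(mask)
  for (R in reductions)
    if (nrow(R) != nvox)
      stop("reduction voxel count does not match mask", call. = FALSE)
  G <- do.call(cbind, reductions)          # nvox x (S * p1)
  fit <- infomax_ica(t(G), n_components, seed = seed, ...)
  S <- fit$sources                          # K x nvox
  Z <- t(scale(t(S)))                       # z-score within mask
  mixing <- t(MASS_ginv(Z) %*% G)           # (S*p1) x K
  ev <- rowSums((fit$unmixing %*% (fit$whitening %*% t(G)))^2)
  structure(list(zmaps = Z, mask = mask, n_components = n_components,
                 mixing = mixing,
                 explained_var = ev / sum(ev),
                 convergence = fit[c("iterations", "final_change",
                                     "converged")],
                 seed = as.integer(seed)),
            class = "group_ica_result")
}

# Moore-Penrose pseudoinverse of the source matrix's transpose (small)
MASS_ginv <- function(Z, tol = 1e-10) {
  s <- svd(t(Z))                            # nvox x K
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.group_ica_result <- function(x, ...) {
  cat(sprintf("<group_ica_result> %d components on %d voxels (%s after %d iterations)\n",
              x$n_components, sum(x$mask),
              if (x$convergence$converged) "converged" else "not converged",
              x$convergence$iterations))
  invisible(x)
}
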