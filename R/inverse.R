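#' Forward-project cortical sources to the scalp
#'
#' Applies the forward model `Phi = K J + eps`: scalp potentials are the
#' projection of oriented patch source amplitudes through the lead field,
#' plus independent Gaussian sensor noise.
#'
#' @param K lead field matrix, sensors x patches (microvolt per unit dipole
#'   moment).
#' @param J source matrix, patches x samples (unit dipole moments).
#' @param noise_sd standard deviation of additive Gaussian sensor noise in
#'   microvolt; 0 (default) for a noiseless projection.
#' @return Sensor potential matrix, sensors x samples.
#' @export
forward_project <- function(K, J, noise_sd = 0) {
  K <- as.matrix(K)
  J <- as.matrix(J)
  if (ncol(K) != nrow(J)) {
    stop("dimension mismatch: K has ", ncol(K), " patches but J has ",
         nrow(J), " rows")
  }
  stopifnot(noise_sd >= 0)
  Phi <- K %*% J
  if (noise_sd > 0) {
    Phi <- Phi + matrix(rnorm(length(Phi), sd = noise_sd), nrow(Phi))
  }
  Phi
}

# Average-reference a sensors x samples matrix (or lead-field columns):
# subtract the mean across sensors at each sample/column.
average_reference <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

#' Regularized inverse source estimation
#'
#' Estimates oriented patch source amplitudes `J` from scalp potentials `Phi`
#' as the minimiser of the penalised least-squares objective
#' \deqn{\hat J = \arg\min_J \|\Phi - K J\|^2 + \alpha \|W J\|^2,}
#' the data-fidelity term plus a smoothness (or energy) penalty. With
#' `W = NULL` (identity) this is the classical minimum-norm inverse; with the
#' cortical surface Laplacian from [build_laplacian()] it is the
#' CSL-regularized inverse. The closed-form solution is
#' `(K'K + alpha W'W + ridge I)^{-1} K' Phi`; `ridge` is a small stabiliser
#' that guarantees invertibility (`W'W` is singular on constant patterns).
#'
#' When the problem is underdetermined (more patches than sensors) the
#' algebraically equivalent representer form
#' `M^{-1} K' (K M^{-1} K' + I)^{-1} Phi` with `M = alpha W'W + ridge I` is
#' used, which only factorises a sensors x sensors matrix.
#'
#' Scalp EEG has no absolute voltage reference, so by default both `Phi` and
#' the rows of `K` are average-referenced before solving
#' (`reference = TRUE`), the standard dense-array convention.
#'
#' @param K lead field, sensors x patches.
#' @param Phi scalp potentials, sensors x samples (a vector is treated as one
#'   sample).
#' @param W smoothing operator (patches x patches), e.g. from
#'   [build_laplacian()]; `NULL` for the identity (minimum norm).
#' @param alpha regularization weight, `>= 0`, or `"gcv"` to select it with
#'   [choose_alpha()] on the default grid.
#' @param ridge stabilising ridge added to the normal matrix; default
#'   `1e-10 * trace(K'K + alpha W'W) / n_patches`.
#' @param reference average-reference `K` and `Phi` first (default `TRUE`).
#' @return An object of class `eeg_inverse` with elements `J_hat`
#'   (patches x samples), `method` (`"minimum_norm"` or `"csl"`), `alpha`,
#'   `ridge`, `operator` (the patches x sensors inverse operator), `K`, `Phi`
#'   (both as solved, i.e. after referencing), `W`, `gcv` (the [choose_alpha()]
#'   table when `alpha = "gcv"`).
#' @seealso [choose_alpha()], [source_residual()], methods [coef.eeg_inverse()],
#'   [fitted.eeg_inverse()], [residuals.eeg_inverse()],
#'   [predict.eeg_inverse()], [simulate.eeg_inverse()]
#' @export
solve_inverse <- function(K, Phi, W = NULL, alpha = "gcv", ridge = NULL,
                          reference = TRUE) {
  K <- as.matrix(K)
  Phi <- as.matrix(Phi)
  if (nrow(Phi) != nrow(K)) {
    stop("Phi has ", nrow(Phi), " sensors but K has ", nrow(K))
  }
  ns <- nrow(K)
  np <- ncol(K)
  method <- if (is.null(W)) "minimum_norm" else "csl"
  if (is.null(W)) W <- Matrix::Diagonal(np)
  W <- methods::as(W, "CsparseMatrix")
  if (any(dim(W) != np)) stop("W must be ", np, " x ", np)

  if (reference) {
    K <- average_reference(K)
    Phi <- average_reference(Phi)
  }

  gcv_tab <- NULL
  if (identical(alpha, "gcv")) {
    alpha <- choose_alpha(K, Phi, W, ridge = ridge, reference = FALSE)
    gcv_tab <- attr(alpha, "gcv")
    alpha <- as.numeric(alpha)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("`alpha` must be a single number >= 0 (or \"gcv\")")
  }

  if (alpha == 0) {
    if (qr(K)$rank < np) {
      stop("alpha = 0 requires K'K to be invertible, but K is rank ",
           "deficient (rank ", qr(K)$rank, " < ", np, " patches)")
    }
    # unpenalised full-rank least squares needs no stabiliser
    if (is.null(ridge)) ridge <- 0
  }

  op <- inverse_operator(K, W, alpha, ridge)
  J_hat <- op$G %*% Phi
  structure(
    list(J_hat = J_hat, method = method, alpha = alpha, ridge = op$ridge,
         operator = op$G, K = K, Phi = Phi, W = W, gcv = gcv_tab,
         referenced = reference),
    class = "eeg_inverse"
  )
}

# The patches x sensors inverse operator G with
# G = (K'K + alpha W'W + ridge I)^{-1} K'.
# Uses the representer form when patches > sensors.
inverse_operator <- function(K, W, alpha, ridge = NULL) {
  ns <- nrow(K)
  np <- ncol(K)
  WtW <- Matrix::crossprod(W)
  if (is.null(ridge)) {
    ridge <- 1e-10 * (sum(K^2) + alpha * sum(Matrix::diag(WtW))) / np
    ridge <- max(ridge, 1e-12 * sum(K^2) / np)
  }
  if (np > ns) {
    M <- alpha * WtW + Matrix::Diagonal(np, ridge)
    MiKt <- as.matrix(Matrix::solve(M, t(K)))          # p x s
    A <- K %*% MiKt + diag(ns)                          # s x s
    G <- MiKt %*% solve(A)
  } else {
    A <- as.matrix(crossprod(K) + alpha * WtW) + diag(ridge, np)
    G <- tryCatch(solve(A, t(K)), error = function(e) {
      stop("regularized normal matrix is singular (rank deficiency): ",
           conditionMessage(e))
    })
  }
  list(G = G, ridge = ridge)
}

#' Residual of a source estimate
#'
#' Returns the sensor-space residual `Phi - K J_hat` (the error term of the
#' forward model) and the relative misfit `||Phi - K J_hat|| / ||Phi||`
#' (Frobenius norms; 0/0 is defined as 0).
#'
#' @param K lead field, sensors x patches.
#' @param Phi measured potentials, sensors x samples.
#' @param J_hat estimated sources, patches x samples.
#' @return List with `residual` (matrix) and `relative_fit` (scalar).
#' @export
source_residual <- function(K, Phi, J_hat) {
  K <- as.matrix(K)
  Phi <- as.matrix(Phi)
  J_hat <- as.matrix(J_hat)
  R <- Phi - K %*% J_hat
  denom <- sqrt(sum(Phi^2))
  rel <- if (denom == 0) {
    if (sqrt(sum(R^2)) == 0) 0 else Inf
  } else {
    sqrt(sum(R^2)) / denom
  }
  list(residual = R, relative_fit = rel)
}

#' Select the regularization weight by generalized cross-validation
#'
#' Evaluates the GCV score
#' \deqn{GCV(\alpha) = \frac{RSS(\alpha)/n}{(1 - tr(H_\alpha)/n_s)^2}}
#' over a grid of candidate weights, where `H = K (K'K + alpha W'W +
#' ridge I)^{-1} K'` is the sensor-space hat matrix and RSS the residual sum
#' of squares over all samples, and returns the minimising grid value. Large
#' alpha wins on pure noise (nothing to fit), tiny alpha on noiseless
#' consistent data.
#'
#' @param K,Phi,W,ridge as in [solve_inverse()].
#' @param grid positive candidate weights; default a log grid
#'   `10^(-6..2)` scaled by `trace(K'K)/trace(W'W)`.
#' @param reference average-reference first (default `TRUE`).
#' @return The selected alpha (numeric scalar) with attribute `gcv`, a
#'   data.frame of the grid and its scores.
#' @export
choose_alpha <- function(K, Phi, W = NULL, grid = NULL, ridge = NULL,
                         reference = TRUE) {
  K <- as.matrix(K)
  Phi <- as.matrix(Phi)
  np <- ncol(K)
  if (is.null(W)) W <- Matrix::Diagonal(np)
  W <- methods::as(W, "CsparseMatrix")
  if (reference) {
    K <- average_reference(K)
    Phi <- average_reference(Phi)
  }
  if (is.null(grid)) {
    scale <- sum(K^2) / max(sum(W@x^2), .Machine$double.eps)
    grid <- 10^seq(-6, 2, by = 1) * scale
  }
  if (!length(grid) || any(grid <= 0)) {
    stop("`grid` must be a non-empty vector of positive weights")
  }
  ns <- nrow(K)
  n_tot <- length(Phi)
  scores <- vapply(grid, function(a) {
    op <- inverse_operator(K, W, a, ridge)
    H <- K %*% op$G
    R <- Phi - H %*% Phi
    df <- sum(diag(as.matrix(H)))
    denom <- (1 - df / ns)^2
    if (denom <= .Machine$double.eps) return(Inf)
    (sum(R^2) / n_tot) / denom
  }, numeric(1))
  if (all(!is.finite(scores))) stop("all GCV scores are non-finite")
  best <- which.min(scores)
  out <- grid[[best]]
  attr(out, "gcv") <- data.frame(alpha = grid, gcv = scores)
  out
}

#' @export
print.eeg_inverse <- function(x, ...) {
  cat("Regularized EEG source estimate\n")
  cat(sprintf("  method: %s, alpha = %.4g (ridge %.3g)\n",
              x$method, x$alpha, x$ridge))
  cat(sprintf("  %d patches x %d samples from %d sensors\n",
              nrow(x$J_hat), ncol(x$J_hat), nrow(x$K)))
  rf <- source_residual(x$K, x$Phi, x$J_hat)$relative_fit
  cat(sprintf("  relative sensor misfit: %.4g\n", rf))
  invisible(x)
}

#' @export
summary.eeg_inverse <- function(object, ...) {
  rf <- source_residual(object$K, object$Phi, object$J_hat)
  out <- list(
    method = object$method, alpha = object$alpha, ridge = object$ridge,
    n_patches = nrow(object$J_hat), n_samples = ncol(object$J_hat),
    n_sensors = nrow(object$K),
    relative_fit = rf$relative_fit,
    source_energy = sum(object$J_hat^2),
    roughness = sum(as.matrix(object$W %*% object$J_hat)^2),
    gcv = object$gcv
  )
  class(out) <- "summary.eeg_inverse"
  out
}

#' @export
print.summary.eeg_inverse <- function(x, ...) {
  cat(sprintf("EEG inverse (%s), alpha = %.4g\n", x$method, x$alpha))
  cat(sprintf("  %d sensors -> %d patches, %d samples\n",
              x$n_sensors, x$n_patches, x$n_samples))
  cat(sprintf("  relative misfit %.4g | source energy %.4g | roughness %.4g\n",
              x$relative_fit, x$source_energy, x$roughness))
  if (!is.null(x$gcv)) {
    cat("  GCV grid:\n")
    print(format(x$gcv, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Extract the estimated source amplitudes
#' @param object an `eeg_inverse` fit.
#' @param ... unused.
#' @return The patches x samples matrix of dipole moments.
#' @export
coef.eeg_inverse <- function(object, ...) object$J_hat

#' @export
fitted.eeg_inverse <- function(object, ...) object$K %*% object$J_hat

#' @export
residuals.eeg_inverse <- function(object, ...) {
  object$Phi - fitted(object)
}

#' Apply a fitted inverse operator to new scalp data
#'
#' The inverse operator is linear, so once fitted it can be applied to any
#' new sensor data with the same montage.
#'
#' @param object an `eeg_inverse` fit.
#' @param newdata sensors x samples matrix of scalp potentials; if omitted
#'   the training estimate is returned.
#' @param ... unused.
#' @return Patches x samples source estimate.
#' @export
predict.eeg_inverse <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$J_hat)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != nrow(object$K)) {
    stop("newdata must have ", nrow(object$K), " sensor rows")
  }
  if (isTRUE(object$referenced)) newdata <- average_reference(newdata)
  object$operator %*% newdata
}

#' Simulate scalp data from a fitted source estimate
#'
#' Draws sensor replicates from the fitted forward model
#' `K J_hat + noise`, with noise standard deviation estimated from the
#' residuals unless supplied.
#'
#' @param object an `eeg_inverse` fit.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param noise_sd noise standard deviation; default the residual SD.
#' @param ... unused.
#' @return A list of `nsim` sensors x samples matrices.
#' @export
simulate.eeg_inverse <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = NULL, ...) {
  if (!is.null(seed)) {
    restore <- local_rng(seed)
    on.exit(restore(), add = TRUE)
  }
  mu <- fitted(object)
  if (is.null(noise_sd)) noise_sd <- sd(as.numeric(residuals(object)))
  lapply(seq_len(nsim), function(i) {
    mu + matrix(rnorm(length(mu), sd = noise_sd), nrow(mu))
  })
}
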