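# Conditional input similarities: binary search of the Gaussian kernel
# bandwidth per point so the row perplexity matches the target.
.tsnePij <- function(D2, perplexity, iter = 64L, tol = 1e-6) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    di <- D2[i, -i]
    for (t in seq_len(iter)) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sumP) + beta * sum(di * p) / sumP
        p <- p / sumP
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else { betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)      # symmetrize, joint distribution
  pmax(P, .Machine$double.xmin)
}

#' t-SNE embedding of spectra
#'
#' Exact (dense-gradient) t-distributed stochastic neighbour embedding into
#' two dimensions, minimizing the Kullback-Leibler divergence between the
#' perplexity-calibrated Gaussian input similarities and the Student-t
#' embedding similarities. Gradient descent uses the classic schedule:
#' early exaggeration (factor 12 for the first quarter of the iterations),
#' momentum 0.5 switching to 0.8, learning rate 200, with per-coordinate
#' adaptive gains. The implementation is dense, intended for the small
#' replicate sets typical of SERS experiments (tens of spectra); identical
#' `(seed, parameters, input)` give bit-identical coordinates.
#'
#' @param set a [SpectrumSet-class].
#' @param perplexity effective neighbourhood size; must satisfy
#'   `perplexity <= (N - 1) / 3`.
#' @param n_iter optimization iterations (>= 250; 500 is typical for small N).
#' @param seed integer seed fixing the random initialization.
#' @return List of class `"SpectraTSNE"`: `coordinates` (N x 2, labelled),
#'   `perplexity`, `n_iter`, `seed`, `kl_divergence`.
#' @export
tsneEmbed <- function(set, perplexity = 3, n_iter = 500L, seed = 1L) {
  stopifnot(is(set, "SpectrumSet"))
  n <- nSpectra(set)
  n_iter <- as.integer(n_iter)
  if (n_iter < 250L) stop("n_iter must be >= 250")
  if (!is.numeric(perplexity) || perplexity <= 0 ||
      perplexity > (n - 1) / 3)
    stop("perplexity must be in (0, (N-1)/3] = (0, ", (n - 1) / 3,
         "] for N = ", n)
  X <- set@intensities
  D2 <- as.matrix(dist(X))^2
  P <- .tsnePij(D2, perplexity)
  exagg <- 12
  exaggIter <- max(50L, n_iter %/% 4L)
  Pex <- P * exagg
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 200
  for (t in seq_len(n_iter)) {
    Pt <- if (t <= exaggIter) Pex else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    W <- (Pt - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (t <= exaggIter) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  num <- 1 / (1 + as.matrix(dist(Y))^2)
  diag(num) <- 0
  Q <- pmax(num / sum(num), .Machine$double.xmin)
  kl <- sum(P * log(P / Q))
  rownames(Y) <- set@labels
  colnames(Y) <- c("tsne1", "tsne2")
  structure(list(coordinates = Y, perplexity = perplexity, n_iter = n_iter,
                 seed = as.integer(seed), kl_divergence = kl,
                 groups = spectrumGroups(set)),
            class = "SpectraTSNE")
}

#' @export
print.SpectraTSNE <- function(x, ...) {
  cat(sprintf("t-SNE embedding of %d spectra (perplexity %g, %d iterations, seed %d); KL = %.4f\n",
              nrow(x$coordinates), x$perplexity, x$n_iter, x$seed,
              x$kl_divergence))
  invisible(x)
}
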