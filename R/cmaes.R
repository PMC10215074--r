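#' Covariance matrix adaptation evolution strategy (minimizer)
#'
#' A standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation, for small unconstrained
#' problems (box handling belongs to the caller, see
#' [optimize_placement()]). Deterministic given `seed`.
#'
#' @param fn Objective `function(x) -> scalar` (smaller is better).
#' @param x0 Numeric start mean.
#' @param sigma0 Initial step size.
#' @param popsize Offspring per generation (lambda, default `4 + 3 log n`).
#' @param max_evals Evaluation budget.
#' @param seed Integer RNG seed.
#' @param tol_sigma Stop when `sigma` falls below this (stagnation).
#' @return List with `x_best`, `f_best`, `xs` (evaluations x n matrix),
#'   `fs`, `generations`, `evals`.
#' @export
cmaes <- function(fn, x0, sigma0, popsize = NULL, max_evals = 2000,
                  seed = 1, tol_sigma = 1e-12) {
  n <- length(x0)
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  set.seed(as.integer(seed))
  m <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(n); ps <- pc <- numeric(n)
  B <- diag(n); D <- rep(1, n)
  xs <- matrix(NA_real_, max_evals + lambda, n)
  fs <- rep(NA_real_, max_evals + lambda)
  evals <- 0L; gen <- 0L
  x_best <- m; f_best <- Inf
  while (evals < max_evals && sigma > tol_sigma) {
    gen <- gen + 1L
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- m + sigma * ary
    f <- apply(arx, 2, fn)
    idx <- order(f)
    for (j in seq_len(lambda)) {
      xs[evals + j, ] <- arx[, j]
      fs[evals + j] <- f[j]
    }
    evals <- evals + lambda
    if (f[idx[1]] < f_best) { f_best <- f[idx[1]]; x_best <- arx[, idx[1]] }
    ysel <- ary[, idx[seq_len(mu)], drop = FALSE]
    ybar <- c(ysel %*% w)
    m <- m + sigma * ybar
    Cinv_sqrt_y <- B %*% ((1 / D) * crossprod(B, ybar))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * c(Cinv_sqrt_y)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (w * t(ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
  }
  keep <- seq_len(evals)
  list(x_best = x_best, f_best = f_best, xs = xs[keep, , drop = FALSE],
       fs = fs[keep], generations = gen, evals = evals)
}
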