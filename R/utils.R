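# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers user RNG.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# composite trapezoidal weights for an (unevenly spaced) increasing grid
.trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  w
}

.logit <- function(p) log(p / (1 - p))
.invlogit <- function(x) 1 / (1 + exp(-x))

# central-difference Hessian; adequate for the smooth concentrated
# log-likelihoods used here (asymptotic CIs only)
.num_hessian <- function(fn, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        ei <- numeric(p); ei[i] <- eps
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / eps^2
      } else {
        ei <- numeric(p); ei[i] <- eps
        ej <- numeric(p); ej[j] <- eps
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
          (4 * eps^2)
      }
    }
  }
  H
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
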