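# Independent oracles used across the test files.  These deliberately
# re-derive results by brute force or from first principles and never call
# the package code paths they are used to check.

# all permutations of 1..m as a matrix (m! rows); small m only
perms <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- if (m == 1) matrix(1L, 1, 1) else {
      p <- perms(m - 1)
      do.call(rbind, lapply(seq_len(m), function(k) {
        rest <- setdiff(seq_len(m), k)
        cbind(k, matrix(rest[p], nrow(p), m - 1))
      }))
    }
    cache[[key]] <<- out
    out
  }
})

# exhaustive minimum of the sum of adjacent distances over all orders
brute_sarf_min <- function(d) {
  m <- nrow(d)
  P <- perms(m)
  s <- numeric(nrow(P))
  for (j in seq_len(m - 1)) s <- s + d[cbind(P[, j], P[, j + 1])]
  min(s)
}

# grid-search ML estimate of r from k discordant out of n pairs
rf_ml_grid <- function(k, n, type = c("ril", "dh"),
                       grid = seq(0, 0.4999, by = 1e-5)) {
  type <- match.arg(type)
  R <- if (type == "dh") grid else 2 * grid / (1 + 2 * grid)
  ll <- ifelse(R > 0, k * log(R), ifelse(k == 0, 0, -Inf)) +
    ifelse(R < 1, (n - k) * log(1 - R), -Inf)
  grid[which.max(ll)]
}

# O(n^2) dynamic-programming longest strictly increasing subsequence
lis_dp <- function(v) {
  n <- length(v)
  if (n == 0) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    if (v[j] < v[i]) best[i] <- max(best[i], best[j] + 1L)
  max(best)
}

# independent plain interval mapping in R: conditional probabilities from
# the immediate flanking markers (complete data) and an EM mixture fit
im_reference <- function(y, codes, mpos, step = 0.1, fun = "haldane",
                         popt = "ril", tol = 1e-12, maxit = 2000) {
  obs_rf <- function(d) {
    r <- if (fun == "haldane") (1 - exp(-d / 50)) / 2 else tanh(d / 50) / 2
    if (popt == "ril") 2 * r / (1 + 2 * r) else r
  }
  M <- length(mpos)
  grid <- seq(mpos[1], mpos[M], by = step)
  if (max(grid) < mpos[M] - 1e-9) grid <- c(grid, mpos[M])
  n <- length(y)
  out <- data.frame(pos = grid, lod = NA_real_, add = NA_real_)
  mu0 <- mean(y)
  s20 <- mean((y - mu0)^2)
  ll0 <- -n / 2 * (log(2 * pi * s20) + 1)
  for (gidx in seq_along(grid)) {
    g <- grid[gidx]
    l <- max(which(mpos <= g + 1e-12))
    l <- min(l, M - 1)
    R1 <- obs_rf(g - mpos[l])
    R2 <- obs_rf(mpos[l + 1] - g)
    tL <- ifelse(codes[, l] == 0, 1 - R1, R1)
    tR <- ifelse(codes[, l + 1] == 0, 1 - R2, R2)
    p <- tL * tR / (tL * tR + (1 - tL) * (1 - tR))
    xb <- 2 * p - 1
    vx <- sum((xb - mean(xb))^2)
    a <- if (vx > 1e-12) sum((xb - mean(xb)) * y) / vx else 0
    mu <- mean(y) - a * mean(xb)
    s2 <- mean((y - mu - a * xb)^2)
    ll <- -Inf
    for (it in seq_len(maxit)) {
      d1 <- dnorm(y, mu + a, sqrt(s2))
      d2 <- dnorm(y, mu - a, sqrt(s2))
      den <- p * d1 + (1 - p) * d2
      llnew <- sum(log(den))
      if (it > 1 && abs(llnew - ll) < tol * (abs(ll) + 1e-8)) {
        ll <- llnew
        break
      }
      ll <- llnew
      w <- p * d1 / den
      Sw <- sum(w)
      Sy <- sum(y)
      Swy <- sum((2 * w - 1) * y)
      cc <- 2 * Sw - n
      det <- n^2 - cc^2
      if (abs(det) < 1e-9 * n^2) {
        mu <- Sy / n
        a <- 0
      } else {
        mu <- (n * Sy - cc * Swy) / det
        a <- (n * Swy - cc * Sy) / det
      }
      s2 <- mean(w * (y - mu - a)^2 + (1 - w) * (y - mu + a)^2)
      s2 <- max(s2, 1e-12)
    }
    out$lod[gidx] <- max((ll - ll0) / log(10), 0)
    out$add[gidx] <- a
  }
  out
}

# quick random genotype matrix for QC / rf tests
random_geno <- function(n, m, miss = 0, pop = "ril", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(rbinom(n * m, 1, 0.5), n, m)
  if (miss > 0) G[runif(n * m) < miss] <- NA
  colnames(G) <- sprintf("mk%02d", seq_len(m))
  geno_matrix(G, pop)
}

# random distance matrix shaped like a noisy linkage-map problem: markers
# on a line with additive distances perturbed by estimation noise
noisy_map_dist <- function(m, span = 60, noise = 1.5,
                           names = paste0("x", seq_len(m))) {
  pos <- sort(runif(m, 0, span))
  E <- matrix(rnorm(m * m, 0, noise), m)
  D <- abs(outer(pos, pos, "-")) + (E + t(E)) / 2
  D <- pmax((D + t(D)) / 2, 0.01)
  diag(D) <- 0
  dimnames(D) <- list(names, names)
  D
}
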