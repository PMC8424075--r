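sim_xy <- function(n = 200, m = 51, beta = NULL, seed = 1,
                   sigma = 1) {
  set.seed(seed)
  pos <- seq(0, 100, by = 100 / (m - 1))
  G <- simulate_genotypes(pos, n, "ril")
  colnames(G) <- sprintf("m%02d", seq_len(m))
  X <- 1 - 2 * G
  y <- rnorm(n, 0, sigma)
  if (!is.null(beta)) y <- y + drop(X %*% beta)
  list(G = G, X = X, y = y, pos = pos)
}

test_that("stepwise selection controls entry, finds signal, drops copies", {
  # strong single signal is recovered (possibly via a perfect proxy)
  d <- sim_xy(beta = {
    b <- rep(0, 51)
    b[17] <- 2
    b
  }, seed = 3, sigma = 0.5)
  sel <- stepwise_select(d$y, d$X)
  expect_true(any(abs(sel$index - 17) <= 1))

  # duplicated marker column: only the lowest-index copy can enter
  X2 <- cbind(d$X[, 17, drop = FALSE], d$X[, 17, drop = FALSE])
  colnames(X2) <- c("c1", "c2")
  sel2 <- stepwise_select(d$y, X2)
  expect_equal(sel2$index, 1L)

  # pure-noise phenotypes select nothing in the vast majority of runs
  set.seed(10)
  n_selected <- replicate(100, {
    dd <- sim_xy(seed = sample.int(1e6, 1))
    length(stepwise_select(dd$y, dd$X)$index)
  })
  expect_gte(mean(n_selected == 0), 0.95)
})

test_that("phenotype adjustment excludes the scanned interval's flanks", {
  d <- sim_xy(beta = {
    b <- rep(0, 51)
    b[10] <- 1.5
    b
  }, seed = 5, sigma = 0.5)
  sel <- stepwise_select(d$y, d$X)
  expect_true(10 %in% sel$index)
  # no cofactors: identity
  none <- list(index = integer(0), beta = numeric(0), intercept = 0)
  expect_identical(adjust_phenotype(d$y, d$X, none), d$y)
  # single far cofactor: exact closed form
  b10 <- sel$beta[match(10, sel$index)]
  expect_equal(adjust_phenotype(d$y, d$X, sel, exclude = sel$index[-1]),
               d$y - b10 * d$X[, 10],
               tolerance = 1e-12)
  # cofactor flanking the interval is excluded from the adjustment
  expect_identical(adjust_phenotype(d$y, d$X, sel, exclude = sel$index),
                   d$y)
})

test_that("conditional QTL probabilities match enumeration and edge cases", {
  # QTL at a marker: probability 1 on the marker's genotype
  expect_equal(conditional_qtl_probs(c(0L, 1L), c(1L, 0L), 0, 0.1, "ril"),
               c(1, 0))
  # both flanks missing: prior
  expect_equal(conditional_qtl_probs(NA, NA, 0.1, 0.1, "ril"), 0.5)
  # midpoint of a 2 cM interval with agreeing flanks: near-certainty,
  # matching the R1'R2'/(R1'R2' + R1R2) closed form
  r <- map_rf(1, "haldane")
  R <- 2 * r / (1 + 2 * r)
  closed <- (1 - R)^2 / ((1 - R)^2 + R^2)
  expect_equal(conditional_qtl_probs(0L, 0L, r, r, "ril"), closed)
  expect_gte(closed, 0.999)
  # disagreeing equidistant flanks: no information either way
  expect_equal(conditional_qtl_probs(0L, 1L, r, r, "ril"), 0.5)
  # one-sided information uses the single-flank discordance
  expect_equal(conditional_qtl_probs(0L, NA, r, 0.3, "ril"), 1 - R)
})

test_that("EM fit matches regression at markers and the likelihood grid", {
  set.seed(12)
  n <- 150
  x <- sample(c(-1, 1), n, replace = TRUE)
  y <- 0.8 * x + rnorm(n)
  p <- as.numeric(x == 1)
  fit <- em_interval_mapping(y, p)
  # known genotypes: EM equals marker regression; closed-form LOD
  f <- lm(y ~ x)
  ss0 <- sum((y - mean(y))^2)
  ss1 <- sum(resid(f)^2)
  expect_equal(fit$add, unname(coef(f)[2]), tolerance = 1e-6)
  expect_equal(fit$lod, n / 2 * log10(ss0 / ss1), tolerance = 1e-6)
  expect_lt(abs(fit$add - 0.8), 2 * summary(f)$coefficients[2, 2])

  # uninformative probabilities collapse to the null
  fit0 <- em_interval_mapping(y, rep(0.5, n))
  expect_equal(fit0$lod, 0)
  expect_equal(fit0$add, 0)

  # EM optimum agrees with a brute-force likelihood grid search
  set.seed(13)
  for (i in 1:20) {
    nn <- 60
    pp <- runif(nn, 0.05, 0.95)
    yy <- rnorm(nn, ifelse(runif(nn) < pp, 0.7, -0.7), 1)
    ft <- em_interval_mapping(yy, pp, tol = 1e-12, maxit = 2000)
    ll_em <- im_loglik(yy, pp, ft$mu, ft$add, ft$sigma2)
    grid_mu <- seq(ft$mu - 0.3, ft$mu + 0.3, length.out = 41)
    grid_a <- seq(ft$add - 0.3, ft$add + 0.3, length.out = 41)
    ll_grid <- max(outer(grid_mu, grid_a, Vectorize(function(m, a)
      im_loglik(yy, pp, m, a, ft$sigma2))))
    expect_gte(ll_em + 1e-4, ll_grid)
  }
})

test_that("EM iterations never decrease the observed-data likelihood", {
  set.seed(14)
  n <- 80
  pp <- runif(n, 0.1, 0.9)
  yy <- rnorm(n, ifelse(runif(n) < pp, 1, -1), 1.5)
  # replay EM manually with the exported likelihood evaluator
  mu <- mean(yy); a <- 0.1; s2 <- var(yy)
  ll_prev <- -Inf
  for (it in 1:50) {
    ll <- im_loglik(yy, pp, mu, a, s2)
    expect_gte(ll, ll_prev - 1e-9)
    ll_prev <- ll
    d1 <- dnorm(yy, mu + a, sqrt(s2)); d2 <- dnorm(yy, mu - a, sqrt(s2))
    w <- pp * d1 / (pp * d1 + (1 - pp) * d2)
    cc <- 2 * sum(w) - n
    det <- n^2 - cc^2
    Sy <- sum(yy); Swy <- sum((2 * w - 1) * yy)
    mu <- (n * Sy - cc * Swy) / det
    a <- (n * Swy - cc * Sy) / det
    s2 <- mean(w * (yy - mu - a)^2 + (1 - w) * (yy - mu + a)^2)
  }
})

test_that("with no cofactors the scan equals simple interval mapping", {
  set.seed(15)
  for (i in 1:20) {
    pos <- seq(0, 20, by = 2)
    G <- simulate_genotypes(pos, 120, "ril")
    colnames(G) <- sprintf("m%02d", seq_along(pos))
    y <- rnorm(120) + 0.3 * (1 - 2 * G[, 6])
    map <- genetic_map(data.frame(marker = colnames(G), chrom = "1",
                                  pos = pos))
    st <- scan_settings(step = 0.5, p_in = 1e-9, p_out = 2e-9,
                        fun = "haldane", tol = 1e-12, maxit = 2000)
    scan <- icim_scan(y, geno_matrix(G, "ril"), map, st)
    expect_equal(nrow(scan$cofactors), 0L)
    ref <- im_reference(y, G, pos, step = 0.5, fun = "haldane",
                        popt = "ril")
    expect_equal(scan$profile$lod, ref$lod, tolerance = 1e-6)
    expect_equal(scan$profile$add, ref$add, tolerance = 1e-4)
  }
})

test_that("scans are invariant to phenotype location and scale", {
  set.seed(16)
  d <- sim_xy(n = 120, m = 21, beta = {
    b <- rep(0, 21)
    b[8] <- 1
    b
  })
  map <- genetic_map(data.frame(marker = colnames(d$G), chrom = "1",
                                pos = seq(0, 100, by = 5)))
  st <- scan_settings(step = 1, fun = "haldane")
  s1 <- icim_scan(d$y, geno_matrix(d$G, "ril"), map, st)
  s2 <- icim_scan(3 * d$y + 10, geno_matrix(d$G, "ril"), map, st)
  expect_equal(s1$profile$lod, s2$profile$lod, tolerance = 1e-6)
  expect_equal(3 * s1$profile$add, s2$profile$add, tolerance = 1e-4)
})

test_that("fully missing markers are scanned via informative flanks", {
  set.seed(17)
  pop <- simulate_population(model_catalog("I", 0.2))
  cons <- map_scenario(pop, "consensus")
  st <- scan_settings(step = 0.5, fun = "haldane")
  scan <- icim_scan(cons$y, cons$geno, cons$map, st)
  expect_equal(nrow(scan$profile), 201L)
  expect_true(all(is.finite(scan$profile$lod)))
  expect_true(all(scan$profile$lod >= 0))
})

test_that("QTL calling respects threshold, separation, and one-LOD drops", {
  mk_scan <- function(pos, lod) {
    structure(list(profile = tibble::tibble(chrom = "1", pos = pos,
                                            lod = lod, add = 1, pve = 5,
                                            iterations = 1),
                   settings = scan_settings(fun = "haldane")),
              class = "icim_scan")
  }
  pos <- seq(0, 40, by = 0.5)
  # sub-threshold profile: no calls
  low <- mk_scan(pos, 2.4 * exp(-(pos - 20)^2 / 50))
  expect_equal(nrow(call_qtls(low)), 0L)

  # single clean peak: one call with a one-LOD-drop interval
  lod1 <- 8 * exp(-(pos - 20)^2 / 18)
  one <- call_qtls(mk_scan(pos, lod1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$peak, 20)
  half_w <- sqrt(18 * log(8 / 7))   # analytic one-LOD half-width
  expect_equal(one$ci_hi - one$ci_lo, 2 * half_w, tolerance = 0.05)

  # two peaks 8 cM apart, both above threshold: two calls
  lod2 <- 6 * exp(-(pos - 16)^2 / 4) + 5 * exp(-(pos - 24)^2 / 4)
  two <- call_qtls(mk_scan(pos, lod2))
  expect_equal(nrow(two), 2L)
  expect_equal(two$peak, c(16, 24))

  # shoulder without a 1-LOD dip within 5 cM: merged into one call
  lod3 <- pmax(6 * exp(-(pos - 20)^2 / 30),
               5.9 * exp(-(pos - 22)^2 / 30))
  expect_equal(nrow(call_qtls(mk_scan(pos, lod3))), 1L)
})
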