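#' Convert between recombination frequency and map distance
#'
#' `map_distance()` converts a recombination frequency `r` (per meiosis)
#' into centimorgans; `map_rf()` is the exact inverse.  The Haldane
#' function assumes no crossover interference, d = -50 ln(1 - 2r); the
#' Kosambi function allows moderate interference,
#' d = 25 ln((1 + 2r) / (1 - 2r)).
#'
#' @param r recombination frequency in \[0, 0.5).
#' @param d map distance in cM (>= 0).
#' @param fun mapping function, `"kosambi"` (default) or `"haldane"`.
#' @return distance in cM, or recombination frequency.
#' @export
map_distance <- function(r, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(r < 0 | r >= 0.5)) abort("r must lie in [0, 0.5)")
  switch(fun,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname map_distance
#' @export
map_rf <- function(d, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(d < 0)) abort("distance must be non-negative")
  switch(fun,
         haldane = (1 - exp(-d / 50)) / 2,
         kosambi = tanh(d / 50) / 2)
}

# observable discordance fraction R between two homozygous loci as a
# function of the meiotic recombination frequency r
rf_to_observed <- function(r, pop_type) {
  switch(pop_type, dh = r, ril = 2 * r / (1 + 2 * r))
}

observed_to_rf <- function(R, pop_type) {
  switch(pop_type, dh = R, ril = R / (2 * (1 - R)))
}

#' Two-point recombination-frequency estimate for RIL/DH data
#'
#' Maximum-likelihood estimate of the meiotic recombination frequency `r`
#' between two markers from one homozygous population, with its sampling
#' variance (delta method for RILs).  With `n` informative line pairs and
#' `k` discordant ones, the observed discordance is R = k/n.  For DH
#' populations r = R directly; for selfed RILs the expected discordance is
#' R = 2r/(1 + 2r), hence r = R / (2(1 - R)) with
#' Var(r) = R(1 - R)/n * (2(1 - R)^2)^-2.
#'
#' The estimate is flagged non-estimable when fewer than `n_min` informative
#' pairs are available or when R >= 0.5 (no linkage signal); non-estimable
#' estimates carry zero weight in [combine_rf()].
#'
#' @param g1,g2 genotype code vectors (0/1/`NA`) for the two markers.
#' @param pop_type `"ril"` or `"dh"`.
#' @param n_min minimum informative pairs for estimability (default 20).
#' @return one-row tibble with `r`, `variance`, `n`, `k`, `estimable`.
#' @export
rf_estimate <- function(g1, g2, pop_type = c("ril", "dh"), n_min = 20) {
  pop_type <- match.arg(pop_type)
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  k <- sum(g1[ok] != g2[ok])
  if (n == 0) {
    return(tibble::tibble(r = NA_real_, variance = Inf, n = 0L, k = 0L,
                          estimable = FALSE))
  }
  R <- k / n
  if (R >= 0.5) {
    return(tibble::tibble(r = NA_real_, variance = Inf, n = n, k = k,
                          estimable = FALSE))
  }
  vR <- R * (1 - R) / n
  if (pop_type == "dh") {
    r <- R
    v <- vR
  } else {
    r <- R / (2 * (1 - R))
    v <- vR * (1 / (2 * (1 - R)^2))^2
  }
  r <- min(r, 0.4999)
  tibble::tibble(r = r, variance = v, n = as.integer(n), k = as.integer(k),
                 estimable = n >= n_min)
}

# weight for inverse-variance combination; the floor (1/(n+2))^2 keeps
# zero-variance (no-recombinant) estimates dominant but finite
rf_weight <- function(variance, n, estimable, floor = NULL) {
  fl <- floor %||% (1 / (ifelse(is.na(n), 1e6, n) + 2))^2
  w <- 1 / pmax(variance, fl)
  w[!estimable | !is.finite(variance) & variance > 0] <- 0
  w[!estimable] <- 0
  w
}

#' Combine recombination-frequency estimates across populations
#'
#' Inverse-variance-weighted combination of per-population two-point
#' estimates: r_c = sum(w_i r_i) / sum(w_i) with w_i = 1/Var_i and weight
#' zero for populations where the pair is not estimable;
#' Var(r_c) = 1 / sum(w_i).  Estimates with zero sampling variance (no
#' observed recombinants) dominate through a variance floor of
#' (1/(n + 2))^2; if several zero-variance estimates disagree a conflict
#' message is emitted and they are averaged by their floored weights.
#'
#' @param estimates tibble of estimates as returned by [rf_estimate()]
#'   (columns `r`, `variance`, `n`, `estimable`).
#' @param variance_floor optional fixed variance floor overriding the
#'   per-population (1/(n+2))^2 default.
#' @return one-row tibble with the combined `r`, `variance`, `n`
#'   (informative pairs summed over estimable populations), `estimable`.
#' @export
combine_rf <- function(estimates, variance_floor = NULL) {
  if (nrow(estimates) == 0) abort("no estimates to combine")
  if (nrow(estimates) == 1) return(estimates[, intersect(
    c("r", "variance", "n", "k", "estimable"), names(estimates))])
  est <- estimates$estimable
  zero <- est & estimates$variance == 0
  if (sum(zero) > 1 && length(unique(estimates$r[zero])) > 1)
    inform("conflicting zero-variance recombination estimates; averaging",
           class = "clamap_rf_conflict")
  w <- rf_weight(estimates$variance, estimates$n, est, variance_floor)
  if (any(zero)) w[!zero] <- 0   # perfect data dominates exactly
  if (sum(w) == 0) {
    return(tibble::tibble(r = NA_real_, variance = Inf,
                          n = as.integer(sum(estimates$n[est])),
                          estimable = FALSE))
  }
  r_in <- ifelse(est, estimates$r, 0)     # zero-weight entries may be NA
  r <- sum(w * r_in) / sum(w)
  v <- 1 / sum(rf_weight(estimates$variance, estimates$n, est,
                         variance_floor))
  tibble::tibble(r = min(r, 0.4999), variance = v,
                 n = as.integer(sum(estimates$n[est])), estimable = TRUE)
}

#' Pairwise combined recombination-frequency matrix
#'
#' Estimates the two-point recombination frequency for every marker pair in
#' every population carrying both markers, then combines populations by
#' inverse-variance weighting.  Each population is visited once and its
#' pairwise estimates are computed in one vectorised pass.  A pair is
#' estimable if at least one population provides an estimable two-point
#' estimate for it.
#'
#' @param populations list of [geno_matrix()] objects (marker sets may
#'   differ and overlap partially).
#' @param markers marker universe; default is the union over populations.
#' @param n_min minimum informative pairs per population (default 20).
#' @param variance_floor optional fixed variance floor (see
#'   [combine_rf()]).
#' @return an `rf_matrix` object: list with `markers` and symmetric
#'   matrices `r`, `variance`, `n`, `estimable`.
#' @export
build_rf_matrix <- function(populations, markers = NULL, n_min = 20,
                            variance_floor = NULL) {
  if (inherits(populations, "geno_matrix")) populations <- list(populations)
  univ <- unique(unlist(lapply(populations, colnames)))
  markers <- markers %||% univ
  if (!all(markers %in% univ))
    abort("marker(s) absent from every population")
  m <- length(markers)
  Wsum <- matrix(0, m, m); WRsum <- matrix(0, m, m)
  Nsum <- matrix(0L, m, m); Est <- matrix(FALSE, m, m)
  Zero <- matrix(FALSE, m, m)  # a zero-variance estimate exists
  WR0 <- matrix(0, m, m); W0 <- matrix(0, m, m)

  for (popn in populations) {
    idx <- match(colnames(popn), markers)
    keep <- !is.na(idx)
    G <- popn[, keep, drop = FALSE]
    idx <- idx[keep]
    obs <- !is.na(G)
    A <- (G == 1L) & obs; A[!obs] <- FALSE
    B <- (G == 0L) & obs; B[!obs] <- FALSE
    obs <- matrix(as.numeric(obs), nrow(G))
    A <- matrix(as.numeric(A), nrow(G))
    B <- matrix(as.numeric(B), nrow(G))
    n <- crossprod(obs)
    k <- crossprod(A, B) + crossprod(B, A)
    R <- k / n
    est <- n >= n_min & !is.na(R) & R < 0.5
    vR <- R * (1 - R) / n
    if (pop_type(popn) == "dh") {
      r <- R; v <- vR
    } else {
      r <- R / (2 * (1 - R))
      v <- vR * (1 / (2 * (1 - R)^2))^2
    }
    r <- pmin(r, 0.4999)
    w <- rf_weight(v, n, est, variance_floor)
    w[!est] <- 0
    z <- est & v == 0
    # zero-variance entries recorded separately so they dominate exactly
    w_nz <- w; w_nz[z] <- 0
    r0 <- r; r0[!est] <- 0
    Wsum[idx, idx] <- Wsum[idx, idx] + w_nz
    WRsum[idx, idx] <- WRsum[idx, idx] + w_nz * r0
    W0[idx, idx] <- W0[idx, idx] + ifelse(z, w, 0)
    WR0[idx, idx] <- WR0[idx, idx] + ifelse(z, w * r0, 0)
    Zero[idx, idx] <- Zero[idx, idx] | z
    Nsum[idx, idx] <- Nsum[idx, idx] + ifelse(est, n, 0)
    Est[idx, idx] <- Est[idx, idx] | est
  }
  r_c <- ifelse(Zero, WR0 / W0, WRsum / Wsum)
  v_c <- 1 / (Wsum + W0)
  r_c[!Est] <- NA_real_
  v_c[!Est] <- Inf
  diag(r_c) <- 0; diag(v_c) <- 0; diag(Est) <- TRUE
  dimnames(r_c) <- dimnames(v_c) <- dimnames(Nsum) <- dimnames(Est) <-
    list(markers, markers)
  structure(list(markers = markers, r = r_c, variance = v_c,
                 n = Nsum, estimable = Est),
            class = "rf_matrix")
}

#' @export
print.rf_matrix <- function(x, ...) {
  m <- length(x$markers)
  off <- x$estimable & upper.tri(x$estimable)
  cat(sprintf("<rf_matrix> %d markers, %.1f%% of pairs estimable\n",
              m, 100 * mean(off[upper.tri(off)])))
  invisible(x)
}

#' Export an rf_matrix as a tidy pair table
#'
#' @param x an `rf_matrix`.
#' @param ... unused.
#' @return tibble with one row per unordered marker pair: `marker_i`,
#'   `marker_j`, `r`, `variance`, `n`, `estimable`.
#' @method tidy rf_matrix
#' @export
tidy.rf_matrix <- function(x, ...) {
  m <- length(x$markers)
  ut <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    marker_i = x$markers[ut[, 1]],
    marker_j = x$markers[ut[, 2]],
    r = x$r[ut],
    variance = x$variance[ut],
    n = x$n[ut],
    estimable = x$estimable[ut]
  )
}
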