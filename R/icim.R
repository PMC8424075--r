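#' Settings for an ICIM scan
#'
#' Defaults follow common practice for biparental QTL scans: scanning step
#' 0.2 cM (0.1 cM is conventional in simulation studies), stepwise entry
#' and removal probabilities 0.001 and 0.002, and a LOD threshold of 2.5.
#'
#' @param step scanning step in cM.
#' @param p_in,p_out stepwise-regression entry/removal p-value thresholds
#'   (must satisfy 0 < p_in < p_out < 1).
#' @param lod_threshold LOD threshold for calling QTLs.
#' @param fun mapping function used to convert map distances to
#'   recombination frequencies during scanning.
#' @param tol,maxit EM convergence tolerance (relative log-likelihood
#'   change) and iteration cap.
#' @return a `scan_settings` list.
#' @export
scan_settings <- function(step = 0.2, p_in = 0.001, p_out = 0.002,
                          lod_threshold = 2.5,
                          fun = c("kosambi", "haldane"),
                          tol = 1e-8, maxit = 200) {
  fun <- match.arg(fun)
  if (!(p_in > 0 && p_in < p_out && p_out < 1))
    abort("need 0 < p_in < p_out < 1")
  if (step <= 0) abort("step must be positive")
  structure(list(step = step, p_in = p_in, p_out = p_out,
                 lod_threshold = lod_threshold, fun = fun,
                 tol = tol, maxit = maxit),
            class = "scan_settings")
}

#' Forward-backward stepwise marker selection
#'
#' Selects background (cofactor) markers for ICIM by stepwise linear
#' regression: at each forward step the candidate with the smallest
#' partial-F p-value enters if p < `p_in`; after every addition, included
#' markers whose partial-F p-value (given the others) exceeds `p_out` are
#' removed, worst first; the cycle repeats to a fixed point.  Ties break
#' to the lower marker index, and candidates collinear with the current
#' model (for example duplicated marker columns) are skipped, so only the
#' lowest-index copy can enter.
#'
#' @param y phenotype vector.
#' @param X marker design matrix, +1/-1 coding with missing values imputed
#'   to 0 (the expectation under 1:1 segregation).
#' @param p_in,p_out entry/removal p-value thresholds.
#' @return list with `index` (selected columns, in entry order),
#'   `beta` (their joint least-squares coefficients), `intercept`.
#' @export
stepwise_select <- function(y, X, p_in = 0.001, p_out = 0.002) {
  n <- length(y)
  m <- ncol(X)
  colssq <- colSums(X^2)
  S <- integer(0)
  repeat {
    changed <- FALSE
    df_fwd <- n - length(S) - 2
    if (df_fwd >= 1) {
      Q <- cbind(1, X[, S, drop = FALSE])
      qrQ <- qr(Q)
      ry <- qr.resid(qrQ, y)
      RSS <- sum(ry^2)
      cand <- setdiff(seq_len(m), S)
      if (length(cand) > 0) {
        RX <- qr.resid(qrQ, X[, cand, drop = FALSE])
        ssx <- colSums(RX^2)
        ok <- ssx > 1e-8 * pmax(colssq[cand], 1)
        red <- rep(0, length(cand))
        red[ok] <- colSums(RX[, ok, drop = FALSE] * ry)^2 / ssx[ok]
        RSS1 <- pmax(RSS - red, 1e-12)
        pval <- pf(red / (RSS1 / df_fwd), 1, df_fwd, lower.tail = FALSE)
        pval[!ok] <- 1
        best <- which.min(pval)        # ties -> lowest index
        if (pval[best] < p_in) {
          S <- c(S, cand[best])
          changed <- TRUE
        }
      }
    }
    # backward elimination to a fixed point
    while (length(S) > 0) {
      Qf <- cbind(1, X[, S, drop = FALSE])
      RSSf <- sum(qr.resid(qr(Qf), y)^2)
      dff <- n - length(S) - 1
      if (dff < 1) {                   # over-saturated: drop last entered
        S <- S[-length(S)]
        next
      }
      pdrop <- vapply(seq_along(S), function(j) {
        Qm <- cbind(1, X[, S[-j], drop = FALSE])
        RSSm <- sum(qr.resid(qr(Qm), y)^2)
        Fj <- (RSSm - RSSf) / (RSSf / dff)
        pf(Fj, 1, dff, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_out) {
        S <- S[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(S) == 0)
    return(list(index = integer(0), beta = numeric(0),
                intercept = mean(y)))
  fit <- lm.fit(cbind(1, X[, S, drop = FALSE]), y)
  list(index = S,
       beta = setNames(fit$coefficients[-1],
                       colnames(X)[S] %||% as.character(S)),
       intercept = fit$coefficients[1])
}

#' Background-adjust a phenotype for one scanned interval
#'
#' Subtracts the fitted cofactor contributions from the phenotype,
#' excluding any cofactor that is a flanking marker of the interval being
#' scanned (so the scanned interval's own signal is not absorbed).  With
#' no cofactors the phenotype is returned unchanged and ICIM reduces to
#' simple interval mapping.
#'
#' @param y phenotype vector.
#' @param X imputed +1/-1 marker matrix used in [stepwise_select()].
#' @param selection result of [stepwise_select()].
#' @param exclude column indices of the current interval's flanking
#'   markers.
#' @return adjusted phenotype vector.
#' @export
adjust_phenotype <- function(y, X, selection, exclude = integer(0)) {
  keep <- setdiff(selection$index, exclude)
  if (length(keep) == 0) return(y)
  b <- selection$beta[match(keep, selection$index)]
  y - drop(X[, keep, drop = FALSE] %*% b)
}

#' Conditional QTL genotype probabilities from flanking markers
#'
#' Probability that a line carries the parent-1 QTL homozygote (code 0,
#' genotype score +1) given its flanking marker genotypes, assuming
#' independent recombination in the two sub-intervals on the observable
#' discordance metric of the population type (R = r for DH,
#' R = 2r/(1 + 2r) for selfed RILs).  A missing flank contributes no
#' information; with both flanks missing the prior (0.5, 0.5) results.
#' All arguments are recycled to the longest length.
#'
#' @param g_left,g_right flanking genotype codes (0/1/`NA`).
#' @param r_left,r_right meiotic recombination frequencies between the
#'   QTL position and the left/right flank.
#' @param pop_type `"ril"` or `"dh"`.
#' @return vector of P(QTL genotype = parent-1 homozygote).
#' @export
conditional_qtl_probs <- function(g_left, g_right, r_left, r_right,
                                  pop_type = c("ril", "dh")) {
  pop_type <- match.arg(pop_type)
  RL <- rf_to_observed(r_left, pop_type)
  RR <- rf_to_observed(r_right, pop_type)
  # P(flank | QTL class), with a missing flank contributing factor 1
  fac <- function(g, R, q) {
    out <- ifelse(is.na(g), 1, ifelse(g == q, 1 - R, R))
    out[is.na(out)] <- 1               # missing flank, R irrelevant
    out
  }
  num <- fac(g_left, RL, 0L) * fac(g_right, RR, 0L)
  den <- num + fac(g_left, RL, 1L) * fac(g_right, RR, 1L)
  num / den
}

#' EM interval-mapping fit at a single position
#'
#' Fits the two-component Gaussian mixture with means mu + a and mu - a,
#' common variance and fixed per-line mixing probabilities by EM, and
#' reports the LOD score against the single-Gaussian null fitted to the
#' same (background-adjusted) phenotype.
#'
#' @param dy background-adjusted phenotype vector.
#' @param pplus per-line probability of the +1 QTL class (see
#'   [conditional_qtl_probs()]).
#' @param tol,maxit EM control.
#' @return one-row tibble: `lod`, `add`, `mu`, `sigma2`, `iterations`,
#'   `converged`.
#' @export
em_interval_mapping <- function(dy, pplus, tol = 1e-8, maxit = 200) {
  stopifnot(length(dy) == length(pplus))
  res <- em_scan_cpp(matrix(dy, ncol = 1), 1L,
                     matrix(pplus, ncol = 1), tol, maxit)
  res <- unname(res)
  tibble::tibble(lod = res[1, 1], add = res[1, 2], mu = res[1, 3],
                 sigma2 = res[1, 4], iterations = res[1, 5],
                 converged = res[1, 5] < maxit)
}

#' Interval-mapping mixture log-likelihood
#'
#' Observed-data log-likelihood of the two-component mixture with fixed
#' per-line mixing probabilities at given parameters; useful for checking
#' EM monotonicity or comparing fits.
#'
#' @param y (adjusted) phenotype vector.
#' @param pplus per-line probability of the +1 QTL class.
#' @param mu,add,sigma2 mixture parameters.
#' @return log-likelihood value.
#' @export
im_loglik <- function(y, pplus, mu, add, sigma2) {
  im_loglik_cpp(y, pplus, mu, add, sigma2)
}

# conditional-probability matrix (n lines x P scan positions) using the
# nearest informative flanking marker on each side of every position;
# markers missing in every line are handled by the same rule (they are
# never informative, so the fallback is automatic)
build_pplus <- function(codes, mpos, grid, popt, fun) {
  n <- nrow(codes)
  keep <- colSums(!is.na(codes)) > 0
  codes <- codes[, keep, drop = FALSE]
  opos <- mpos[keep]
  Mo <- ncol(codes)
  P <- length(grid)
  pp <- matrix(0.5, n, P)
  if (Mo == 0) return(pp)
  complete <- !anyNA(codes)
  if (complete) {
    # all lines share the same flanking markers: vectorise over the whole
    # n x P grid with the observable discordance R per position
    Li <- findInterval(grid, opos)
    has_l <- Li >= 1
    has_r <- Li < Mo
    RL <- rep(0, P)
    RL[has_l] <- rf_to_observed(
      map_rf(grid[has_l] - opos[Li[has_l]], fun), popt)
    RR <- rep(0, P)
    RR[has_r] <- rf_to_observed(
      map_rf(opos[pmin(Li, Mo - 1)[has_r] + 1] - grid[has_r], fun), popt)
    GL <- codes[, pmax(Li, 1L), drop = FALSE]        # n x P
    GR <- codes[, pmin(Li + 1L, Mo), drop = FALSE]
    rlE <- rep(RL, each = n)
    rrE <- rep(RR, each = n)
    # P(flank | Q class): for codes in {0,1}, (1-R) - (1-2R) g selects
    # 1-R when the flank matches the class and R otherwise
    fl0 <- (1 - rlE) - (1 - 2 * rlE) * as.numeric(GL)
    fl1 <- rlE + (1 - 2 * rlE) * as.numeric(GL)
    fr0 <- (1 - rrE) - (1 - 2 * rrE) * as.numeric(GR)
    fr1 <- rrE + (1 - 2 * rrE) * as.numeric(GR)
    if (any(!has_l)) {
      idx <- rep(!has_l, each = n)
      fl0[idx] <- 1; fl1[idx] <- 1
    }
    if (any(!has_r)) {
      idx <- rep(!has_r, each = n)
      fr0[idx] <- 1; fr1[idx] <- 1
    }
    num <- fl0 * fr0
    pp <- matrix(num / (num + fl1 * fr1), n, P)
  } else {
    for (i in seq_len(n)) {
      oi <- which(!is.na(codes[i, ]))
      if (length(oi) == 0) next
      po <- opos[oi]
      li <- findInterval(grid, po)
      gl <- ifelse(li >= 1, codes[i, oi[pmax(li, 1)]], NA_integer_)
      rl <- ifelse(li >= 1, map_rf(pmax(grid - po[pmax(li, 1)], 0), fun),
                   0.25)
      ri <- li + 1
      gr <- ifelse(ri <= length(oi), codes[i, oi[pmin(ri, length(oi))]],
                   NA_integer_)
      rr <- ifelse(ri <= length(oi),
                   map_rf(pmax(po[pmin(ri, length(oi))] - grid, 0), fun),
                   0.25)
      pp[i, ] <- conditional_qtl_probs(gl, gr, rl, rr, popt)
    }
  }
  pp
}

#' Inclusive composite interval mapping scan
#'
#' Scans every chromosome of the map for additive QTLs: background
#' markers are selected once per trait by [stepwise_select()]; at each
#' scanned position the phenotype is adjusted for all cofactors except
#' the current interval's flanking markers, the conditional QTL-genotype
#' probabilities are computed from the nearest informative flanking
#' markers per line, and the interval-mapping mixture is fitted by EM.
#' PVE at a position is 100 a^2 s2x / s2y, with s2x the sample variance
#' of the per-line expected QTL code and s2y the variance of the
#' unadjusted phenotype.
#'
#' @param y phenotype vector (one value per line of `geno`).
#' @param geno a [geno_matrix()].
#' @param map a `genetic_map` covering (a subset of) the genotyped
#'   markers; scan order and intervals follow the map.
#' @param settings a [scan_settings()] list.
#' @return an `icim_scan` object; `tidy()` returns the per-position
#'   profile (`chrom`, `pos`, `lod`, `add`, `pve`).
#' @export
icim_scan <- function(y, geno, map, settings = scan_settings()) {
  map <- genetic_map(map, normalize = FALSE)
  mk <- map$marker
  if (!all(mk %in% colnames(geno)))
    abort("map contains markers absent from the genotype matrix")
  n <- nrow(geno)
  if (length(y) != n) abort("phenotype length must match line count")
  codes <- unclass(geno)[, mk, drop = FALSE]
  popt <- pop_type(geno)
  X <- 1 - 2 * codes
  X[is.na(X)] <- 0
  sel <- stepwise_select(y, X, settings$p_in, settings$p_out)
  s2y <- var(y)

  profiles <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    if (length(rows) < 2) next
    mpos <- map$pos[rows]
    M <- length(rows)
    grid <- seq(mpos[1], mpos[M], by = settings$step)
    if (tail(grid, 1) < mpos[M] - 1e-9) grid <- c(grid, mpos[M])
    ivl <- pmin(pmax(findInterval(grid, mpos), 1L), M - 1L)

    # per-interval adjusted phenotype: full adjustment, then add back the
    # contribution of any cofactor that flanks the interval
    S_local <- match(sel$index, rows)        # cofactor position on chrom
    dy_full <- adjust_phenotype(y, X, sel)
    dy <- matrix(dy_full, n, M - 1)
    if (any(!is.na(S_local))) {
      for (s in which(!is.na(S_local))) {
        gidx <- sel$index[s]
        lidx <- S_local[s]
        for (k in intersect(c(lidx - 1, lidx), seq_len(M - 1)))
          dy[, k] <- dy[, k] + sel$beta[s] * X[, gidx]
      }
    }
    pp <- build_pplus(codes[, rows, drop = FALSE], mpos, grid,
                      popt, settings$fun)
    fit <- em_scan_cpp(dy, as.integer(ivl), pp, settings$tol,
                       settings$maxit)
    xb <- 2 * pp - 1
    sx2 <- (colMeans(xb^2) - colMeans(xb)^2) * n / (n - 1)
    profiles[[ch]] <- tibble::tibble(
      chrom = ch, pos = grid,
      lod = fit[, "lod"], add = fit[, "add"],
      pve = 100 * fit[, "add"]^2 * sx2 / s2y,
      iterations = fit[, "iterations"])
  }
  structure(list(profile = dplyr::bind_rows(profiles),
                 cofactors = tibble::tibble(
                   marker = mk[match(sel$index, seq_along(mk))],
                   index = sel$index,
                   beta = unname(sel$beta)),
                 intercept = sel$intercept,
                 settings = settings, n = n, s2y = s2y),
            class = "icim_scan")
}

#' @export
print.icim_scan <- function(x, ...) {
  cat(sprintf(
    "<icim_scan> %d positions, %d cofactor(s), max LOD %.2f\n",
    nrow(x$profile), nrow(x$cofactors), max(x$profile$lod)))
  invisible(x)
}

#' Call QTLs from an ICIM scan profile
#'
#' Peaks are local maxima of the LOD profile at or above the threshold;
#' two maxima are distinct peaks only if they are at least `min_sep` cM
#' apart or separated by a valley dropping at least `dip` LOD below the
#' lower of the two.  Each peak's support interval is the one-LOD-drop
#' region around it (linear interpolation between grid points, clipped at
#' chromosome ends); effect and PVE are read at the peak.
#'
#' @param scan an `icim_scan` object.
#' @param lod_threshold LOD threshold (default: from the scan settings).
#' @param min_sep,dip peak-separation rules in cM and LOD units.
#' @return tibble: `chrom`, `peak`, `lod`, `add`, `pve`, `ci_lo`,
#'   `ci_hi`.
#' @export
call_qtls <- function(scan, lod_threshold = NULL, min_sep = 5, dip = 1) {
  thr <- lod_threshold %||% scan$settings$lod_threshold
  out <- list()
  prof <- scan$profile
  for (ch in unique(prof$chrom)) {
    p <- prof[prof$chrom == ch, ]
    lod <- p$lod
    np <- length(lod)
    if (np < 3) next
    is_max <- vapply(seq_len(np), function(i) {
      l <- if (i > 1) lod[i - 1] else -Inf
      r <- if (i < np) lod[i + 1] else -Inf
      lod[i] >= l && lod[i] >= r &&
        (lod[i] > l || lod[i] > r)     # plateau: keep first point
    }, TRUE)
    # plateau handling: keep only the first index of equal-neighbour runs
    cand <- which(is_max & lod >= thr)
    if (length(cand) == 0) next
    cand <- cand[order(-lod[cand], p$pos[cand])]
    kept <- integer(0)
    for (i in cand) {
      distinct <- TRUE
      for (k in kept) {
        rng <- sort(c(i, k))
        valley <- min(lod[rng[1]:rng[2]])
        if (abs(p$pos[i] - p$pos[k]) < min_sep &&
            (lod[i] - valley) < dip) {
          distinct <- FALSE
          break
        }
      }
      if (distinct) kept <- c(kept, i)
    }
    for (i in kept) {
      drop_to <- lod[i] - 1
      lo <- p$pos[1]
      for (j in seq(i, 1)) {
        if (lod[j] < drop_to) {
          f <- (drop_to - lod[j]) / (lod[j + 1] - lod[j])
          lo <- p$pos[j] + f * (p$pos[j + 1] - p$pos[j])
          break
        }
      }
      hi <- p$pos[np]
      for (j in seq(i, np)) {
        if (lod[j] < drop_to) {
          f <- (drop_to - lod[j]) / (lod[j - 1] - lod[j])
          hi <- p$pos[j] - f * (p$pos[j] - p$pos[j - 1])
          break
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, peak = p$pos[i], lod = lod[i], add = p$add[i],
        pve = p$pve[i], ci_lo = lo, ci_hi = hi)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(chrom = character(), peak = double(),
                          lod = double(), add = double(), pve = double(),
                          ci_lo = double(), ci_hi = double()))
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$peak)
}
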