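#' Catalogue of additive-QTL simulation models
#'
#' Returns the design of one of the three standard simulation models on a
#' 100 cM chromosome carrying 101 evenly spaced markers (1 cM grid):
#' model `"I"` has a single QTL at 34.5 cM with additive effect +1;
#' models `"II"` and `"III"` have two linked QTLs at 26.5 and 34.5 cM, in
#' coupling (+1, +1) for model II and in repulsion (-1, +1) for model III.
#' Broad-sense heritability is restricted to the levels studied with each
#' model: 0.05/0.1/0.2 for model I and 0.1/0.2/0.4 for models II and III.
#' The two-QTL positions are configurable via `qtl_pos` since only the
#' single-QTL position is fixed by convention.
#'
#' @param model `"I"`, `"II"` or `"III"`.
#' @param h2 broad-sense heritability level (must be valid for the model).
#' @param n population size (default 200).
#' @param pop_type `"ril"` (default) or `"dh"`.
#' @param qtl_pos override for the two-QTL positions of models II/III.
#' @return a `sim_design` list: `chrom_len`, `marker_pos`, `qtl` (tibble
#'   `name`, `pos`, `effect`), `h2`, `n`, `pop_type`.
#' @export
model_catalog <- function(model = c("I", "II", "III"), h2, n = 200,
                          pop_type = c("ril", "dh"),
                          qtl_pos = c(26.5, 34.5)) {
  model <- match.arg(model)
  pop_type <- match.arg(pop_type)
  allowed <- if (model == "I") c(0.05, 0.1, 0.2) else c(0.1, 0.2, 0.4)
  if (!isTRUE(any(abs(h2 - allowed) < 1e-12)))
    abort(sprintf("h2 = %s is not a studied level for model %s (use %s)",
                  h2, model, paste(allowed, collapse = "/")))
  qtl <- switch(model,
    I = tibble::tibble(name = "QTL1", pos = 34.5, effect = 1),
    II = tibble::tibble(name = c("QTL1", "QTL2"), pos = qtl_pos,
                        effect = c(1, 1)),
    III = tibble::tibble(name = c("QTL1", "QTL2"), pos = qtl_pos,
                         effect = c(-1, 1)))
  structure(list(chrom_len = 100, marker_pos = 0:100, qtl = qtl, h2 = h2,
                 n = n, pop_type = pop_type),
            class = "sim_design")
}

#' Simulate homozygous-line genotypes along a chromosome
#'
#' Simulates `n` fully homozygous lines (RIL by selfing, or DH) as a
#' Markov chain along the ordered loci: the first locus is Bernoulli(1/2)
#' over the two parental classes and the switch probability between
#' adjacent loci is the *observable* discordance of the population type --
#' the meiotic recombination fraction r (Haldane inverse of the interval
#' length, crossovers without interference) for DH, and the single-spore
#' inflation R = 2r/(1 + 2r) for selfed RILs.
#'
#' @param pos locus positions in cM (sorted, one chromosome).
#' @param n number of lines.
#' @param pop_type `"ril"` or `"dh"`.
#' @return integer matrix n x length(pos) of 0/1 codes.
#' @export
simulate_genotypes <- function(pos, n, pop_type = c("ril", "dh")) {
  pop_type <- match.arg(pop_type)
  if (is.unsorted(pos)) abort("locus positions must be sorted")
  L <- length(pos)
  r <- map_rf(diff(pos), "haldane")
  Radj <- rf_to_observed(r, pop_type)
  G <- matrix(0L, n, L)
  G[, 1] <- rbinom(n, 1, 0.5)
  for (j in seq_len(L - 1)) {
    sw <- runif(n) < Radj[j]
    G[, j + 1] <- ifelse(sw, 1L - G[, j], G[, j])
  }
  G
}

#' Simulate phenotypes at a target heritability
#'
#' Phenotype = genetic value + Gaussian noise.  The genetic value of line
#' i is the sum of additive effects over QTLs on the +1/-1 genotype scale;
#' the error variance is sized against the *realized* sample genetic
#' variance so that the broad-sense heritability equals `h2` in
#' expectation for the population actually drawn (linkage covariance
#' between QTLs is automatically included).  If the realized genetic
#' variance is zero the supplied `expected_vg` is used instead (logged via
#' a message).
#'
#' @param x matrix n x Q of QTL genotype codes (+1/-1).
#' @param effects additive effects, length Q.
#' @param h2 broad-sense heritability in (0, 1).
#' @param expected_vg fallback genetic variance when the realized one
#'   degenerates to zero.
#' @return numeric phenotype vector with attributes `"genetic_value"` and
#'   `"sigma2_e"`.
#' @export
simulate_phenotypes <- function(x, effects, h2, expected_vg = NULL) {
  if (h2 <= 0 || h2 >= 1) abort("h2 must lie in (0, 1)")
  g <- drop(x %*% effects)
  vg <- var(g)
  if (vg == 0) {
    if (!is.null(expected_vg) && expected_vg > 0) {
      inform("realized genetic variance is zero; using expected value",
             class = "clamap_vg_fallback")
      vg <- expected_vg
    } else if (all(effects == 0)) {
      inform("null genetic model; phenotype is unit-variance noise",
             class = "clamap_vg_fallback")
      vg <- h2 / (1 - h2)              # gives sigma2_e = 1
    } else {
      abort("zero realized genetic variance and no expected_vg fallback")
    }
  }
  s2e <- vg * (1 - h2) / h2
  y <- g + rnorm(length(g), 0, sqrt(s2e))
  attr(y, "genetic_value") <- g
  attr(y, "sigma2_e") <- s2e
  y
}

#' Simulate one population under a simulation design
#'
#' Draws marker and QTL genotypes jointly (the QTLs are loci inside the
#' Markov chain, not imputed from flanking markers) and a phenotype at the
#' design heritability.  QTL genotype codes are +1 for the parent-1
#' homozygote and -1 for the parent-2 homozygote, so an additive effect of
#' 1 separates the homozygote means by 2 units.
#'
#' @param design a `sim_design` from [model_catalog()].
#' @param seed optional integer seed.
#' @return a `sim_population` list: `geno` ([geno_matrix()] of markers
#'   only), `map` (`genetic_map` of the markers), `qtl_x` (n x Q matrix of
#'   +1/-1 codes), `y`, `design`.
#' @export
simulate_population <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk_pos <- design$marker_pos
  q_pos <- design$qtl$pos
  all_pos <- sort(c(mk_pos, q_pos))
  is_q <- match(q_pos, all_pos)         # QTL positions assumed distinct
  G <- simulate_genotypes(all_pos, design$n, design$pop_type)
  qx <- 1 - 2 * G[, is_q, drop = FALSE]
  Gm <- G[, -is_q, drop = FALSE]
  colnames(Gm) <- sprintf("M%03d", seq_along(mk_pos))
  rownames(Gm) <- sprintf("L%03d", seq_len(design$n))
  # expected genetic variance under free recombination-adjusted linkage,
  # used only if the realized variance degenerates
  a <- design$qtl$effect
  Rq <- outer(q_pos, q_pos, function(p1, p2)
    rf_to_observed(map_rf(abs(p1 - p2), "haldane"), design$pop_type))
  evg <- sum(outer(a, a) * (1 - 2 * Rq))
  y <- simulate_phenotypes(qx, a, design$h2, expected_vg = evg)
  map <- genetic_map(tibble::tibble(marker = colnames(Gm), chrom = "1",
                                    pos = mk_pos))
  structure(list(geno = geno_matrix(Gm, design$pop_type), map = map,
                 qtl_x = qx, y = y, design = design),
            class = "sim_population")
}

#' Restrict a simulated population to a map scenario
#'
#' Produces the genotype/map pair used for QTL scanning under one of two
#' scenarios: `"individual"` keeps only the markers at even cM positions
#' (half the grid, 2 cM density) with a map of those markers;
#' `"consensus"` keeps the full map but sets the genotype codes of the
#' odd-cM markers to missing for every line -- the markers exist on the
#' consensus map yet were never genotyped in this population.  The
#' observed genotype data are identical between the two scenarios.
#'
#' @param pop a `sim_population`.
#' @param scenario `"individual"` or `"consensus"`.
#' @return list with `geno` ([geno_matrix()]), `map` (`genetic_map`), `y`.
#' @export
map_scenario <- function(pop, scenario = c("individual", "consensus")) {
  scenario <- match.arg(scenario)
  map <- pop$map
  even <- abs(map$pos / 2 - round(map$pos / 2)) < 1e-9
  if (scenario == "individual") {
    geno <- geno_matrix(unclass(pop$geno)[, even, drop = FALSE],
                        pop_type(pop$geno))
    map <- genetic_map(map[even, ], normalize = FALSE)
  } else {
    codes <- unclass(pop$geno)
    codes[, !even] <- NA_integer_
    geno <- geno_matrix(codes, pop_type(pop$geno))
  }
  list(geno = geno, map = map, y = pop$y)
}

#' Multi-population fixture with partially overlapping marker sets
#'
#' Generates `k` populations from a single true map, each observing a
#' random marker subset: every marker enters each population independently
#' with probability sqrt(`overlap`), so any two populations share a
#' fraction of about `overlap` of the marker universe.  Per-population
#' individual maps are re-estimated from that population's own genotypes
#' (true marker order restricted to its markers, adjacent distances from
#' its own two-point estimates).
#'
#' @param truth_map `genetic_map` of the full marker set (one or more
#'   chromosomes).
#' @param k number of populations.
#' @param overlap target pairwise shared fraction in (0, 1].
#' @param n lines per population.
#' @param seed optional seed.
#' @param pop_type population type.
#' @param fun mapping function for re-estimated individual maps.
#' @return list with `populations` (list of [geno_matrix()]), `maps`
#'   (list of `genetic_map`), `truth_map`.
#' @export
multi_population_fixture <- function(truth_map, k, overlap, n, seed = NULL,
                                     pop_type = c("ril", "dh"),
                                     fun = "haldane") {
  pop_type <- match.arg(pop_type)
  if (overlap <= 0 || overlap > 1) abort("overlap must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  q <- sqrt(overlap)
  pops <- list(); maps <- list()
  for (j in seq_len(k)) {
    pop_chunks <- list(); map_chunks <- list()
    for (ch in unique(truth_map$chrom)) {
      sub <- truth_map[truth_map$chrom == ch, ]
      take <- runif(nrow(sub)) < q
      take[c(1, nrow(sub))] <- TRUE      # keep ends so groups stay linked
      G <- simulate_genotypes(sub$pos, n, pop_type)
      colnames(G) <- sub$marker
      G <- G[, take, drop = FALSE]
      # re-estimate adjacent distances from this population's own data
      p_sub <- sub[take, ]
      d <- vapply(seq_len(nrow(p_sub) - 1), function(i) {
        e <- rf_estimate(G[, i], G[, i + 1], pop_type, n_min = 10)
        if (e$estimable) map_distance(e$r, fun)
        else p_sub$pos[i + 1] - p_sub$pos[i]
      }, 0)
      map_chunks[[ch]] <- tibble::tibble(marker = p_sub$marker, chrom = ch,
                                         pos = cumsum(c(0, d)))
      pop_chunks[[ch]] <- G
    }
    Gall <- do.call(cbind, pop_chunks)
    rownames(Gall) <- sprintf("P%d_L%03d", j, seq_len(n))
    pops[[j]] <- geno_matrix(Gall, pop_type)
    maps[[j]] <- genetic_map(dplyr::bind_rows(map_chunks))
  }
  shared <- if (k > 1) mean(utils::combn(k, 2, function(ij) {
    length(intersect(colnames(pops[[ij[1]]]), colnames(pops[[ij[2]]]))) /
      nrow(truth_map)
  })) else 1
  list(populations = pops, maps = maps, truth_map = truth_map,
       shared_fraction = shared)
}
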