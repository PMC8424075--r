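# small rf_matrix built directly from a distance matrix, for tests that
# need full control over adjacency structure
rf_from_dist <- function(D, fun = "haldane") {
  r <- map_rf(D, fun)
  est <- is.finite(D)
  diag(est) <- TRUE
  v <- matrix(1e-4, nrow(D), ncol(D))
  v[!est] <- Inf
  diag(v) <- 0
  structure(list(markers = rownames(D), r = r, variance = v,
                 n = matrix(200L, nrow(D), ncol(D)), estimable = est),
            class = "rf_matrix")
}

linear_dist <- function(pos, names = sprintf("m%02d", seq_along(pos))) {
  D <- abs(outer(pos, pos, "-"))
  dimnames(D) <- list(names, names)
  D
}

test_that("TSP ordering recovers linear maps and matches brute force", {
  pos <- c(0, 3, 7, 12, 20, 26)
  D <- linear_dist(pos)
  ord <- order_markers_tsp(D)
  expect_equal(as.character(ord), rownames(D))
  expect_equal(attr(ord, "sarf"), 26)

  # exhaustive optimum on random map-like instances (criterion: >= 95%
  # hits, never worse than 1.05x the optimum)
  set.seed(61)
  hits <- 0
  trials <- 500
  for (i in seq_len(trials)) {
    m <- sample(5:8, 1)
    D <- noisy_map_dist(m)
    got <- attr(order_markers_tsp(D), "sarf")
    opt <- brute_sarf_min(D)
    expect_lte(got, 1.05 * opt + 1e-9)
    if (got <= opt + 1e-9) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})

test_that("ordering is canonical under input permutation and reversal", {
  pos <- c(0, 2, 5, 9, 14, 22, 31)
  D <- linear_dist(pos)
  ord0 <- as.character(order_markers_tsp(D))
  set.seed(5)
  for (i in 1:10) {
    p <- sample(nrow(D))
    ordp <- as.character(order_markers_tsp(D[p, p]))
    expect_equal(ordp, ord0)
  }
  expect_error(order_markers_tsp(D[1, 1, drop = FALSE]), "at least 2")
})

test_that("position assignment accumulates, bins, bridges, and splits", {
  # adjacent r = 0.1, 0.1 under Haldane: 0, 11.157, 22.31 cM
  rf <- rf_from_dist(linear_dist(c(0, 11.15717, 22.31435)))
  p <- assign_positions(rf$markers, rf, "haldane")
  expect_equal(p$pos, c(0, -50 * log(0.8), -100 * log(0.8)),
               tolerance = 1e-4)

  # r = 0 between the pair: one bin, identical positions
  rf0 <- rf_from_dist(linear_dist(c(0, 0, 5)))
  p0 <- assign_positions(rf0$markers, rf0, "haldane")
  expect_equal(p0$pos[1], p0$pos[2])
  expect_equal(max(p0$bin), 2L)

  # missing adjacent rf bridged through the next marker, interpolated
  Db <- linear_dist(c(0, 6, 14))
  Db["m01", "m02"] <- Db["m02", "m01"] <- Inf
  rfb <- rf_from_dist(Db)
  pb <- assign_positions(rfb$markers, rfb, "haldane")
  expect_equal(max(pb$pos), 14, tolerance = 1e-9)
  expect_equal(pb$pos[2], 7, tolerance = 1e-9)       # even interpolation
  expect_equal(attr(pb, "bridged")$interpolated, 1L)

  # fully disconnected pair splits with a warning
  Dd <- linear_dist(c(0, 4, 100, 104))
  Dd[1:2, 3:4] <- Inf
  Dd[3:4, 1:2] <- Inf
  rfd <- rf_from_dist(Dd)
  expect_warning(pd <- assign_positions(rfd$markers, rfd, "haldane"),
                 class = "clamap_disconnected_group")
  expect_equal(max(pd$subgroup), 2L)
})

test_that("2-opt output never degrades the nearest-neighbour seed", {
  set.seed(77)
  for (i in 1:25) {
    m <- sample(6:12, 1)
    D <- noisy_map_dist(m)
    ord <- order_markers_tsp(D)
    # any single adjacent transposition cannot improve (local optimality)
    o <- match(as.character(ord), rownames(D))
    s0 <- sum(D[cbind(o[-m], o[-1])])
    for (j in 1:(m - 1)) {
      o2 <- o
      o2[c(j, j + 1)] <- o2[c(j + 1, j)]
      expect_gte(sum(D[cbind(o2[-m], o2[-1])]), s0 - 1e-9)
    }
  }
})

test_that("chromosome grouping keeps anchors and resolves conflicts by linkage", {
  set.seed(303)
  # two chromosomes, marker mX reported on different chromosomes by the
  # two maps but tightly linked to the chr1 anchors
  pos1 <- c(0, 5, 10, 15)
  G <- simulate_genotypes(sort(c(pos1, 2.5)), 150, "ril")
  ch1 <- sprintf("c1_%d", 1:4)
  chr2 <- simulate_genotypes(c(0, 5, 10), 150, "ril")
  ch2 <- sprintf("c2_%d", 1:3)
  colnames(G) <- c(ch1[1], "mX", ch1[2:4])   # mX truly at 2.5 cM on chr1
  colnames(chr2) <- ch2
  geno <- geno_matrix(cbind(G, chr2), "ril")
  map_a <- genetic_map(data.frame(
    marker = c(ch1, "mX", ch2),
    chrom = c(rep("1A", 4), "1A", rep("2B", 3)),
    pos = c(pos1, 2.5, 0, 5, 10)))
  map_b <- genetic_map(data.frame(
    marker = c(ch1, "mX", ch2),
    chrom = c(rep("1A", 4), "7A", rep("2B", 3)),  # conflicting call
    pos = c(pos1, 0, 0, 5, 10)))
  asg <- assign_groups(list(map_a, map_b), list(geno))
  expect_equal(asg$chrom[asg$marker == "mX"], "1A")
  expect_equal(asg$status[asg$marker == "mX"], "linkage")
  expect_true(all(asg$anchor[asg$marker %in% ch1]))
  expect_false(asg$anchor[asg$marker == "mX"])

  # marker linked to no anchor: dropped and logged
  lone <- matrix(rbinom(150, 1, 0.5), dimnames = list(NULL, "lone"))
  geno2 <- geno_matrix(cbind(G, chr2, lone), "ril")
  map_c <- genetic_map(rbind(tibble::as_tibble(map_a),
                             data.frame(marker = "lone", chrom = "5D",
                                        pos = 0)))
  map_d <- genetic_map(rbind(tibble::as_tibble(map_b),
                             data.frame(marker = "lone", chrom = "6B",
                                        pos = 0)))
  asg2 <- assign_groups(list(map_c, map_d), list(geno2))
  expect_equal(asg2$status[asg2$marker == "lone"], "dropped")
  expect_true(is.na(asg2$chrom[asg2$marker == "lone"]))
})

test_that("pruning removes a planted inflator and leaves clean maps alone", {
  set.seed(88)
  pos <- seq(0, 100, by = 5)
  G <- simulate_genotypes(pos, 250, "ril")
  colnames(G) <- sprintf("m%02d", seq_along(pos))
  geno <- geno_matrix(G, "ril")
  rfm <- build_rf_matrix(list(geno))
  # a misplaced marker (truly at 90 cM, forced between 45 and 50 cM)
  # inflates the group by two long adjacent intervals
  ord <- c(colnames(G)[1:10], "m19", colnames(G)[c(11:18, 20:21)])
  len_with <- max(suppressWarnings(
    assign_positions(ord, rfm, "haldane"))$pos)
  pr <- prune_inflators(ord, rfm, max_contrib = 10, fun = "haldane")
  expect_equal(pr$removed$marker, "m19")
  len_without <- max(assign_positions(pr$order, rfm, "haldane")$pos)
  expect_gt(len_with - len_without, 10)

  # clean map: nothing pruned
  rfc <- build_rf_matrix(list(geno_matrix(G, "ril")))
  prc <- prune_inflators(colnames(G), rfc, max_contrib = 10,
                         fun = "haldane")
  expect_equal(nrow(prc$removed), 0)
  expect_lt(nrow(prc$removed) / ncol(G), 0.01)
})

test_that("single-population consensus reproduces the input order", {
  set.seed(21)
  pos <- seq(0, 60, by = 3)
  G <- simulate_genotypes(pos, 220, "ril")
  colnames(G) <- sprintf("s%02d", seq_along(pos))
  geno <- geno_matrix(G, "ril")
  imap <- genetic_map(data.frame(marker = colnames(G), chrom = "3B",
                                 pos = pos))
  cons <- build_consensus(list(geno), list(imap), fun = "haldane")
  expect_setequal(cons$map$marker, colnames(G))
  expect_equal(abs(spearman_collinearity(cons$map$marker,
                                         colnames(G))), 1)
})

test_that("three-population consensus with partial overlap recovers truth", {
  truth <- genetic_map(data.frame(marker = sprintf("t%02d", 1:51),
                                  chrom = "1A",
                                  pos = seq(0, 100, by = 2)))
  fx <- multi_population_fixture(truth, k = 3, overlap = 0.5, n = 200,
                                 seed = 99)
  cons <- build_consensus(fx$populations, fx$maps, fun = "haldane")
  # every marker genotyped in at least one population is retained unless
  # explicitly pruned, and pruning stays rare
  univ <- unique(unlist(lapply(fx$populations, colnames)))
  expect_setequal(cons$map$marker, setdiff(univ, cons$pruned$marker))
  expect_lt(nrow(cons$pruned) / length(univ), 0.05)
  rho <- abs(spearman_collinearity(cons$map$marker, truth$marker))
  expect_gte(rho, 0.99)
  # variance reduction: adjacent combined estimates exist for the chain
  expect_true(all(diff(cons$map$pos) >= 0))
})

test_that("disjoint marker sets split instead of fabricating linkage", {
  set.seed(55)
  G1 <- simulate_genotypes(seq(0, 20, 5), 100, "ril")
  colnames(G1) <- paste0("a", 1:5)
  G2 <- simulate_genotypes(seq(0, 20, 5), 100, "ril")
  colnames(G2) <- paste0("b", 1:5)
  maps <- list(
    genetic_map(data.frame(marker = colnames(G1), chrom = "4A",
                           pos = seq(0, 20, 5))),
    genetic_map(data.frame(marker = colnames(G2), chrom = "4A",
                           pos = seq(0, 20, 5))))
  cons <- suppressWarnings(build_consensus(
    list(geno_matrix(G1, "ril"), geno_matrix(G2, "ril")), maps,
    fun = "haldane"))
  expect_gte(length(unique(cons$map$chrom)), 2)
})
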