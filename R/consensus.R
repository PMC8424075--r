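#' Assign markers to consensus chromosome groups
#'
#' Markers are grouped by their chromosome assignment in the contributing
#' individual maps.  Markers placed on the same chromosome in every map
#' that carries them keep that chromosome, and those present in *all* maps
#' become anchors.  Markers with conflicting assignments are resolved by
#' combined linkage strength: the candidate chromosome maximising the sum
#' of inverse sampling variances over anchors with an estimable combined
#' recombination frequency <= `r_link` wins.  Markers that cannot be
#' resolved (no linkage to any candidate's anchors) are dropped and
#' logged.
#'
#' @param individual_maps list of `genetic_map` tibbles.
#' @param populations list of [geno_matrix()] objects, parallel to the
#'   maps; needed only when conflicting assignments must be resolved.
#' @param r_link maximum combined recombination frequency counted as
#'   linkage to an anchor (default 0.3).
#' @param n_min minimum informative pairs (see [rf_estimate()]).
#' @return tibble with columns `marker`, `chrom`, `anchor`, `n_maps`,
#'   `status` (`"consistent"`, `"linkage"`, `"dropped"`); dropped markers
#'   have `chrom = NA`.
#' @export
assign_groups <- function(individual_maps, populations = NULL,
                          r_link = 0.3, n_min = 20) {
  if (length(individual_maps) < 1) abort("need at least one map")
  k <- length(individual_maps)
  votes <- dplyr::bind_rows(lapply(individual_maps, function(m)
    tibble::as_tibble(m)[, c("marker", "chrom")]))
  tab <- dplyr::summarise(votes,
                          chroms = list(unique(.data$chrom)),
                          n_maps = dplyr::n(),
                          .by = "marker")
  tab$anchor <- tab$n_maps == k & lengths(tab$chroms) == 1
  consistent <- lengths(tab$chroms) == 1
  out <- tibble::tibble(
    marker = tab$marker,
    chrom = ifelse(consistent, vapply(tab$chroms, `[`, "", 1), NA),
    anchor = tab$anchor,
    n_maps = tab$n_maps,
    status = ifelse(consistent, "consistent", "dropped")
  )
  conflicted <- which(!consistent)
  if (length(conflicted) > 0 && !is.null(populations)) {
    anchors_by_chrom <- split(out$marker[out$anchor],
                              out$chrom[out$anchor])
    for (i in conflicted) {
      mk <- tab$marker[i]
      cands <- tab$chroms[[i]]
      score <- vapply(cands, function(ch) {
        anc <- anchors_by_chrom[[ch]]
        if (is.null(anc) || length(anc) == 0) return(0)
        sum(vapply(anc, function(a)
          anchor_link_weight(mk, a, populations, n_min), 0))
      }, 0)
      if (max(score) > 0) {
        out$chrom[i] <- cands[which.max(score)]
        out$status[i] <- "linkage"
      }
    }
  }
  out
}

# combined 1/variance weight between marker and anchor if linked at r <= 0.3
anchor_link_weight <- function(marker, anchor, populations, n_min,
                               r_link = 0.3) {
  ests <- dplyr::bind_rows(lapply(populations, function(p) {
    if (!(marker %in% colnames(p)) || !(anchor %in% colnames(p)))
      return(NULL)
    rf_estimate(p[, marker], p[, anchor], pop_type(p), n_min = n_min)
  }))
  if (is.null(ests) || nrow(ests) == 0) return(0)
  cmb <- combine_rf(ests)
  if (!cmb$estimable || is.na(cmb$r) || cmb$r > r_link) return(0)
  1 / max(cmb$variance, 1e-12)
}

# sum of adjacent distances along an order (the TSP/SARF objective)
sarf <- function(d, ord) {
  if (length(ord) < 2) return(0)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# one first-improvement sweep of 2-opt on the open path: reversing
# ord[i..j] replaces edges (i-1, i) and (j, j+1) by (i-1, j) and (i, j+1)
two_opt_pass <- function(d, ord) {
  m <- length(ord)
  improved <- FALSE
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      if (i == 1 && j == m) next
      delta <- 0
      if (i > 1) delta <- delta + d[ord[i - 1], ord[j]] -
          d[ord[i - 1], ord[i]]
      if (j < m) delta <- delta + d[ord[i], ord[j + 1]] -
          d[ord[j], ord[j + 1]]
      if (delta < -1e-12) {
        ord[i:j] <- ord[j:i]
        improved <- TRUE
      }
    }
  }
  list(ord = ord, improved = improved)
}

# or-opt sweep: relocate segments of length 1..3 (either orientation) to
# their best improving insertion point; complements 2-opt, whose reversal
# moves cannot fix a single displaced marker between two well-ordered runs
or_opt_pass <- function(d, ord) {
  m <- length(ord)
  improved <- FALSE
  for (L in seq_len(min(3, m - 2))) {
    i <- 1
    while (i + L - 1 <= m) {
      seg <- ord[i:(i + L - 1)]
      rest <- ord[-(i:(i + L - 1))]
      nr <- length(rest)
      # cost change from removing the segment
      rem <- 0
      if (i > 1) rem <- rem + d[ord[i - 1], ord[i]]
      if (i + L <= m) rem <- rem + d[ord[i + L - 1], ord[i + L]]
      if (i > 1 && i + L <= m) rem <- rem - d[ord[i - 1], ord[i + L]]
      best_delta <- -1e-12
      best_k <- NA
      best_seg <- seg
      for (k in 0:nr) {
        lft <- if (k >= 1) rest[k] else NA
        rgt <- if (k < nr) rest[k + 1] else NA
        cut <- if (!is.na(lft) && !is.na(rgt)) d[lft, rgt] else 0
        for (sg in if (L > 1) list(seg, rev(seg)) else list(seg)) {
          ins <- cut * 0
          if (!is.na(lft)) ins <- ins + d[lft, sg[1]]
          if (!is.na(rgt)) ins <- ins + d[sg[L], rgt]
          delta <- (ins - cut) - rem
          if (delta < best_delta) {
            best_delta <- delta
            best_k <- k
            best_seg <- sg
          }
        }
      }
      if (!is.na(best_k)) {
        ord <- append(rest, best_seg, after = best_k)
        improved <- TRUE
      }
      i <- i + 1
    }
  }
  list(ord = ord, improved = improved)
}

#' Order markers by nearest-neighbour + 2-opt TSP heuristic
#'
#' Finds a marker order minimising the sum of adjacent distances (SARF) as
#' an open travelling-salesman path: a nearest-neighbour tour is grown
#' from the marker whose nearest neighbour is farthest away (a likely
#' chromosome end), then improved by 2-opt segment reversals alternated
#' with or-opt relocations of segments of up to three markers
#' (first-improvement, left-to-right sweeps repeated to a joint fixed
#' point; the relocation moves repair single displaced markers that
#' reversals alone cannot).
#' Non-estimable distances (`NA`) are completed by the shortest path over
#' estimable edges (map distances are additive along a chromosome);
#' disconnected pairs fall back to twice the largest estimable distance,
#' discouraging but not forbidding adjacency.  The
#' result is deterministic in the input and canonically oriented so that
#' the lexicographically smallest marker among `anchors` lies in the front
#' half.
#'
#' @param dist symmetric matrix of pairwise distances (cM or r), `NA` for
#'   non-estimable pairs; dimnames are marker names.
#' @param anchors markers used to fix the orientation (default: all).
#' @return character vector of marker names in order, with the achieved
#'   SARF as attribute `"sarf"`.
#' @export
order_markers_tsp <- function(dist, anchors = NULL) {
  m <- nrow(dist)
  if (is.null(rownames(dist)))
    dimnames(dist) <- list(paste0("M", 1:m), paste0("M", 1:m))
  if (m < 2) abort("need at least 2 markers to order")
  d <- as.matrix(dist)
  if (any(is.na(d))) {
    # map distances are additive along a chromosome, so a pair with no
    # direct estimate is completed by the shortest path over estimated
    # edges (Floyd-Warshall); only truly disconnected pairs fall back to
    # the 2 x max penalty, which discourages adjacency without
    # forbidding it
    dmax <- suppressWarnings(max(d, na.rm = TRUE))
    if (!is.finite(dmax)) dmax <- 1
    g <- d
    g[is.na(g)] <- Inf
    for (k in seq_len(m))
      g <- pmin(g, outer(g[, k], g[k, ], `+`))
    d <- pmin(g, d, na.rm = TRUE)
    d[!is.finite(d)] <- 2 * dmax
  }
  diag(d) <- Inf

  # nearest-neighbour construction from the most isolated marker
  nnd <- apply(d, 1, min)
  start <- which.max(nnd)
  ord <- integer(m)
  ord[1] <- start
  left <- rep(TRUE, m); left[start] <- FALSE
  for (i in 2:m) {
    cand <- which(left)
    nxt <- cand[which.min(d[ord[i - 1], cand])]
    ord[i] <- nxt
    left[nxt] <- FALSE
  }
  nn_sarf <- sarf(d, ord)

  # 2-opt segment reversals alternated with or-opt relocations of short
  # segments, both first-improvement left-to-right, to a joint fixed point
  repeat {
    imp2 <- two_opt_pass(d, ord)
    ord <- imp2$ord
    imp3 <- or_opt_pass(d, ord)
    ord <- imp3$ord
    if (!imp2$improved && !imp3$improved) break
  }
  stopifnot(sarf(d, ord) <= nn_sarf + 1e-9)

  out <- rownames(dist)[ord]
  out <- orient_order(out, anchors %||% rownames(dist))
  structure(out, sarf = sarf(d, match(out, rownames(dist))))
}

# reverse the order if the smallest-named anchor sits in the back half
orient_order <- function(ord, anchors) {
  anchors <- intersect(anchors, ord)
  if (length(anchors) == 0) anchors <- ord
  key <- min(anchors)
  i <- match(key, ord)
  if (i - 1 > length(ord) - i) rev(ord) else ord
}

#' Assign cM positions along an ordered marker sequence
#'
#' Walks the order accumulating map distances converted from the combined
#' adjacent recombination frequencies.  When an adjacent pair is not
#' estimable, the shortest estimable bridge is used: the nearest
#' downstream marker with an estimable frequency to the last placed marker
#' defines the interval and the intervening markers are spaced evenly
#' inside it (logged).  Pairs at r = 0 share a position (one bin).  If no
#' bridge exists the group is split into subgroups with a warning.
#'
#' @param order character vector of marker names in map order.
#' @param rf an `rf_matrix` covering the markers.
#' @param fun mapping function (see [map_distance()]).
#' @return tibble `marker`, `pos`, `bin`, `subgroup` with attributes
#'   `"bridged"` (log tibble).
#' @export
assign_positions <- function(order, rf, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  m <- length(order)
  pos <- numeric(m)
  sub <- integer(m)
  sub[1] <- 1L
  bridged <- list()
  i <- 1
  while (i < m) {
    r_adj <- rf$r[order[i], order[i + 1]]
    if (isTRUE(rf$estimable[order[i], order[i + 1]])) {
      pos[i + 1] <- pos[i] + map_distance(min(r_adj, 0.4999), fun)
      sub[i + 1] <- sub[i]
      i <- i + 1
    } else {
      ks <- if (i + 2 <= m) (i + 2):m else integer(0)
      est <- ks[vapply(ks, function(k)
        isTRUE(rf$estimable[order[i], order[k]]), TRUE)]
      if (length(est) == 0) {          # disconnected: start a new subgroup
        pos[i + 1] <- 0
        sub[i + 1] <- sub[i] + 1L
        i <- i + 1
      } else {
        k <- est[1]
        D <- map_distance(min(rf$r[order[i], order[k]], 0.4999), fun)
        steps <- k - i
        pos[(i + 1):k] <- pos[i] + D * seq_len(steps) / steps
        sub[(i + 1):k] <- sub[i]
        bridged[[length(bridged) + 1]] <- tibble::tibble(
          from = order[i], to = order[k], span_cM = D,
          interpolated = steps - 1L)
        i <- k
      }
    }
  }
  if (max(sub) > 1)
    warn(sprintf("group disconnected; split into %d subgroups", max(sub)),
         class = "clamap_disconnected_group")
  out <- tibble::tibble(marker = order, pos = pos, subgroup = sub)
  out <- dplyr::mutate(out, pos = .data$pos - min(.data$pos),
                       bin = cumsum(c(1, diff(.data$pos) > 1e-9)),
                       .by = "subgroup")
  attr(out, "bridged") <- dplyr::bind_rows(bridged)
  out
}

#' Remove markers that inflate a linkage group
#'
#' Emulates the manual curation step of consensus-map construction:
#' iteratively removes the marker whose deletion most shortens the group,
#' as long as the gain exceeds `max_contrib` cM per marker; positions are
#' re-assigned after every removal.  If a physical map is supplied,
#' markers whose removal raises the group's Spearman collinearity with it
#' by more than 0.02 are also removed.  All removals are logged.
#'
#' @param order ordered marker names of one group.
#' @param rf an `rf_matrix` covering the markers.
#' @param max_contrib maximum tolerated single-marker length contribution
#'   in cM (default 10).
#' @param physical optional physical map tibble (`marker`, `chrom`, `bp`).
#' @param fun mapping function.
#' @return list with elements `order` (retained markers, in order) and
#'   `removed` (log tibble: `marker`, `reason`, `gain`).
#' @export
prune_inflators <- function(order, rf, max_contrib = 10, physical = NULL,
                            fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  removed <- list()
  glen <- function(o) {
    if (length(o) < 2) return(0)
    p <- suppressWarnings(assign_positions(o, rf, fun))
    max(p$pos)
  }
  repeat {
    if (length(order) <= 2) break
    len <- glen(order)
    gains <- vapply(seq_along(order),
                    function(i) len - glen(order[-i]), 0)
    best <- which.max(gains)
    if (gains[best] <= max_contrib) break
    removed[[length(removed) + 1]] <- tibble::tibble(
      marker = order[best], reason = "length", gain = gains[best])
    order <- order[-best]
  }
  if (!is.null(physical)) {
    repeat {
      if (length(order) <= 4) break
      base_rho <- tryCatch(
        spearman_collinearity(order, physical), error = function(e) NA)
      if (is.na(base_rho)) break
      gains <- vapply(seq_along(order), function(i) {
        tryCatch(spearman_collinearity(order[-i], physical) - base_rho,
                 error = function(e) -Inf)
      }, 0)
      best <- which.max(gains)
      if (gains[best] <= 0.02) break
      removed[[length(removed) + 1]] <- tibble::tibble(
        marker = order[best], reason = "collinearity", gain = gains[best])
      order <- order[-best]
    }
  }
  list(order = order, removed = dplyr::bind_rows(removed))
}

#' Build a consensus genetic map from multiple populations
#'
#' Runs the full combined-linkage-analysis pipeline: (1) group markers by
#' chromosome across the individual maps, resolving conflicts by combined
#' linkage to anchors; (2) estimate a combined recombination-frequency
#' matrix per group; (3) order the markers of each group by the
#' nearest-neighbour + 2-opt heuristic on combined map distances;
#' (4) assign cM positions from adjacent combined frequencies and prune
#' map-inflating markers.  Per-group Spearman collinearity against each
#' input map is reported as a diagnostic.
#'
#' @param populations list of [geno_matrix()] objects.
#' @param individual_maps list of `genetic_map` tibbles (same order).
#' @param fun mapping function (default `"kosambi"`).
#' @param n_min,r_link,max_contrib,variance_floor tuning parameters, see
#'   [rf_estimate()], [assign_groups()], [prune_inflators()],
#'   [combine_rf()].
#' @param physical optional physical map used during pruning.
#' @return a `consensus_map` object: list with `map` (tibble `marker`,
#'   `chrom`, `pos`, `bin`, `n_pops`, `provenance`), `pruned`,
#'   `diagnostics`, `assignment`.
#' @export
build_consensus <- function(populations, individual_maps,
                            fun = c("kosambi", "haldane"),
                            n_min = 20, r_link = 0.3, max_contrib = 10,
                            physical = NULL, variance_floor = NULL) {
  fun <- match.arg(fun)
  if (inherits(populations, "geno_matrix")) populations <- list(populations)
  asg <- assign_groups(individual_maps, populations,
                       r_link = r_link, n_min = n_min)
  pruned_all <- list()
  groups <- list()
  for (ch in sort(unique(asg$chrom[!is.na(asg$chrom)]))) {
    mks <- asg$marker[!is.na(asg$chrom) & asg$chrom == ch]
    if (length(mks) < 2) {
      groups[[ch]] <- tibble::tibble(marker = mks, chrom = ch, pos = 0,
                                     bin = 1L)
      next
    }
    rfm <- build_rf_matrix(populations, markers = mks, n_min = n_min,
                           variance_floor = variance_floor)
    D <- rfm$r
    D[!rfm$estimable] <- NA
    D[rfm$estimable] <- map_distance(pmin(D[rfm$estimable], 0.4999), fun)
    anchors <- asg$marker[asg$anchor & asg$marker %in% mks]
    ord <- order_markers_tsp(D, anchors = anchors)
    pr <- prune_inflators(as.character(ord), rfm, max_contrib = max_contrib,
                          physical = physical, fun = fun)
    if (nrow(pr$removed) > 0)
      pruned_all[[ch]] <- dplyr::mutate(pr$removed, chrom = ch)
    ptab <- suppressWarnings(assign_positions(pr$order, rfm, fun))
    ptab <- dplyr::mutate(
      ptab,
      chrom = if (max(ptab$subgroup) > 1)
        paste0(ch, ifelse(.data$subgroup == 1, "",
                          paste0(".", .data$subgroup)))
      else ch)
    groups[[ch]] <- ptab[, c("marker", "chrom", "pos", "bin")]
  }
  cmap <- dplyr::bind_rows(groups)
  prov <- vapply(cmap$marker, function(mk)
    paste(which(vapply(populations, function(p) mk %in% colnames(p), TRUE)),
          collapse = ","), "")
  cmap$n_pops <- lengths(strsplit(prov, ","))
  cmap$provenance <- prov
  cmap <- dplyr::arrange(cmap, .data$chrom, .data$pos)

  diags <- list()
  for (ch in unique(cmap$chrom)) {
    sub <- cmap$marker[cmap$chrom == ch]
    base_ch <- sub("\\.[0-9]+$", "", ch)
    for (j in seq_along(individual_maps)) {
      im <- individual_maps[[j]]
      rho <- tryCatch(
        spearman_collinearity(sub, im$marker[im$chrom == base_ch]),
        error = function(e) NA_real_)
      diags[[length(diags) + 1]] <- tibble::tibble(
        chrom = ch, map = j, spearman = abs(rho))
    }
  }
  structure(list(map = cmap,
                 pruned = dplyr::bind_rows(pruned_all),
                 diagnostics = dplyr::bind_rows(diags),
                 assignment = asg,
                 mapping_function = fun),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  s <- map_summary(x$map)
  tot <- s[s$chrom == "all", ]
  cat(sprintf(
    "<consensus_map> %d markers in %d groups, %.1f cM, %d bins\n",
    tot$n_markers, nrow(s) - 1, tot$length, tot$n_bins))
  if (nrow(x$pruned) > 0)
    cat(sprintf("  %d marker(s) pruned\n", nrow(x$pruned)))
  invisible(x)
}

#' @rdname build_consensus
#' @param x a `consensus_map`.
#' @param ... unused.
#' @method tidy consensus_map
#' @export
tidy.consensus_map <- function(x, ...) x$map

#' @rdname build_consensus
#' @method glance consensus_map
#' @export
glance.consensus_map <- function(x, ...) {
  s <- map_summary(x$map)
  tot <- s[s$chrom == "all", ]
  tibble::tibble(n_markers = tot$n_markers,
                 n_groups = nrow(s) - 1L,
                 length_cM = tot$length,
                 n_bins = tot$n_bins,
                 n_pruned = nrow(x$pruned),
                 n_dropped = sum(is.na(x$assignment$chrom)))
}
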