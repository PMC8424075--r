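#' Score one replicate's QTL calls against the simulated truth
#'
#' A true QTL is detected when at least one called peak lies inside the
#' support window of `support_half_width` cM on either side of its true
#' position.  Every call is assigned to at most one true QTL (the nearest
#' whose window contains it; ties go to the lower position); among calls
#' assigned to the same QTL only the highest-LOD one supplies the
#' estimates and the others are discarded without penalty.  Calls
#' assigned to no QTL are false positives.
#'
#' @param calls tibble of QTL calls from [call_qtls()].
#' @param truth tibble with columns `name` and `pos` (true QTLs).
#' @param support_half_width half-width of the detection window in cM
#'   (default 2.5, i.e. a 5 cM window).
#' @return list with `per_qtl` (tibble: `qtl`, `detected`, `pos`, `add`,
#'   `lod`, `cil`) and `n_false` (false-positive count).
#' @export
evaluate_detection <- function(calls, truth, support_half_width = 2.5) {
  Q <- nrow(truth)
  assigned <- rep(NA_integer_, nrow(calls))
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      dist <- abs(calls$peak[i] - truth$pos)
      inside <- which(dist <= support_half_width)
      if (length(inside) > 0) {
        inside <- inside[order(dist[inside], truth$pos[inside])]
        assigned[i] <- inside[1]
      }
    }
  }
  per <- lapply(seq_len(Q), function(q) {
    idx <- which(assigned == q)
    if (length(idx) == 0)
      return(tibble::tibble(qtl = truth$name[q], detected = FALSE,
                            pos = NA_real_, add = NA_real_,
                            lod = NA_real_, cil = NA_real_))
    best <- idx[which.max(calls$lod[idx])]
    tibble::tibble(qtl = truth$name[q], detected = TRUE,
                   pos = calls$peak[best], add = calls$add[best],
                   lod = calls$lod[best],
                   cil = calls$ci_hi[best] - calls$ci_lo[best])
  })
  list(per_qtl = dplyr::bind_rows(per),
       n_false = sum(is.na(assigned)))
}

#' Summarise a set of replicate outcomes
#'
#' Power per true QTL is the percentage of replicates detecting it; the
#' false discovery rate is pooled over replicates,
#' 100 * FP / (FP + TP), where TP counts every per-QTL detection.
#' Position, effect, confidence-interval-length and LOD summaries (mean
#' and SD) are computed over detecting replicates only, as is standard
#' when power is low.
#'
#' @param outcomes list of results from [evaluate_detection()].
#' @return a `qtl_experiment_summary` list with `per_qtl` (tibble) and
#'   `fdr` (percent).
#' @export
summarize_experiment <- function(outcomes) {
  if (length(outcomes) == 0) abort("no outcomes to summarise")
  reps <- length(outcomes)
  per <- dplyr::bind_rows(lapply(outcomes, `[[`, "per_qtl"))
  fp <- sum(vapply(outcomes, `[[`, 0, "n_false"))
  tp <- sum(per$detected)
  summary <- dplyr::summarise(
    per,
    power = 100 * mean(.data$detected),
    pos_mean = mean(.data$pos[.data$detected]),
    pos_sd = sd(.data$pos[.data$detected]),
    add_mean = mean(.data$add[.data$detected]),
    add_sd = sd(.data$add[.data$detected]),
    cil_mean = mean(.data$cil[.data$detected]),
    cil_sd = sd(.data$cil[.data$detected]),
    lod_mean = mean(.data$lod[.data$detected]),
    lod_sd = sd(.data$lod[.data$detected]),
    .by = "qtl"
  )
  structure(list(per_qtl = summary,
                 fdr = if (fp + tp > 0) 100 * fp / (fp + tp) else 0,
                 n_false = fp, n_true_detections = tp, reps = reps),
            class = "qtl_experiment_summary")
}

#' @export
print.qtl_experiment_summary <- function(x, ...) {
  cat(sprintf("<qtl_experiment_summary> %d replicates, FDR %.2f%%\n",
              x$reps, x$fdr))
  print(x$per_qtl)
  invisible(x)
}

#' Run a full QTL-mapping simulation experiment
#'
#' Simulates `reps` RIL/DH populations under a catalogued genetic model,
#' restricts each to the requested map scenario, runs the ICIM scan
#' (scanning step 0.1 cM by default, as is conventional for simulation
#' studies), calls QTLs and scores them against the truth, and summarises
#' detection power, FDR and the estimate distributions.  Fully seeded and
#' reproducible; the Haldane mapping function is used throughout because
#' the simulated crossovers carry no interference.
#'
#' @param model,h2 model identifier and heritability (see
#'   [model_catalog()]).
#' @param scenario `"individual"` or `"consensus"` (see
#'   [map_scenario()]).
#' @param reps number of simulated populations.
#' @param n population size.
#' @param seed integer seed.
#' @param step scanning step in cM.
#' @param support_half_width detection window half-width in cM.
#' @param qtl_pos two-QTL positions for models II/III.
#' @return a `qtl_experiment` object; `tidy()` gives the per-QTL summary
#'   row(s), `glance()` the design plus FDR.
#' @export
run_experiment <- function(model, h2, scenario = c("individual",
                                                   "consensus"),
                           reps = 1000, n = 200, seed = NULL, step = 0.1,
                           support_half_width = 2.5,
                           qtl_pos = c(26.5, 34.5)) {
  scenario <- match.arg(scenario)
  design <- model_catalog(model, h2, n = n, qtl_pos = qtl_pos)
  settings <- scan_settings(step = step, fun = "haldane")
  if (!is.null(seed)) set.seed(seed)
  outcomes <- vector("list", reps)
  for (b in seq_len(reps)) {
    pop <- simulate_population(design)
    sc <- map_scenario(pop, scenario)
    scan <- icim_scan(sc$y, sc$geno, sc$map, settings)
    calls <- call_qtls(scan)
    outcomes[[b]] <- evaluate_detection(calls, design$qtl,
                                        support_half_width)
  }
  summ <- summarize_experiment(outcomes)
  structure(list(summary = summ, outcomes = outcomes, model = model,
                 h2 = h2, scenario = scenario, reps = reps, n = n,
                 seed = seed, step = step),
            class = "qtl_experiment")
}

#' @export
print.qtl_experiment <- function(x, ...) {
  cat(sprintf("<qtl_experiment> model %s, h2 = %g, %s map, %d reps\n",
              x$model, x$h2, x$scenario, x$reps))
  print(x$summary)
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `qtl_experiment`.
#' @param ... unused.
#' @method tidy qtl_experiment
#' @export
tidy.qtl_experiment <- function(x, ...) {
  dplyr::mutate(x$summary$per_qtl, model = x$model, h2 = x$h2,
                scenario = x$scenario, .before = 1)
}

#' @rdname run_experiment
#' @method glance qtl_experiment
#' @export
glance.qtl_experiment <- function(x, ...) {
  tibble::tibble(model = x$model, h2 = x$h2, scenario = x$scenario,
                 reps = x$reps, n = x$n,
                 power_mean = mean(x$summary$per_qtl$power),
                 fdr = x$summary$fdr)
}

#' Group QTL records into common QTLs
#'
#' Single-linkage grouping of QTL records that share the consensus-map
#' coordinate system: two records from the *same* population merge when
#' their positions are less than `max_cm` apart; records from *different*
#' populations additionally require the minimum gap between their
#' flanking-marker physical intervals to be below `max_mb` (when physical
#' coordinates are present on both; otherwise the genetic rule alone
#' applies and the group is flagged `genetic_only`).
#'
#' @param records tibble with columns `name`, `population`, `chrom`,
#'   `pos`, and optionally `phys_lo`/`phys_hi` (Mb).
#' @param max_cm genetic-distance threshold (default 20 cM, strict).
#' @param max_mb physical-distance threshold (default 25 Mb, strict).
#' @return `records` with added columns `common_group` and
#'   `genetic_only`.
#' @export
qtl_commonality <- function(records, max_cm = 20, max_mb = 25) {
  nr <- nrow(records)
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  has_phys <- all(c("phys_lo", "phys_hi") %in% names(records))
  genetic_only <- logical(nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (j <= i) next
    if (records$chrom[i] != records$chrom[j]) next
    close_cm <- abs(records$pos[i] - records$pos[j]) < max_cm
    if (!close_cm) next
    same_pop <- records$population[i] == records$population[j]
    merge <- FALSE
    if (same_pop) {
      merge <- TRUE
    } else if (has_phys && !is.na(records$phys_lo[i]) &&
               !is.na(records$phys_lo[j])) {
      gap <- max(0, max(records$phys_lo[i], records$phys_lo[j]) -
                   min(records$phys_hi[i], records$phys_hi[j]))
      merge <- gap < max_mb
    } else {
      merge <- TRUE
      genetic_only[c(i, j)] <- TRUE
    }
    if (merge) parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(nr), find, 0L)
  records$common_group <- match(root, unique(root))
  records$genetic_only <- genetic_only
  records
}

#' Flag stable QTLs
#'
#' A QTL is stable in a population when it was identified in at least
#' half of the environments tested there (detections >=
#' ceiling(environments / 2)).
#'
#' @param records tibble with columns `common_group`, `population`,
#'   `environment`.
#' @param environments_tested named vector: environments tested per
#'   population.
#' @return tibble with one row per (group, population): `n_detected`,
#'   `n_tested`, `stable`.
#' @export
stability_filter <- function(records, environments_tested) {
  out <- dplyr::summarise(records,
                          n_detected = dplyr::n_distinct(.data$environment),
                          .by = c("common_group", "population"))
  out$n_tested <- unname(environments_tested[out$population])
  out$stable <- out$n_detected >= ceiling(out$n_tested / 2)
  out
}

#' Cluster stable QTLs across traits
#'
#' Single-linkage clustering of stable QTLs (across traits, within a
#' chromosome): two QTLs join the same cluster when the gap between their
#' confidence intervals is strictly less than `max_gap` cM (overlapping
#' intervals have gap 0).
#'
#' @param records tibble with columns `chrom`, `ci_lo`, `ci_hi`.
#' @param max_gap CI-gap threshold in cM (default 15, strict).
#' @return `records` with an added `cluster` column (labelled
#'   chromosome-wise).
#' @export
cluster_qtls <- function(records, max_gap = 15) {
  nr <- nrow(records)
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (j <= i || records$chrom[i] != records$chrom[j]) next
    gap <- max(0, max(records$ci_lo[i], records$ci_lo[j]) -
                 min(records$ci_hi[i], records$ci_hi[j]))
    if (gap < max_gap) parent[find(i)] <- find(j)
  }
  root <- vapply(seq_len(nr), find, 0L)
  records$cluster <- paste0(records$chrom, "-c",
                            stats::ave(root, records$chrom,
                                       FUN = function(r)
                                         match(r, unique(r))))
  records
}

#' Predict genotypic values from stable-QTL effects
#'
#' Predicts each line's genotypic value as the intercept (typically the
#' population phenotype mean) plus the sum of additive effects times the
#' line's +1/-1 genotype codes at the stable QTLs, and counts per line
#' the loci carrying the trait-increasing allele.  Missing QTL genotypes
#' are skipped and counted in `n_missing`.
#'
#' @param x matrix n x Q of +1/-1 QTL genotype codes (`NA` allowed).
#' @param effects additive effects, length Q.
#' @param intercept scalar intercept.
#' @return tibble: `line`, `predicted`, `n_positive`, `n_missing`.
#' @export
predict_genotypic_values <- function(x, effects, intercept = 0) {
  x <- as.matrix(x)
  if (ncol(x) != length(effects))
    abort("one effect per QTL column required")
  contrib <- sweep(x, 2, effects, `*`)
  pred <- intercept + rowSums(contrib, na.rm = TRUE)
  pos_allele <- sweep(x, 2, sign(effects), `*`) == 1
  tibble::tibble(
    line = rownames(x) %||% as.character(seq_len(nrow(x))),
    predicted = pred,
    n_positive = rowSums(pos_allele, na.rm = TRUE),
    n_missing = rowSums(is.na(x))
  )
}
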