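#' Cluster-calling thresholds
#'
#' Container for the four calling criteria: a 10-kbp window is a G4
#' cluster when `pqs_count >= pqs_min`, `g4_pds_count >= g4_pds_min` and
#' `ratio <= ratio_max`; a cluster is ligand-inducible when additionally
#' `g4_k_count <= g4_k_max`. Defaults are the published criteria derived
#' from gamma-H2AX-enriched control genes.
#'
#' @param pqs_min Minimum PQS count per window (default 24).
#' @param g4_pds_min Minimum count of G4-seq (PDS condition) intervals
#'   (default 10).
#' @param ratio_max Maximum ligand/control depletion ratio (default 0.292).
#' @param g4_k_max Maximum count of G4-seq (K+ condition) intervals for
#'   the ligand-inducible subset (default 6).
#' @return An object of class `g4_thresholds`.
#' @export
g4_thresholds <- function(pqs_min = 24, g4_pds_min = 10, ratio_max = 0.292,
                          g4_k_max = 6) {
  stopifnot(pqs_min >= 0, g4_pds_min >= 0, ratio_max > 0, g4_k_max >= 0)
  structure(list(pqs_min = pqs_min, g4_pds_min = g4_pds_min,
                 ratio_max = ratio_max, g4_k_max = g4_k_max),
            class = "g4_thresholds")
}

#' @export
print.g4_thresholds <- function(x, ...) {
  cat("G4 cluster calling thresholds (per 10-kbp window):\n",
      "  PQS count          >= ", x$pqs_min, "\n",
      "  G4-seq PDS count   >= ", x$g4_pds_min, "\n",
      "  depletion ratio    <= ", format(x$ratio_max), "\n",
      "  G4-seq K+ count    <= ", x$g4_k_max, "  (ligand-inducible)\n",
      sep = "")
  invisible(x)
}

#' Join counts, depletion statistics and track counts into window features
#'
#' Builds the per-window feature table that cluster calling operates on:
#' the paired counts with ratio/fold-change/Fisher statistics
#' ([window_stats()]) plus per-window counts of PQS hits, of G4-seq
#' intervals under PDS and K+ conditions, and of TSS (all assigned by
#' start coordinate, [count_hits_per_window()]).
#'
#' @param counts Paired count table.
#' @param pqs PQS hits ([call_pqs()]), GRanges.
#' @param pds,kplus,tss Optional GRanges tracks: G4-seq under PDS, G4-seq
#'   under K+, and TSS positions. Omitted tracks yield columns of `NA`.
#' @param normalize,compute_fisher,fdr Passed to [window_stats()].
#' @return A data.frame extending the counts schema with `pqs_count`,
#'   `g4_pds_count`, `g4_k_count`, `tss_count`, `ratio`, `fold_change`,
#'   `fisher_p` and `valid` columns.
#' @export
build_window_features <- function(counts, pqs, pds = NULL, kplus = NULL,
                                  tss = NULL, normalize = FALSE,
                                  compute_fisher = TRUE, fdr = FALSE) {
  out <- window_stats(counts, normalize = normalize,
                      compute_fisher = compute_fisher, fdr = fdr)
  win <- .table_windows(counts)
  cnt <- function(track) {
    if (is.null(track)) rep(NA_integer_, length(win))
    else as.integer(count_hits_per_window(track, win))
  }
  out$pqs_count <- cnt(pqs)
  out$g4_pds_count <- cnt(pds)
  out$g4_k_count <- cnt(kplus)
  out$tss_count <- cnt(tss)
  out
}

#' Per-gene mean window features for a control gene set
#'
#' Averages window features over the 10-kbp windows overlapping each gene
#' region, giving the per-gene densities from which calling thresholds
#' are derived. The depletion ratio is averaged over valid windows only.
#'
#' @param features Window feature table ([build_window_features()]).
#' @param genes GRanges of gene regions, named (via `names()` or a `name`
#'   metadata column).
#' @return A data.frame with one row per gene: `gene`, `n_windows`,
#'   `pqs_mean`, `pds_mean`, `ratio_mean`, `k_mean`.
#' @export
gene_set_features <- function(features, genes) {
  stopifnot(is(genes, "GRanges"), length(genes) > 0)
  nms <- names(genes)
  if (is.null(nms) && !is.null(genes$name)) nms <- genes$name
  if (is.null(nms)) nms <- paste0("gene", seq_along(genes))
  win <- .table_windows(features)
  suppressWarnings(ov <- findOverlaps(genes, win, ignore.strand = TRUE))
  rows <- lapply(seq_along(genes), function(i) {
    idx <- subjectHits(ov)[queryHits(ov) == i]
    if (length(idx) == 0L) {
      stop("gene '", nms[i], "' overlaps no window")
    }
    d <- features[idx, ]
    data.frame(gene = nms[i], n_windows = length(idx),
               pqs_mean = mean(d$pqs_count),
               pds_mean = mean(d$g4_pds_count),
               ratio_mean = mean(d$ratio[d$valid]),
               k_mean = mean(d$g4_k_count))
  })
  do.call(rbind, rows)
}

## ceiling/floor with a small tolerance so fp noise in means cannot flip
## a printed criterion (e.g. 9.800000000000001 must still ceil to 10)
.ceil_tol <- function(x, tol = 1e-8) ceiling(x - tol)
.floor_tol <- function(x, tol = 1e-8) floor(x + tol)

#' Derive calling thresholds from control gene sets
#'
#' Turns the mean feature densities of a positive control set (genes with
#' ligand-induced gamma-H2AX enrichment, i.e. known G4-cluster genes) into
#' the four calling thresholds: `pqs_min` is the rounded mean PQS density,
#' `g4_pds_min` the ceiling of the mean G4-seq PDS density, `ratio_max`
#' the unrounded mean depletion ratio, and `g4_k_max` the floor of the
#' mean G4-seq K+ density. Positive-set means of (24, 9.8, 0.292, 6.2)
#' therefore give thresholds (24, 10, 0.292, 6). A negative control set
#' (gamma-H2AX-negative genes) is used only as a sanity report: a warning
#' is issued if its means do not fall on the non-cluster side of every
#' threshold.
#'
#' @param positive Per-gene feature table ([gene_set_features()]) of the
#'   positive control genes; must be non-empty.
#' @param negative Optional per-gene feature table of negative control
#'   genes.
#' @return A [g4_thresholds()] object; the positive-set means are kept in
#'   attribute `positive_means`.
#' @export
derive_thresholds <- function(positive, negative = NULL) {
  stopifnot(is.data.frame(positive))
  if (nrow(positive) == 0L) stop("positive control gene set is empty")
  m <- c(pqs = mean(positive$pqs_mean),
         pds = mean(positive$pds_mean),
         ratio = mean(positive$ratio_mean),
         k = mean(positive$k_mean))
  # without a K+ track the inducible threshold stays at its default
  k_max <- if (is.na(m[["k"]])) formals(g4_thresholds)$g4_k_max else
    .floor_tol(m[["k"]])
  th <- g4_thresholds(pqs_min = round(m[["pqs"]]),
                      g4_pds_min = .ceil_tol(m[["pds"]]),
                      ratio_max = m[["ratio"]],
                      g4_k_max = k_max)
  attr(th, "positive_means") <- m
  if (!is.null(negative) && nrow(negative) > 0L) {
    nm <- c(pqs = mean(negative$pqs_mean),
            pds = mean(negative$pds_mean),
            ratio = mean(negative$ratio_mean))
    sep <- nm[["pqs"]] < th$pqs_min && nm[["pds"]] < th$g4_pds_min &&
      nm[["ratio"]] > th$ratio_max
    if (!sep) {
      warning("negative control set means do not fall on the non-cluster ",
              "side of every threshold")
    }
    attr(th, "negative_means") <- nm
  }
  th
}

#' Call G4 clusters on 10-kbp window features
#'
#' A window is called a G4 cluster when it satisfies the conjunction of
#' all three criteria: PQS count at or above `pqs_min`, G4-seq PDS count
#' at or above `g4_pds_min`, and depletion ratio at or below `ratio_max`.
#' Invalid windows (zero control reads) are never clusters. Each
#' qualifying window is one cluster; adjacent qualifying windows are not
#' merged unless `merge_adjacent = TRUE` (exploratory use; the merged
#' version is returned in attribute `merged`).
#'
#' @param features Window feature table with `pqs_count`, `g4_pds_count`,
#'   `ratio` and `valid` columns (see [build_window_features()]).
#' @param thresholds A [g4_thresholds()] object.
#' @param merge_adjacent Also compute merged runs of adjacent qualifying
#'   windows? Default `FALSE`.
#' @return The feature table with an `is_cluster` column appended; the
#'   attribute `cluster_summary` holds the number of clusters and their
#'   mean ratio, PQS count and PDS count (see [cluster_summary()]).
#' @export
call_clusters <- function(features, thresholds, merge_adjacent = FALSE) {
  stopifnot(inherits(thresholds, "g4_thresholds"))
  need <- c("pqs_count", "g4_pds_count", "ratio", "valid")
  if (!all(need %in% names(features))) {
    stop("features table must have columns: ", paste(need, collapse = ", "))
  }
  is_cluster <- features$valid &
    features$pqs_count >= thresholds$pqs_min &
    features$g4_pds_count >= thresholds$g4_pds_min &
    features$ratio <= thresholds$ratio_max
  is_cluster[is.na(is_cluster)] <- FALSE
  out <- features
  out$is_cluster <- is_cluster
  cl <- out[is_cluster, ]
  attr(out, "cluster_summary") <- list(
    n_clusters = nrow(cl),
    mean_ratio = if (nrow(cl)) mean(cl$ratio) else NA_real_,
    mean_pqs = if (nrow(cl)) mean(cl$pqs_count) else NA_real_,
    mean_pds = if (nrow(cl)) mean(cl$g4_pds_count) else NA_real_
  )
  attr(out, "thresholds") <- thresholds
  if (merge_adjacent && nrow(cl)) {
    attr(out, "merged") <- reduce(.table_windows(cl))
  }
  out
}

#' Summary statistics of called clusters
#'
#' @param calls Output of [call_clusters()].
#' @return List with `n_clusters`, `mean_ratio`, `mean_pqs`, `mean_pds`.
#' @export
cluster_summary <- function(calls) {
  s <- attr(calls, "cluster_summary")
  if (is.null(s)) stop("not a call_clusters() result")
  s
}

#' Extract ligand-inducible G4 clusters
#'
#' A called cluster is ligand-inducible when it carries at most
#' `g4_k_max` G4-seq intervals from the K+ (no-ligand) condition, i.e.
#' its quadruplexes fold mainly when a ligand stabilises them.
#'
#' @param calls Output of [call_clusters()] with a `g4_k_count` column.
#' @param thresholds A [g4_thresholds()] object (uses `g4_k_max`).
#' @return The subset of rows that are ligand-inducible clusters, with an
#'   `is_ligand_inducible` column (all `TRUE`).
#' @export
extract_ligand_inducible <- function(calls, thresholds) {
  stopifnot(inherits(thresholds, "g4_thresholds"),
            "g4_k_count" %in% names(calls),
            "is_cluster" %in% names(calls))
  flag <- calls$is_cluster & calls$g4_k_count <= thresholds$g4_k_max
  flag[is.na(flag)] <- FALSE
  out <- calls[flag, ]
  if (nrow(out)) out$is_ligand_inducible <- TRUE
  out
}

#' TSS-overlap enrichment of called clusters
#'
#' Counts TSS per window (a TSS belongs to the half-open window containing
#' its start coordinate; a TSS on a boundary belongs to the downstream
#' window) and compares the fraction of clusters containing at least one
#' TSS with the genome-wide fraction of windows doing so, with an odds
#' ratio and two-sided Fisher's exact p on the 2x2 cluster-by-has-TSS
#' table.
#'
#' @param calls Output of [call_clusters()].
#' @param tss GRanges of TSS positions (points; intervals are reduced to
#'   their start).
#' @return A list of class `g4_tss_enrichment`: `calls` (input with
#'   `tss_count` and `has_tss` columns refreshed), `n_clusters`,
#'   `cluster_fraction`, `genome_fraction`, `odds_ratio`, `fisher_p`.
#'   With empty TSS input both fractions are 0 (warning); a degenerate
#'   2x2 table gives `NA` odds ratio with a warning.
#' @export
tss_enrichment <- function(calls, tss) {
  stopifnot(is(tss, "GRanges"), "is_cluster" %in% names(calls))
  win <- .table_windows(calls)
  if (length(tss) == 0L) {
    warning("empty TSS input; fractions are 0")
    tss_count <- integer(length(win))
  } else {
    tss_count <- count_hits_per_window(tss, win)
  }
  calls$tss_count <- as.integer(tss_count)
  calls$has_tss <- tss_count >= 1L
  cl <- calls$is_cluster
  cluster_fraction <- if (any(cl)) mean(calls$has_tss[cl]) else NA_real_
  genome_fraction <- mean(calls$has_tss)
  tab <- matrix(c(sum(cl & calls$has_tss), sum(cl & !calls$has_tss),
                  sum(!cl & calls$has_tss), sum(!cl & !calls$has_tss)),
                nrow = 2, byrow = TRUE)
  odds_ratio <- NA_real_
  fisher_p <- NA_real_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    if (length(tss) > 0L) {
      warning("degenerate cluster-by-TSS table; odds ratio undefined")
    }
    if (sum(tab) > 0) fisher_p <- 1
  } else {
    ft <- fisher.test(tab)
    odds_ratio <- unname(ft$estimate)
    fisher_p <- ft$p.value
  }
  structure(list(calls = calls,
                 n_clusters = sum(cl),
                 cluster_fraction = cluster_fraction,
                 genome_fraction = genome_fraction,
                 odds_ratio = odds_ratio,
                 fisher_p = fisher_p),
            class = "g4_tss_enrichment")
}

#' @export
print.g4_tss_enrichment <- function(x, ...) {
  cat("TSS-overlap enrichment of G4 clusters\n",
      sprintf("  clusters with >=1 TSS: %.1f%% of %d\n",
              100 * x$cluster_fraction, x$n_clusters),
      sprintf("  genome-wide windows with >=1 TSS: %.1f%%\n",
              100 * x$genome_fraction),
      sprintf("  odds ratio %.2f, Fisher p = %.3g\n",
              x$odds_ratio, x$fisher_p),
      sep = "")
  invisible(x)
}

#' Compare cluster calls with planted simulator truth
#'
#' Window-level recall and precision of the called set against the
#' windows overlapping planted clusters.
#'
#' @param calls Output of [call_clusters()].
#' @param truth Simulator truth ([simulate_genome()]).
#' @return List with `recall`, `precision`, `n_true`, `n_called`,
#'   `n_overlap`.
#' @export
evaluate_calls <- function(calls, truth) {
  win <- .table_windows(calls)
  suppressWarnings(
    truth_win <- overlapsAny(win, truth$planted_clusters,
                             ignore.strand = TRUE)
  )
  pred <- calls$is_cluster
  n_overlap <- sum(truth_win & pred)
  list(recall = if (sum(truth_win)) n_overlap / sum(truth_win) else NA_real_,
       precision = if (sum(pred)) n_overlap / sum(pred) else NA_real_,
       n_true = sum(truth_win), n_called = sum(pred),
       n_overlap = n_overlap)
}
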