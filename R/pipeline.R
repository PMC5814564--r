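#' Run the full G4-cluster detection pipeline
#'
#' Chains the analysis stages: PQS scanning of the reference, read
#' binning of both libraries (when reads rather than a count table are
#' supplied), per-window depletion statistics, threshold derivation from
#' control gene sets (or the published defaults), cluster calling,
#' ligand-inducible extraction and TSS enrichment. With `outdir` set, all
#' tables and browser tracks are written together with a machine-readable
#' run manifest (parameters, package/R versions, output checksums) and a
#' human-readable summary. Identical inputs and parameters give identical
#' outputs.
#'
#' @param genome Reference: FASTA path or [Biostrings::DNAStringSet].
#' @param reads_control,reads_ligand Mapped reads per library: GRanges or
#'   BAM/SAM/BED path. Ignored when `counts` is given.
#' @param counts Optional precomputed paired count table
#'   (`chrom start end count_control count_ligand`) or TSV path.
#' @param pds,kplus,tss Optional G4-seq PDS / G4-seq K+ / TSS tracks:
#'   GRanges or BED paths. Without `tss` the enrichment stage is skipped
#'   and flagged in the result.
#' @param positive_genes,negative_genes Optional control gene sets
#'   (GRanges or BED paths) for threshold derivation; without them
#'   `thresholds` (default: the published criteria) is used directly.
#' @param thresholds A [g4_thresholds()] override.
#' @param bin Window size for calling (default 10000).
#' @param g4_window,g4_threshold G4Hunter parameters (defaults 25, 1.2).
#' @param normalize Library-size normalisation for `fold_change`.
#' @param compute_fisher Compute per-window Fisher p-values.
#' @param truth Optional simulator truth: adds recall/precision
#'   evaluation.
#' @param outdir Optional output directory (created if needed).
#' @return A list bundle: `windows`, `features`, `thresholds`, `calls`,
#'   `summary`, `inducible`, `enrichment` (or `NULL` with
#'   `tss_skipped = TRUE`), `evaluation` (if `truth`), `outputs` (paths,
#'   if written).
#' @export
run_g4_pipeline <- function(genome,
                            reads_control = NULL, reads_ligand = NULL,
                            counts = NULL,
                            pds = NULL, kplus = NULL, tss = NULL,
                            positive_genes = NULL, negative_genes = NULL,
                            thresholds = NULL,
                            bin = 10000L,
                            g4_window = 25L, g4_threshold = 1.2,
                            normalize = FALSE, compute_fisher = TRUE,
                            truth = NULL, outdir = NULL) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  stopifnot(is(genome, "DNAStringSet"))
  as_track <- function(x) {
    if (is.null(x) || is(x, "GRanges")) x else read_bed(x)
  }
  pds <- as_track(pds); kplus <- as_track(kplus); tss <- as_track(tss)
  positive_genes <- as_track(positive_genes)
  negative_genes <- as_track(negative_genes)

  windows <- make_windows(setNames(width(genome), names(genome)), bin)

  if (is.null(counts)) {
    if (is.null(reads_control) || is.null(reads_ligand)) {
      stop("supply either `counts` or both read inputs")
    }
    counts <- window_counts(count_reads(reads_control, windows),
                            count_reads(reads_ligand, windows))
  } else if (is.character(counts)) {
    counts <- read_counts_tsv(counts)
  }
  .check_counts(counts)

  pqs <- call_pqs(genome, window = g4_window, threshold = g4_threshold)
  features <- build_window_features(counts, pqs, pds = pds, kplus = kplus,
                                    tss = tss, normalize = normalize,
                                    compute_fisher = compute_fisher)

  if (is.null(thresholds)) {
    if (!is.null(positive_genes)) {
      pos <- gene_set_features(features, positive_genes)
      neg <- if (!is.null(negative_genes)) {
        gene_set_features(features, negative_genes)
      }
      thresholds <- derive_thresholds(pos, neg)
    } else {
      thresholds <- g4_thresholds()
    }
  }

  calls <- call_clusters(features, thresholds)
  inducible <- if (!is.null(kplus)) {
    extract_ligand_inducible(calls, thresholds)
  }
  tss_skipped <- is.null(tss)
  enrichment <- if (!tss_skipped) tss_enrichment(calls, tss)
  evaluation <- if (!is.null(truth)) evaluate_calls(calls, truth)

  bundle <- list(windows = windows, pqs = pqs, features = features,
                 thresholds = thresholds, calls = calls,
                 summary = cluster_summary(calls),
                 inducible = inducible,
                 enrichment = enrichment, tss_skipped = tss_skipped,
                 evaluation = evaluation)
  if (!is.null(outdir)) {
    bundle$outputs <- .write_pipeline_outputs(
      bundle, counts, outdir,
      params = list(bin = bin, g4_window = g4_window,
                    g4_threshold = g4_threshold, normalize = normalize,
                    compute_fisher = compute_fisher))
  }
  bundle
}

.write_pipeline_outputs <- function(bundle, counts, outdir, params) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(counts = p("window_counts.tsv"),
             features = p("window_features.tsv"),
             pqs = p("pqs.bed"),
             clusters_tsv = p("clusters.tsv"),
             clusters_bed = p("clusters.bed"),
             ratio_bedgraph = p("ratio.bedGraph"),
             ratio_igv = p("ratio.igv"),
             manifest = p("manifest.json"),
             summary = p("summary.txt"))
  write_counts_tsv(counts, paths[["counts"]])
  write_counts_tsv(bundle$features, paths[["features"]])
  write_pqs_bed(bundle$pqs, paths[["pqs"]])
  cl <- bundle$calls[bundle$calls$is_cluster, ]
  write_counts_tsv(cl, paths[["clusters_tsv"]])
  write_bed(.table_windows(cl), paths[["clusters_bed"]])
  write_bedgraph(bundle$features, "ratio", paths[["ratio_bedgraph"]],
                 name = "ligand_control_ratio")
  write_igv_track(bundle$features, "ratio", paths[["ratio_igv"]],
                  name = "ligand_control_ratio", feature = "ratio")

  s <- bundle$summary
  lines <- c(
    "G4 cluster detection summary",
    sprintf("windows: %d of %d bp", length(bundle$windows), params$bin),
    sprintf("clusters called: %d", s$n_clusters),
    sprintf("mean cluster ratio / PQS / PDS: %.3f / %.1f / %.1f",
            s$mean_ratio, s$mean_pqs, s$mean_pds),
    sprintf("ligand-inducible clusters: %s",
            if (is.null(bundle$inducible)) "not computed"
            else nrow(bundle$inducible)),
    if (bundle$tss_skipped) "TSS stage: skipped (no TSS input)"
    else sprintf("clusters with TSS: %.1f%% vs %.1f%% genome-wide (p=%.3g)",
                 100 * bundle$enrichment$cluster_fraction,
                 100 * bundle$enrichment$genome_fraction,
                 bundle$enrichment$fisher_p),
    if (!is.null(bundle$evaluation))
      sprintf("planted-truth recall %.3f precision %.3f",
              bundle$evaluation$recall, bundle$evaluation$precision)
  )
  writeLines(lines, paths[["summary"]])

  made <- paths[names(paths) != "manifest"]
  manifest <- list(
    package = "g4wga",
    version = as.character(packageVersion("g4wga")),
    r_version = R.version.string,
    parameters = params,
    thresholds = unclass(bundle$thresholds),
    outputs = as.list(setNames(unname(md5sum(made)), names(made)))
  )
  write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  paths
}
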