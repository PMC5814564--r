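#' Configuration for a synthetic ligand-stalled WGA experiment
#'
#' Parameters of the synthetic-data generator. Defaults describe the
#' reference study conditions used throughout the package's tests: a
#' 20-Mbp genome carrying 50 planted 10-kbp PQS clusters of 40 motifs
#' each over a 2.4-per-10-kbp background, sequenced to a mean window
#' depth of 2000 reads with negative-binomial overdispersion, with
#' ligand-library coverage depleted to 0.13 of the control inside
#' clusters, K+ G4 tracks subsampled from the PDS track, and TSS placed
#' in 39% of clusters versus an 0.087-per-window background.
#'
#' @param genome_length Total genome length in bases.
#' @param n_chromosomes Number of chromosomes (lengths near-equal).
#' @param gc_content GC fraction of the i.i.d. background sequence.
#' @param n_clusters Number of planted PQS clusters.
#' @param cluster_length Cluster (and counting window) length in bases.
#' @param pqs_per_cluster PQS motifs planted per cluster.
#' @param background_pqs_rate Expected planted PQS per 10 kbp outside
#'   clusters.
#' @param mean_depth Expected control-library reads per window.
#' @param dispersion Negative-binomial size parameter (> 0); large values
#'   approach Poisson counts.
#' @param depletion_in_cluster Multiplier on the ligand-library mean in
#'   windows overlapping a planted cluster (< 1 for a meaningful test).
#' @param depletion_outside Multiplier outside clusters.
#' @param fraction_kplus Fraction of a non-inducible cluster's PQS (and of
#'   background PQS) retained in the K+ surrogate track.
#' @param prop_inducible Fraction of clusters designated ligand-inducible.
#' @param inducible_kplus_sites K+ sites retained in a ligand-inducible
#'   cluster (at most the inducible-extraction threshold of 6).
#' @param tss_in_cluster_prob Probability a cluster receives a TSS.
#' @param tss_background_rate Expected TSS per 10 kbp outside clusters.
#' @param read_length Read length for [simulate_read_intervals()].
#' @param seed Integer RNG seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(genome_length = 2e7,
                       n_chromosomes = 2L,
                       gc_content = 0.4,
                       n_clusters = 50L,
                       cluster_length = 10000L,
                       pqs_per_cluster = 40L,
                       background_pqs_rate = 2.4,
                       mean_depth = 2000,
                       dispersion = 20,
                       depletion_in_cluster = 0.13,
                       depletion_outside = 1,
                       fraction_kplus = 0.5,
                       prop_inducible = 0.2,
                       inducible_kplus_sites = 3L,
                       tss_in_cluster_prob = 0.39,
                       tss_background_rate = 0.087,
                       read_length = 150L,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              gc_content = gc_content, n_clusters = n_clusters,
              cluster_length = cluster_length,
              pqs_per_cluster = pqs_per_cluster,
              background_pqs_rate = background_pqs_rate,
              mean_depth = mean_depth, dispersion = dispersion,
              depletion_in_cluster = depletion_in_cluster,
              depletion_outside = depletion_outside,
              fraction_kplus = fraction_kplus,
              prop_inducible = prop_inducible,
              inducible_kplus_sites = inducible_kplus_sites,
              tss_in_cluster_prob = tss_in_cluster_prob,
              tss_background_rate = tss_background_rate,
              read_length = read_length, seed = seed)
  stopifnot(genome_length > 0, n_chromosomes >= 1,
            gc_content > 0, gc_content < 1,
            n_clusters >= 0, cluster_length > 0, pqs_per_cluster >= 0,
            background_pqs_rate >= 0, mean_depth > 0, dispersion > 0,
            depletion_in_cluster > 0, depletion_outside > 0,
            fraction_kplus >= 0, fraction_kplus <= 1,
            prop_inducible >= 0, prop_inducible <= 1,
            inducible_kplus_sites >= 0,
            tss_in_cluster_prob >= 0, tss_in_cluster_prob <= 1,
            tss_background_rate >= 0, read_length > 0, seed == round(seed),
            n_clusters * cluster_length < genome_length)
  structure(cfg, class = "sim_config")
}

## one canonical PQS motif: four G-runs of length 3-4 separated by 1-3 nt
## A/T loops, so the motif always clears the default G4Hunter call
## threshold within a 25-nt window; reverse-complemented for minus strand
.random_pqs_motif <- function(minus_strand) {
  runs <- sample(3:4, 4L, replace = TRUE)
  loops <- sample(1:3, 3L, replace = TRUE)
  parts <- character(7L)
  parts[c(1, 3, 5, 7)] <- strrep("G", runs)
  parts[c(2, 4, 6)] <- vapply(loops, function(k) {
    paste(sample(c("A", "T"), k, replace = TRUE), collapse = "")
  }, character(1L))
  motif <- paste(parts, collapse = "")
  if (minus_strand) motif <- as.character(reverseComplement(DNAString(motif)))
  motif
}

## place n motifs in [start0, start0+width-1] (1-based), one per equal
## slot at a random offset: non-overlapping by construction
.place_in_slots <- function(start0, width, lens, what) {
  n <- length(lens)
  if (n == 0L) return(integer(0))
  slot <- width %/% n
  if (slot < max(lens)) {
    stop(what, " is too small for ", n, " motifs of up to ",
         max(lens), " bases (slot width ", slot, ")")
  }
  offsets <- vapply(lens, function(l) sample.int(slot - l + 1L, 1L) - 1L, 1L)
  start0 + (seq_len(n) - 1L) * slot + offsets
}

#' Simulate a genome with planted PQS clusters
#'
#' Generates i.i.d. background sequence at the configured GC content,
#' plants `n_clusters` clusters of `pqs_per_cluster` canonical PQS motifs
#' (G3-4 runs, 1-3 nt loops; random strand) in randomly chosen 10-kbp
#' windows aligned to the analysis grid, and sprinkles background motifs
#' at `background_pqs_rate` per 10 kbp elsewhere. Every insertion is
#' recorded in the returned truth. Identical configuration (including
#' seed) gives byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `truth`, a list of class `sim_truth` with elements `chrom_lengths`,
#'   `planted_clusters` (GRanges, `inducible` metadata column),
#'   `planted_pqs` (stranded GRanges, `cluster` metadata column: cluster
#'   index or `NA` for background) and `expected_ratio_map` (per-window
#'   expected ligand/control mean ratio).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base_len <- config$genome_length %/% config$n_chromosomes
  lens <- rep(base_len, config$n_chromosomes)
  lens[config$n_chromosomes] <- config$genome_length -
    base_len * (config$n_chromosomes - 1L)
  names(lens) <- paste0("chr", seq_len(config$n_chromosomes))

  win <- suppressWarnings(make_windows(lens, config$cluster_length))
  full <- width(win) == config$cluster_length
  if (config$n_clusters > sum(full)) {
    stop("genome too short for ", config$n_clusters, " clusters")
  }
  cl_idx <- sort(sample(which(full), config$n_clusters))
  clusters <- win[cl_idx]
  mcols(clusters) <- NULL
  clusters$inducible <- as.logical(
    rbinom(length(clusters), 1L, config$prop_inducible))

  ## plan motif insertions per window
  pqs_chrom <- character(0); pqs_start <- integer(0)
  pqs_len <- integer(0); pqs_strand <- character(0)
  pqs_cluster <- integer(0); pqs_motif <- character(0)
  is_cluster_win <- seq_along(win) %in% cl_idx
  cluster_of <- match(seq_along(win), cl_idx)
  for (i in seq_along(win)) {
    if (is_cluster_win[i]) {
      n <- config$pqs_per_cluster
      what <- paste0("cluster ", cluster_of[i], " (",
                     seqnames(win)[i], ":", start(win)[i] - 1L, "-",
                     end(win)[i], ")")
    } else {
      lambda <- config$background_pqs_rate * width(win)[i] / 1e4
      n <- rpois(1L, lambda)
      n <- min(n, width(win)[i] %/% 30L)  # cap: keep slots motif-sized
      what <- "background window"
    }
    if (n == 0L) next
    minus <- as.logical(rbinom(n, 1L, 0.5))
    motifs <- vapply(minus, .random_pqs_motif, character(1L))
    starts <- .place_in_slots(start(win)[i], width(win)[i],
                              nchar(motifs), what)
    pqs_chrom <- c(pqs_chrom, rep(as.character(seqnames(win)[i]), n))
    pqs_start <- c(pqs_start, starts)
    pqs_len <- c(pqs_len, nchar(motifs))
    pqs_strand <- c(pqs_strand, ifelse(minus, "-", "+"))
    pqs_cluster <- c(pqs_cluster,
                     rep(if (is_cluster_win[i]) cluster_of[i] else
                       NA_integer_, n))
    pqs_motif <- c(pqs_motif, motifs)
  }

  ## background sequence, then substitute motifs in place
  bases <- utf8ToInt("ACGT")
  p <- c((1 - config$gc_content) / 2, config$gc_content / 2,
         config$gc_content / 2, (1 - config$gc_content) / 2)
  genome <- DNAStringSet(vapply(names(lens), function(ch) {
    s <- intToUtf8(bases[sample.int(4L, lens[[ch]], replace = TRUE,
                                    prob = p)])
    sel <- pqs_chrom == ch
    if (any(sel)) {
      s <- as.character(replaceAt(
        DNAString(s),
        at = IRanges(pqs_start[sel], width = pqs_len[sel]),
        value = DNAStringSet(pqs_motif[sel])))
    }
    s
  }, character(1L)))

  planted_pqs <- GRanges(pqs_chrom, IRanges(pqs_start, width = pqs_len),
                         strand = pqs_strand, cluster = pqs_cluster,
                         seqlengths = lens)
  planted_pqs <- sort(planted_pqs, ignore.strand = TRUE)

  d <- ifelse(is_cluster_win, config$depletion_in_cluster,
              config$depletion_outside)
  expected_ratio_map <- data.frame(
    chrom = as.character(seqnames(win)), start = start(win) - 1L,
    end = end(win), expected_ratio = d)

  truth <- structure(list(chrom_lengths = lens,
                          planted_clusters = clusters,
                          planted_pqs = planted_pqs,
                          expected_ratio_map = expected_ratio_map),
                     class = "sim_truth")
  list(genome = genome, truth = truth)
}

#' Simulate paired per-window read counts under a depletion model
#'
#' For every window of `cluster_length` tiling the genome, draws the
#' control count from NB(mean = `mean_depth`, size = `dispersion`) and
#' the ligand count from NB(mean = `mean_depth * d(w)`) where `d(w)` is
#' `depletion_in_cluster` if the window overlaps a planted cluster and
#' `depletion_outside` otherwise: the window-level signature of
#' polymerase stalling on ligand-stabilised quadruplexes.
#'
#' @param truth Simulator truth ([simulate_genome()]).
#' @param config The same [sim_config()].
#' @return A data.frame `chrom, start, end, count_control, count_ligand`
#'   (0-based half-open) with `total_control`/`total_ligand` attributes.
#' @export
simulate_window_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  win <- suppressWarnings(make_windows(truth$chrom_lengths,
                                       config$cluster_length))
  suppressWarnings(
    in_cluster <- overlapsAny(win, truth$planted_clusters,
                              ignore.strand = TRUE)
  )
  d <- ifelse(in_cluster, config$depletion_in_cluster,
              config$depletion_outside)
  scale <- width(win) / config$cluster_length  # truncated last windows
  mu_c <- config$mean_depth * scale
  mu_l <- config$mean_depth * d * scale
  out <- data.frame(
    chrom = as.character(seqnames(win)),
    start = start(win) - 1L,
    end = end(win),
    count_control = rnbinom(length(win), size = config$dispersion,
                            mu = mu_c),
    count_ligand = rnbinom(length(win), size = config$dispersion,
                           mu = mu_l)
  )
  attr(out, "total_control") <- sum(out$count_control)
  attr(out, "total_ligand") <- sum(out$count_ligand)
  out
}

#' Simulate surrogate G4-seq and TSS tracks
#'
#' The PDS-condition track contains every planted PQS. The K+-condition
#' track is a per-cluster subsample of it: ligand-inducible clusters
#' retain `inducible_kplus_sites` sites (at or below the inducible
#' extraction threshold), other clusters retain
#' `round(fraction_kplus * n)` sites, and background PQS are retained
#' independently with probability `fraction_kplus`; the K+ track is a
#' subset of the PDS track by construction. TSS are placed in each
#' cluster with probability `tss_in_cluster_prob` and at
#' `tss_background_rate` per 10 kbp elsewhere.
#'
#' @param truth Simulator truth ([simulate_genome()]).
#' @param config The same [sim_config()].
#' @return List of GRanges: `pds`, `kplus`, `tss` (width-1 points).
#' @export
simulate_tracks <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  pds <- truth$planted_pqs
  keep <- logical(length(pds))
  cl <- pds$cluster
  for (i in seq_along(truth$planted_clusters)) {
    idx <- which(!is.na(cl) & cl == i)
    n <- length(idx)
    if (n == 0L) next
    k <- if (truth$planted_clusters$inducible[i]) {
      min(config$inducible_kplus_sites, n)
    } else {
      round(config$fraction_kplus * n)
    }
    if (k > 0L) keep[sample(idx, k)] <- TRUE
  }
  bg <- which(is.na(cl))
  if (length(bg)) {
    keep[bg] <- as.logical(rbinom(length(bg), 1L, config$fraction_kplus))
  }
  kplus <- pds[keep]

  ## TSS: clusters first, then background windows
  win <- suppressWarnings(make_windows(truth$chrom_lengths,
                                       config$cluster_length))
  suppressWarnings(
    in_cluster <- overlapsAny(win, truth$planted_clusters,
                              ignore.strand = TRUE)
  )
  tss_chrom <- character(0); tss_pos <- integer(0)
  clu <- truth$planted_clusters
  got <- as.logical(rbinom(length(clu), 1L, config$tss_in_cluster_prob))
  if (any(got)) {
    pos <- start(clu)[got] +
      vapply(width(clu)[got], function(w) sample.int(w, 1L) - 1L, 1L)
    tss_chrom <- c(tss_chrom, as.character(seqnames(clu))[got])
    tss_pos <- c(tss_pos, pos)
  }
  bg_win <- win[!in_cluster]
  nb <- rpois(length(bg_win),
              config$tss_background_rate * width(bg_win) / 1e4)
  if (any(nb > 0)) {
    rep_i <- rep(seq_along(bg_win), nb)
    pos <- start(bg_win)[rep_i] +
      vapply(width(bg_win)[rep_i], function(w) sample.int(w, 1L) - 1L, 1L)
    tss_chrom <- c(tss_chrom, as.character(seqnames(bg_win))[rep_i])
    tss_pos <- c(tss_pos, pos)
  }
  tss <- sort(GRanges(tss_chrom, IRanges(tss_pos, width = 1L),
                      seqlengths = truth$chrom_lengths))
  list(pds = pds, kplus = kplus, tss = tss)
}

#' Emit per-read intervals realising a window-count table
#'
#' For each window and library, emits `count` reads of `read_length`
#' bases whose start coordinates are uniform within the window (reads may
#' extend into the next window; assignment by 5' start keeps counts
#' exact). Exercises the SAM/BAM/BED read-counting path of
#' [count_reads()] against known per-window totals.
#'
#' @param counts Window-count table ([simulate_window_counts()]).
#' @param truth Simulator truth (chromosome lengths).
#' @param config The same [sim_config()].
#' @return List of GRanges read intervals: `control`, `ligand`.
#' @export
simulate_read_intervals <- function(counts, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  .check_counts(counts)
  set.seed(config$seed + 3L)
  lens <- truth$chrom_lengths
  emit <- function(n_per_win) {
    rep_i <- rep(seq_len(nrow(counts)), n_per_win)
    w <- counts$end[rep_i] - counts$start[rep_i]
    starts <- counts$start[rep_i] + floor(runif(length(rep_i)) * w) + 1L
    ends <- pmin(starts + config$read_length - 1L,
                 lens[counts$chrom[rep_i]])
    GRanges(counts$chrom[rep_i], IRanges(starts, ends),
            seqlengths = lens)
  }
  list(control = emit(counts$count_control),
       ligand = emit(counts$count_ligand))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_window_counts()], [simulate_tracks()] and optionally
#' [simulate_read_intervals()].
#'
#' @param config A [sim_config()].
#' @param emit_reads Also emit per-read intervals? Default `FALSE`.
#' @return List with `genome`, `truth`, `counts`, `tracks` and (if
#'   requested) `reads`.
#' @export
simulate_g4_dataset <- function(config, emit_reads = FALSE) {
  g <- simulate_genome(config)
  counts <- simulate_window_counts(g$truth, config)
  tracks <- simulate_tracks(g$truth, config)
  reads <- if (emit_reads) {
    simulate_read_intervals(counts, g$truth, config)
  }
  list(genome = g$genome, truth = g$truth, counts = counts,
       tracks = tracks, reads = reads)
}
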