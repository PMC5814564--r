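small_cfg <- function(...) {
  sim_config(genome_length = 1e6, n_chromosomes = 2, n_clusters = 5,
             mean_depth = 500, seed = 42, ...)
}

test_that("identical configuration gives byte-identical output", {
  cfg <- small_cfg()
  a <- simulate_g4_dataset(cfg, emit_reads = TRUE)
  b <- simulate_g4_dataset(cfg, emit_reads = TRUE)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$expected_ratio_map, b$truth$expected_ratio_map)
  expect_identical(as.data.frame(a$truth$planted_pqs),
                   as.data.frame(b$truth$planted_pqs))
  expect_identical(a$counts, b$counts)
  expect_identical(as.data.frame(a$tracks$kplus),
                   as.data.frame(b$tracks$kplus))
  expect_identical(as.data.frame(a$reads$ligand),
                   as.data.frame(b$reads$ligand))
  # and the FASTA serialisation itself round-trips identically
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(a$genome, f1)
  write_genome_fasta(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("nothing is planted when nothing is requested", {
  cfg <- sim_config(genome_length = 2e5, n_clusters = 0,
                    background_pqs_rate = 0, mean_depth = 100, seed = 1)
  g <- simulate_genome(cfg)
  expect_length(g$truth$planted_pqs, 0)
  expect_length(g$truth$planted_clusters, 0)
})

test_that("planted clusters are disjoint and contain their PQS", {
  g <- simulate_genome(small_cfg())
  cl <- g$truth$planted_clusters
  expect_length(cl, 5)
  expect_false(any(GenomicRanges::countOverlaps(cl, cl) > 1))
  pqs <- g$truth$planted_pqs
  in_cl <- !is.na(pqs$cluster)
  hits <- GenomicRanges::findOverlaps(pqs[in_cl], cl, type = "within",
                                      ignore.strand = TRUE)
  expect_equal(S4Vectors::queryHits(hits), seq_len(sum(in_cl)))
  expect_equal(S4Vectors::subjectHits(hits), pqs$cluster[in_cl])
})

test_that("scanning the simulated genome recovers the planted density", {
  g <- simulate_genome(small_cfg())
  hits <- call_pqs(g$genome)
  per_cluster <- count_hits_per_window(hits, g$truth$planted_clusters)
  expect_true(all(per_cluster >= 35))
})

test_that("a cluster too small for the requested motif density errors", {
  cfg <- small_cfg(cluster_length = 300, pqs_per_cluster = 40)
  expect_error(simulate_genome(cfg), "cluster 1")
})

# truth built directly (no sequence needed to test the count model)
manual_truth <- function(chrom_lengths, clusters = GenomicRanges::GRanges()) {
  structure(list(chrom_lengths = chrom_lengths,
                 planted_clusters = clusters),
            class = "sim_truth")
}

test_that("counts reproduce the depletion model", {
  # no depletion anywhere: mean(ligand)/mean(control) is 1 within 3 SE
  cfg0 <- sim_config(genome_length = 4e6, n_clusters = 0, mean_depth = 500,
                     depletion_in_cluster = 1, depletion_outside = 1,
                     seed = 5)
  counts <- simulate_window_counts(manual_truth(c(chr1 = 4e6)), cfg0)
  n <- nrow(counts)
  rom <- mean(counts$count_ligand) / mean(counts$count_control)
  # delta-method standard error of the ratio of means
  se <- rom * sqrt(var(counts$count_ligand) / (n * mean(counts$count_ligand)^2) +
                     var(counts$count_control) / (n * mean(counts$count_control)^2))
  expect_lt(abs(rom - 1), 3 * se)

  # 200 cluster windows at depth 5000, depletion 0.13: mean cluster-window
  # ratio lands in the band implied by E[L/C] = d (1 + CV^2)
  cfg <- sim_config(genome_length = 2.2e7, n_clusters = 200,
                    mean_depth = 5000, seed = 6)
  clusters <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, by = 20000, length.out = 200),
                             width = 10000))
  truth <- manual_truth(c(chr1 = 2.2e7 / 2, chr2 = 2.2e7 / 2), clusters)
  counts <- simulate_window_counts(truth, cfg)
  win <- GenomicRanges::GRanges(counts$chrom,
                                IRanges::IRanges(counts$start + 1, counts$end))
  in_cl <- IRanges::overlapsAny(win, clusters)
  expect_equal(sum(in_cl), 200)
  mr <- mean(counts$count_ligand[in_cl] / counts$count_control[in_cl])
  expect_gt(mr, 0.11)
  expect_lt(mr, 0.15)
})

test_that("the expected-ratio map marks exactly the cluster windows", {
  g <- simulate_genome(small_cfg())
  erm <- g$truth$expected_ratio_map
  win <- GenomicRanges::GRanges(erm$chrom,
                                IRanges::IRanges(erm$start + 1, erm$end))
  in_cl <- IRanges::overlapsAny(win, g$truth$planted_clusters)
  expect_true(all(erm$expected_ratio[in_cl] == 0.13))
  expect_true(all(erm$expected_ratio[!in_cl] == 1))
})

test_that("large dispersion approaches Poisson counts", {
  cfg <- sim_config(genome_length = 2e6, n_clusters = 0, mean_depth = 500,
                    dispersion = 1e8, seed = 7)
  counts <- simulate_window_counts(manual_truth(c(chr1 = 2e6)), cfg)
  vm <- var(counts$count_control) / mean(counts$count_control)
  expect_gt(vm, 0.8)
  expect_lt(vm, 1.2)
})

test_that("background count model is calibrated to mean_depth", {
  # >= 10,000 background windows; empirical mean within 2% of mean_depth
  cfg <- sim_config(genome_length = 5.5e6, cluster_length = 500,
                    n_clusters = 0, mean_depth = 2000, seed = 8)
  counts <- simulate_window_counts(manual_truth(c(chr1 = 5.5e6)), cfg)
  full <- counts$end - counts$start == 500
  expect_gte(sum(full), 10000)
  expect_lt(abs(mean(counts$count_control[full]) - 2000) / 2000, 0.02)
})

test_that("K+ track is a subset of the PDS track", {
  cfg <- small_cfg()
  sim <- simulate_g4_dataset(cfg)
  expect_lte(length(sim$tracks$kplus), length(sim$tracks$pds))
  ov <- GenomicRanges::findOverlaps(sim$tracks$kplus, sim$tracks$pds,
                                    type = "equal")
  expect_equal(length(unique(S4Vectors::queryHits(ov))),
               length(sim$tracks$kplus))
})

test_that("fraction_kplus = 1 with no inducible clusters gives identity", {
  cfg <- small_cfg(fraction_kplus = 1, prop_inducible = 0)
  g <- simulate_genome(cfg)
  tr <- simulate_tracks(g$truth, cfg)
  expect_identical(as.data.frame(tr$kplus), as.data.frame(tr$pds))
})

test_that("fraction_kplus = 0 makes every cluster ligand-inducible", {
  cfg <- small_cfg(fraction_kplus = 0, prop_inducible = 0,
                   background_pqs_rate = 0)
  sim <- simulate_g4_dataset(cfg)
  pqs <- call_pqs(sim$genome)
  feats <- build_window_features(sim$counts, pqs, pds = sim$tracks$pds,
                                 kplus = sim$tracks$kplus,
                                 compute_fisher = FALSE)
  calls <- call_clusters(feats, g4_thresholds())
  ind <- extract_ligand_inducible(calls, g4_thresholds())
  expect_equal(nrow(ind), sum(calls$is_cluster))
  expect_gt(nrow(ind), 0)
})

test_that("emitted read intervals reproduce the window counts exactly", {
  cfg <- small_cfg()
  sim <- simulate_g4_dataset(cfg, emit_reads = TRUE)
  win <- make_windows(sim$truth$chrom_lengths, cfg$cluster_length)
  recounted <- count_reads(sim$reads$control, win)
  expect_equal(recounted$count, sim$counts$count_control)
  expect_equal(attr(recounted, "unassigned"), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gc_content = 1.2))
  expect_error(sim_config(depletion_in_cluster = 0))
  expect_error(sim_config(genome_length = 1e5, n_clusters = 20,
                          cluster_length = 10000))
  expect_error(sim_config(dispersion = -1))
})
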