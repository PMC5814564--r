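toy_features <- function(pqs, pds, ratio, k = 0L, valid = !is.na(ratio)) {
  n <- length(pqs)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 10000,
             end = seq_len(n) * 10000,
             count_control = ifelse(valid, 100L, 0L),
             count_ligand = 10L,
             pqs_count = pqs, g4_pds_count = pds, g4_k_count = k,
             ratio = ratio, valid = valid)
}

pos_genes_df <- function(pqs, pds, ratio, k) {
  data.frame(gene = paste0("g", seq_along(pqs)), n_windows = 1L,
             pqs_mean = pqs, pds_mean = pds, ratio_mean = ratio,
             k_mean = k)
}

test_that("printed control-gene means reproduce the printed criteria", {
  # positive-set means (24, 9.8, 0.292, 6.2) -> thresholds (24, 10, 0.292, 6)
  pos <- pos_genes_df(pqs = c(23, 25), pds = c(9.6, 10.0),
                      ratio = c(0.292, 0.292), k = c(6.0, 6.4))
  expect_equal(mean(pos$pds_mean), 9.8)
  th <- derive_thresholds(pos)
  expect_equal(th$pqs_min, 24)
  expect_equal(th$g4_pds_min, 10)
  expect_equal(th$ratio_max, 0.292)
  expect_equal(th$g4_k_max, 6)
})

test_that("integer positive-set means pass through unchanged", {
  th <- derive_thresholds(pos_genes_df(10, 5, 0.5, 3))
  expect_equal(unclass(th)[c("pqs_min", "g4_pds_min", "ratio_max",
                             "g4_k_max")],
               list(pqs_min = 10, g4_pds_min = 5, ratio_max = 0.5,
                    g4_k_max = 3))
})

test_that("negative control set is a sanity report, not a constraint", {
  pos <- pos_genes_df(c(23, 25), c(9.6, 10.0), c(0.292, 0.292), c(6, 6.4))
  neg_ok <- pos_genes_df(2.4, 1.1, 1.92, 1)
  expect_silent(derive_thresholds(pos, neg_ok))
  neg_bad <- pos_genes_df(30, 12, 0.1, 1)  # on the cluster side
  expect_warning(derive_thresholds(pos, neg_bad), "non-cluster side")
  expect_error(derive_thresholds(pos[0, ]), "empty")
})

test_that("cluster calling is the conjunction of the three criteria", {
  th <- g4_thresholds()
  f <- toy_features(pqs = c(40, 23, 40, 40, 40, 40),
                    pds = c(15, 15, 9, 15, 15, 15),
                    ratio = c(0.13, 0.13, 0.13, 0.30, 0.292, NA))
  calls <- call_clusters(f, th)
  # row 1: all criteria met; row 2: PQS 23 < 24; row 3: PDS 9 < 10;
  # row 4: ratio 0.30 > 0.292; row 5: boundary ratio 0.292 qualifies;
  # row 6: invalid window never a cluster
  expect_equal(calls$is_cluster, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  s <- cluster_summary(calls)
  expect_equal(s$n_clusters, 2)
  expect_equal(s$mean_ratio, mean(c(0.13, 0.292)))
})

test_that("random feature tables match an independent row-filter oracle", {
  set.seed(51)
  th <- g4_thresholds()
  for (i in 1:20) {
    n <- 200
    f <- toy_features(pqs = rpois(n, 20), pds = rpois(n, 9),
                      ratio = ifelse(runif(n) < 0.05, NA,
                                     round(runif(n, 0, 0.6), 3)))
    calls <- call_clusters(f, th)
    oracle <- with(f, !is.na(ratio) & pqs_count >= 24 &
                     g4_pds_count >= 10 & ratio <= 0.292)
    expect_equal(calls$is_cluster, oracle)
    # set algebra: the called set is the intersection of the three
    # single-criterion sets (restricted to valid windows)
    s1 <- which(f$valid & f$pqs_count >= th$pqs_min)
    s2 <- which(f$valid & f$g4_pds_count >= th$g4_pds_min)
    s3 <- which(f$valid & !is.na(f$ratio) & f$ratio <= th$ratio_max)
    expect_equal(which(calls$is_cluster), intersect(intersect(s1, s2), s3))
  }
})

test_that("relaxing any threshold never shrinks the called set", {
  set.seed(52)
  f <- toy_features(pqs = rpois(300, 20), pds = rpois(300, 9),
                    ratio = round(runif(300, 0, 0.6), 3))
  base <- call_clusters(f, g4_thresholds())$is_cluster
  relaxed <- list(g4_thresholds(pqs_min = 20),
                  g4_thresholds(g4_pds_min = 8),
                  g4_thresholds(ratio_max = 0.4))
  for (th in relaxed) {
    more <- call_clusters(f, th)$is_cluster
    expect_true(all(more[base]))
  }
})

test_that("ligand-inducible extraction respects the K+ threshold", {
  th <- g4_thresholds()
  f <- toy_features(pqs = c(40, 40, 40, 10), pds = rep(15, 4),
                    ratio = rep(0.13, 4), k = c(0L, 6L, 7L, 0L))
  calls <- call_clusters(f, th)
  ind <- extract_ligand_inducible(calls, th)
  # k=0 and k=6 clusters are inducible; k=7 is not; the non-cluster
  # (PQS 10) is excluded regardless of its k=0
  expect_equal(ind$g4_k_count, c(0L, 6L))
  expect_true(all(ind$is_cluster))
  expect_true(all(ind$is_ligand_inducible))
  # subset chain: inducible subset of clusters subset of valid windows
  expect_true(all(ind$start %in% calls$start[calls$is_cluster]))
  expect_true(all(calls$valid[calls$is_cluster]))
})

test_that("per-gene features average the windows a gene overlaps", {
  f <- toy_features(pqs = c(10, 20, 30, 40), pds = c(1, 2, 3, 4),
                    ratio = c(0.1, 0.2, 0.3, 0.4), k = c(1L, 1L, 2L, 2L))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(5000, 25000),
                                                   c(15000, 35000)))
  names(genes) <- c("geneA", "geneB")
  gf <- gene_set_features(f, genes)
  expect_equal(gf$gene, c("geneA", "geneB"))
  expect_equal(gf$pqs_mean, c(15, 35))  # windows 1-2 and 3-4
  expect_equal(gf$ratio_mean, c(0.15, 0.35))
  off <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 100))
  names(off) <- "ghost"
  expect_error(suppressWarnings(gene_set_features(f, off)), "ghost")
})

test_that("TSS enrichment report handles extremes", {
  th <- g4_thresholds()
  f <- toy_features(pqs = c(40, 40, 10, 10), pds = rep(15, 4),
                    ratio = rep(0.13, 4))
  calls <- call_clusters(f, th)
  # every window contains a TSS: fractions 1, odds ratio undefined
  tss_all <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(5, 10005, 20005,
                                                       30005), width = 1))
  expect_warning(e <- tss_enrichment(calls, tss_all), "degenerate")
  expect_equal(e$cluster_fraction, 1)
  expect_equal(e$genome_fraction, 1)
  expect_true(is.na(e$odds_ratio))
  # TSS only outside clusters
  tss_out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20005, width = 1))
  e2 <- tss_enrichment(calls, tss_out)
  expect_equal(e2$cluster_fraction, 0)
  expect_equal(e2$genome_fraction, 0.25)
  # empty TSS input
  expect_warning(e3 <- tss_enrichment(calls, GenomicRanges::GRanges()),
                 "empty")
  expect_equal(e3$genome_fraction, 0)
  # a TSS exactly on a window boundary belongs to the downstream window
  tss_b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, width = 1))
  e4 <- tss_enrichment(calls, tss_b)
  expect_equal(e4$calls$tss_count, c(0L, 1L, 0L, 0L))
})

test_that("thresholds derived from simulated controls separate windows", {
  cfg <- sim_config(genome_length = 1e6, n_chromosomes = 1, n_clusters = 6,
                    mean_depth = 1000, seed = 53)
  sim <- simulate_g4_dataset(cfg)
  pqs <- call_pqs(sim$genome)
  feats <- build_window_features(sim$counts, pqs, pds = sim$tracks$pds,
                                 kplus = sim$tracks$kplus,
                                 compute_fisher = FALSE)
  # controls: three cluster windows as positives, five background windows
  # as negatives; evaluate separation on all remaining windows
  cl <- sim$truth$planted_clusters
  pos_genes <- cl[1:3]
  names(pos_genes) <- paste0("pos", 1:3)
  win <- GenomicRanges::GRanges(feats$chrom,
                                IRanges::IRanges(feats$start + 1, feats$end))
  bg_idx <- which(!IRanges::overlapsAny(win, cl))[1:5]
  neg_genes <- win[bg_idx]
  names(neg_genes) <- paste0("neg", 1:5)
  th <- derive_thresholds(gene_set_features(feats, pos_genes),
                          gene_set_features(feats, neg_genes))
  calls <- call_clusters(feats, th)
  truth_lab <- IRanges::overlapsAny(win, cl)
  acc <- mean(calls$is_cluster == truth_lab)
  expect_gte(acc, 0.9)
})
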