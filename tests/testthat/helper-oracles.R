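# Independent brute-force oracles used to check the package's fast paths.
# They deliberately share no code with the implementation: per-base scores
# come from an explicit character scan, PQS calling from full window
# enumeration with run merging on a logical mask, window assignment from a
# quadratic linear scan, and Fisher's p from explicit enumeration of all
# 2x2 tables with the observed margins.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1L]]]), collapse = "")
}

oracle_scores <- function(s) {
  ch <- strsplit(toupper(s), "")[[1L]]
  n <- length(ch)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    k <- j - i + 1L
    out[i:j] <- if (ch[i] == "G") min(k, 4) else
      if (ch[i] == "C") -min(k, 4) else 0
    i <- j + 1L
  }
  out
}

# every sliding window, explicit mean, mark covered bases per sign, then
# report maximal runs of marked bases with the mean score over the run
oracle_call_pqs <- function(s, w = 25L, t = 1.2) {
  sc <- oracle_scores(s)
  n <- length(sc)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (n < w) return(empty)
  mask_pos <- logical(n)
  mask_neg <- logical(n)
  for (i in seq_len(n - w + 1L)) {
    m <- sum(sc[i:(i + w - 1L)]) / w
    if (m >= t) mask_pos[i:(i + w - 1L)] <- TRUE
    if (m <= -t) mask_neg[i:(i + w - 1L)] <- TRUE
  }
  runs_of <- function(mask, strand) {
    res <- empty
    i <- 1L
    while (i <= n) {
      if (mask[i]) {
        j <- i
        while (j < n && mask[j + 1L]) j <- j + 1L
        res <- rbind(res, data.frame(start = i, end = j, strand = strand,
                                     score = mean(sc[i:j])))
        i <- j + 1L
      } else i <- i + 1L
    }
    res
  }
  rbind(runs_of(mask_pos, "+"), runs_of(mask_neg, "-"))
}

pqs_to_df <- function(gr) {
  df <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   score = gr$score)
  df[order(df$strand, df$start), , drop = FALSE]
}

# stabbing count of 1-based positions into 0-based half-open windows
oracle_count_in_windows <- function(chrom, pos, win) {
  counts <- integer(nrow(win))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(win))) {
      if (chrom[i] == win$chrom[j] && pos[i] > win$start[j] &&
          pos[i] <= win$end[j]) {
        counts[j] <- counts[j] + 1L
        break
      }
    }
  }
  counts
}

# exhaustive enumeration of all 2x2 tables with margins fixed at the
# observed values; probabilities from log-binomial coefficients
oracle_fisher_enum <- function(a, b, A, B) {
  k <- a + b
  xs <- max(0, k - B):min(k, A)
  pr <- exp(lchoose(A, xs) + lchoose(B, k - xs) - lchoose(A + B, k))
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# tiny SAM file with the given 1-based positions; extra lines appended raw
write_test_sam <- function(path, chrom_sizes, chrom, pos, flag = 0L,
                           mapq = 60L, extra = character(0)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  rec <- sprintf("r%03d\t%d\t%s\t%d\t%d\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                 seq_along(pos), as.integer(flag), chrom, as.integer(pos),
                 as.integer(mapq))
  writeLines(c(hdr, rec, extra), path)
  path
}
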