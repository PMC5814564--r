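#' Per-base G4Hunter scores
#'
#' Assigns every base the signed G4Hunter value determined by the
#' homopolymer run containing it: a base inside a run of `k` consecutive
#' guanines scores `+min(k, 4)`, a base inside a run of `k` consecutive
#' cytosines scores `-min(k, 4)`, and all other bases score 0. Positive
#' scores mark G-rich (plus-strand) quadruplex propensity, negative scores
#' C-rich runs, i.e. a G4 on the minus strand.
#'
#' @param x A single sequence: character scalar or [Biostrings::DNAString].
#'   Case-insensitive. `N` scores 0 silently; other IUPAC ambiguity codes
#'   score 0 with a one-time warning; any non-IUPAC character is an error
#'   naming its offset.
#' @return Numeric vector of per-base scores, same length as the sequence,
#'   each in `[-4, 4]`.
#' @examples
#' g4hunter_scores("ACGT")   # 0 -1 1 0
#' g4hunter_scores("GGGGG")  # all 4
#' @seealso [call_pqs()] for sliding-window calling of PQS regions.
#' @export
g4hunter_scores <- function(x) {
  if (is(x, "XString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(toupper(x))
  if (length(codes) == 0L) return(numeric(0))

  G <- utf8ToInt("G"); C <- utf8ToInt("C")
  acgtn <- utf8ToInt("ACGTN")
  iupac <- utf8ToInt("RYSWKMBDHV")
  bad <- !(codes %in% c(acgtn, iupac))
  if (any(bad)) {
    stop("non-IUPAC character '", intToUtf8(codes[which(bad)[1L]]),
         "' at position ", which(bad)[1L])
  }
  amb <- codes %in% iupac
  if (any(amb)) {
    warning("sequence contains ", sum(amb),
            " IUPAC ambiguity code(s) other than N; scored as 0")
  }

  r <- rle(codes)
  v <- numeric(length(r$values))
  v[r$values == G] <-  pmin(r$lengths[r$values == G], 4L)
  v[r$values == C] <- -pmin(r$lengths[r$values == C], 4L)
  inverse.rle(list(lengths = r$lengths, values = v))
}

## sliding-window means of a score vector via cumulative sums
.window_means <- function(scores, w) {
  n <- length(scores)
  cs <- c(0, cumsum(scores))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

## call PQS regions on one sequence; returns a data.frame of 1-based
## closed [start, end] spans with strand and mean score
.call_pqs_one <- function(scores, window, threshold) {
  n <- length(scores)
  wm <- .window_means(scores, window)
  cs <- c(0, cumsum(scores))
  one_sign <- function(idx, strand) {
    if (length(idx) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), score = numeric(0)))
    }
    reg <- reduce(IRanges(start = idx, width = window))
    sc <- (cs[end(reg) + 1L] - cs[start(reg)]) / width(reg)
    data.frame(start = start(reg), end = end(reg),
               strand = strand, score = sc)
  }
  rbind(one_sign(which(wm >= threshold), "+"),
        one_sign(which(wm <= -threshold), "-"))
}

#' Call putative quadruplex-forming sequences (PQS) with G4Hunter
#'
#' Slides a window of length `window` over each sequence, marks every
#' window whose mean per-base score (see [g4hunter_scores()]) has absolute
#' value at least `threshold`, merges overlapping or adjacent marked
#' windows of the same sign into one region, and reports each merged
#' region with its strand (`+` for G-rich, `-` for C-rich) and the mean
#' base score over the merged span. Regions of opposite sign are never
#' merged. Defaults are the published G4Hunter defaults (window 25,
#' threshold 1.2). The merged above-threshold span is reported without
#' re-trimming to G/C boundaries; the choice is recorded in
#' `metadata()` of the result.
#'
#' @param x Sequences: a named character vector, [Biostrings::DNAStringSet],
#'   or a single sequence (then named `"seq"`).
#' @param window Sliding-window length in bases (default 25).
#' @param threshold Minimum absolute window mean score (default 1.2).
#' @return A [GenomicRanges::GRanges] of PQS hits with a `score` metadata
#'   column (signed mean base score; sign matches strand). Sequences
#'   shorter than `window` yield no hits, with a warning.
#' @examples
#' call_pqs(c(chrT = strrep("GGGTTA", 10)))
#' @export
call_pqs <- function(x, window = 25L, threshold = 1.2) {
  stopifnot(window >= 1L, threshold > 0)
  if (is(x, "DNAStringSet")) {
    lens <- setNames(width(x), names(x))
    seqs <- as.character(x)
  } else if (is(x, "XString")) {
    seqs <- c(seq = as.character(x))
    lens <- setNames(nchar(seqs), names(seqs))
  } else {
    stopifnot(is.character(x))
    if (is.null(names(x)) && length(x) == 1L) names(x) <- "seq"
    stopifnot(!is.null(names(x)))
    seqs <- x
    lens <- setNames(nchar(x), names(x))
  }
  short <- lens < window
  if (any(short)) {
    warning("sequence(s) shorter than the scanning window, skipped: ",
            paste(names(lens)[short], collapse = ", "))
  }
  hits <- lapply(names(seqs)[!short], function(nm) {
    df <- .call_pqs_one(g4hunter_scores(seqs[[nm]]), window, threshold)
    if (nrow(df)) df$chrom <- nm
    df
  })
  hits <- hits[vapply(hits, nrow, 1L) > 0L]
  if (length(hits) == 0L) {
    gr <- GRanges(seqlengths = lens)
    mcols(gr)$score <- numeric(0)
  } else {
    df <- do.call(rbind, hits)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                  score = df$score, seqlengths = lens)
    gr <- sort(gr, ignore.strand = TRUE)
  }
  metadata(gr) <- list(window = window, threshold = threshold,
                       region_refinement = "merged-span")
  gr
}

#' Count interval hits per genome window by start coordinate
#'
#' Assigns each hit (PQS region, G4-seq interval, TSS, ...) to exactly one
#' window: the window containing its leftmost (start) coordinate, so a hit
#' spanning a window boundary is counted once. Hits on chromosomes absent
#' from `windows` (or starting beyond the tiled region) are tallied as
#' unassigned with a warning.
#'
#' @param hits [GenomicRanges::GRanges] of features; strand is ignored.
#' @param windows Non-overlapping sorted windows from [make_windows()].
#' @return Integer vector of counts parallel to `windows`, with attribute
#'   `unassigned` (number of hits not falling in any window).
#' @export
count_hits_per_window <- function(hits, windows) {
  stopifnot(is(hits, "GRanges"), is(windows, "GRanges"))
  if (length(hits) == 0L) {
    out <- integer(length(windows))
    attr(out, "unassigned") <- 0L
    return(out)
  }
  anchors <- GRanges(seqnames(hits), IRanges(start(hits), width = 1L))
  missing_chrom <- !(as.character(seqnames(anchors)) %in%
                       as.character(seqnames(windows)))
  if (any(missing_chrom)) {
    warning("hits on chromosome(s) absent from windows: ",
            paste(unique(as.character(seqnames(anchors))[missing_chrom]),
                  collapse = ", "))
  }
  suppressWarnings(
    ov <- findOverlaps(anchors, windows, ignore.strand = TRUE)
  )
  out <- tabulate(subjectHits(ov), nbins = length(windows))
  attr(out, "unassigned") <- length(hits) - length(ov)
  out
}

#' Export PQS hits as BED6
#'
#' Writes hits from [call_pqs()] as BED6 with name `"PQS"`, the BED score
#' column set to `1000 * |mean score|` clamped to `[0, 1000]`, and the
#' strand column as called.
#'
#' @param hits GRanges from [call_pqs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pqs_bed <- function(hits, path) {
  gr <- hits
  mcols(gr) <- DataFrame(
    name = rep("PQS", length(gr)),
    score = pmin(1000, round(1000 * abs(hits$score)))
  )
  export(gr, path, format = "bed")
  invisible(path)
}
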