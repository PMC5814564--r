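#' Tile a genome into fixed non-overlapping windows
#'
#' Windows tile each chromosome without gaps or overlaps; every window has
#' width `bin` except possibly the last window of a chromosome, which is
#' truncated at the chromosome end. Ordering is the input chromosome
#' order, then start coordinate.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths, or a
#'   two-column data.frame `(chrom, length)`, or a
#'   [GenomeInfoDb::Seqinfo].
#' @param bin Window size in bases (> 0).
#' @return [GenomicRanges::GRanges] of windows with seqlengths set and an
#'   `index` metadata column (ordinal within chromosome).
#' @examples
#' make_windows(c(chr1 = 25000), bin = 10000)
#' @export
make_windows <- function(chrom_sizes, bin) {
  if (is(chrom_sizes, "Seqinfo")) {
    chrom_sizes <- seqlengths(chrom_sizes)
  } else if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2L]]),
                            as.character(chrom_sizes[[1L]]))
  }
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), length(bin) == 1L, bin > 0)
  bin <- as.integer(bin)
  if (any(chrom_sizes < bin)) {
    warning("bin size exceeds the length of chromosome(s): ",
            paste(names(chrom_sizes)[chrom_sizes < bin], collapse = ", "),
            "; a single truncated window is emitted for each")
  }
  n_per_chrom <- ceiling(chrom_sizes / bin)
  starts <- unlist(lapply(n_per_chrom, function(n) {
    (seq_len(n) - 1) * bin + 1
  }), use.names = FALSE)
  chrom <- rep(names(chrom_sizes), n_per_chrom)
  ends <- pmin(starts + bin - 1, chrom_sizes[chrom])
  win <- GRanges(factor(chrom, levels = names(chrom_sizes)),
                 IRanges(starts, ends), seqlengths = chrom_sizes)
  win$index <- unlist(lapply(n_per_chrom, seq_len), use.names = FALSE)
  win
}

## read mapped-read start positions (leftmost reference coordinate) from a
## BAM/SAM file; returns a GRanges of width-1 anchors plus filter tallies
.read_alignment_starts <- function(path, min_mapq, exclude_flags) {
  ext <- tolower(file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(asBam(path, destination = dest,
                                   overwrite = TRUE, indexDestination = TRUE))
  }
  b <- scanBam(path, param = ScanBamParam(
    what = c("rname", "pos", "mapq", "flag")))[[1L]]
  n_in <- length(b$flag)
  keep <- !is.na(b$pos) & bitwAnd(b$flag, as.integer(exclude_flags)) == 0L
  mq <- b$mapq
  mq[is.na(mq)] <- 255L  # MAPQ 255 = unavailable; not filtered by default
  keep <- keep & mq >= min_mapq
  gr <- GRanges(as.character(b$rname)[keep],
                IRanges(b$pos[keep], width = 1L))
  attr(gr, "n_input") <- n_in
  attr(gr, "n_filtered_out") <- n_in - sum(keep)
  gr
}

#' Count mapped reads of one library in fixed genome windows
#'
#' Each read is assigned to the single window containing its 5'-most
#' mapped coordinate (the leftmost reference coordinate), so counts are
#' conserved and counts at a coarse bin equal the sum of the counts of the
#' finer bins that compose it. Paired-end mates are counted independently.
#' For BAM/SAM input, unmapped, secondary and supplementary alignments and
#' reads below `min_mapq` are excluded and tallied.
#'
#' @param x Read intervals as a [GenomicRanges::GRanges], or a path to a
#'   BAM, SAM or BED file.
#' @param windows Windows from [make_windows()].
#' @param min_mapq Minimum mapping quality for BAM/SAM input (default 0;
#'   records with MAPQ unavailable are kept).
#' @param exclude_flags SAM flag mask excluded for BAM/SAM input; default
#'   unmapped (0x4) + secondary (0x100) + supplementary (0x800).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `count`, one row per window, with attributes
#'   `total_reads` (reads passing filters), `unassigned` (filtered reads
#'   whose start lies in no window) and `filtered_out` (BAM/SAM records
#'   removed by flag/MAPQ filters).
#' @export
count_reads <- function(x, windows, min_mapq = 0,
                        exclude_flags = 0x4 + 0x100 + 0x800) {
  stopifnot(is(windows, "GRanges"))
  filtered_out <- 0L
  if (is.character(x)) {
    ext <- tolower(file_ext(x))
    if (ext %in% c("bam", "sam")) {
      x <- .read_alignment_starts(x, min_mapq, exclude_flags)
      filtered_out <- attr(x, "n_filtered_out")
    } else if (ext == "bed") {
      x <- read_bed(x)
    } else {
      stop("unsupported alignment file extension: ", ext)
    }
  }
  stopifnot(is(x, "GRanges"))
  counts <- count_hits_per_window(x, windows)
  out <- data.frame(
    chrom = as.character(seqnames(windows)),
    start = start(windows) - 1L,
    end = end(windows),
    count = as.integer(counts)
  )
  attr(out, "total_reads") <- length(x)
  attr(out, "unassigned") <- attr(counts, "unassigned")
  attr(out, "filtered_out") <- filtered_out
  out
}

#' Pair per-window counts of the ligand and control libraries
#'
#' @param control,ligand Single-library count tables from [count_reads()]
#'   on identical windows (control = untreated WGA library, ligand =
#'   G4-ligand WGA library).
#' @return A data.frame `chrom, start, end, count_control, count_ligand`
#'   with attributes `total_control` and `total_ligand` (library totals).
#' @export
window_counts <- function(control, ligand) {
  stopifnot(identical(control[c("chrom", "start", "end")],
                      ligand[c("chrom", "start", "end")]))
  out <- data.frame(control[c("chrom", "start", "end")],
                    count_control = control$count,
                    count_ligand = ligand$count)
  attr(out, "total_control") <- attr(control, "total_reads")
  attr(out, "total_ligand") <- attr(ligand, "total_reads")
  out
}

#' Per-chromosome depth summary and ligand/control ratio
#'
#' Mirrors the per-chromosome coverage comparison used to flag
#' PQS-dense chromosomes: mean reads per window for each library and
#' their ratio, per chromosome.
#'
#' @param counts Paired count table from [window_counts()] or
#'   [simulate_window_counts()].
#' @return A data.frame `chrom, n_windows, mean_control, mean_ligand,
#'   ratio` where `ratio = sum(ligand)/sum(control)`, in input
#'   chromosome order.
#' @export
chromosome_depth_summary <- function(counts) {
  .check_counts(counts)
  chroms <- unique(counts$chrom)
  rows <- lapply(chroms, function(ch) {
    d <- counts[counts$chrom == ch, ]
    data.frame(chrom = ch, n_windows = nrow(d),
               mean_control = mean(d$count_control),
               mean_ligand = mean(d$count_ligand),
               ratio = if (sum(d$count_control) > 0)
                 sum(d$count_ligand) / sum(d$count_control) else NA_real_)
  })
  do.call(rbind, rows)
}

.check_counts <- function(counts) {
  need <- c("chrom", "start", "end", "count_control", "count_ligand")
  if (!all(need %in% names(counts))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  invisible(counts)
}

## GRanges view of the windows of a counts/features table (start is 0-based)
.table_windows <- function(tab) {
  GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
}
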