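#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import()] (BED is 0-based half-open on
#' disk; the returned GRanges is 1-based) with a pre-scan that reports
#' malformed lines by line number: fewer than three fields, non-numeric
#' coordinates, or `start > end`.
#'
#' @param path BED3/BED6 file; `track`/`browser`/comment lines are
#'   allowed.
#' @return [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  data_i <- which(!grepl("^(#|track\\b|browser\\b)", lines) &
                    nzchar(trimws(lines)))
  for (i in data_i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed BED line ", i, ": fewer than 3 fields")
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", i, ": non-numeric coordinates")
    }
    if (s > e) stop("malformed BED line ", i, ": start > end")
  }
  import(path, format = "bed")
}

#' Write GRanges as BED
#'
#' @param gr GRanges; `name` and `score` metadata columns, if present,
#'   populate the BED name/score fields.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write the paired window-count TSV
#'
#' Tab-separated, header `chrom start end count_control count_ligand`,
#' coordinates 0-based half-open. Reading restores the library-total
#' attributes from the column sums.
#'
#' @param path File path.
#' @return For `read_counts_tsv`, the counts data.frame.
#' @export
read_counts_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  .check_counts(out)
  attr(out, "total_control") <- sum(out$count_control)
  attr(out, "total_ligand") <- sum(out$count_ligand)
  out
}

#' @rdname read_counts_tsv
#' @param counts Counts (or any window-keyed) data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-window value track as bedGraph
#'
#' Windows with missing values are dropped (bedGraph requires numeric
#' values).
#'
#' @param tab Window-keyed data.frame (`chrom`, `start`, `end`).
#' @param value_col Name of the numeric column to export.
#' @param path Output file.
#' @param name Track name for the bedGraph track line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tab, value_col, path, name = value_col) {
  keep <- is.finite(tab[[value_col]])
  gr <- GRanges(tab$chrom[keep],
                IRanges(tab$start[keep] + 1L, tab$end[keep]),
                score = tab[[value_col]][keep])
  line <- methods::new("GraphTrackLine", name = name, type = "bedGraph")
  export(gr, path, format = "bedGraph", trackLine = line)
  invisible(path)
}

#' Write a per-window value track in IGV format
#'
#' Tab-delimited `.igv` track: header line
#' `Chromosome Start End Feature <name>` then one row per window
#' (0-based start, as IGV expects), suitable for the Integrative
#' Genomics Viewer.
#'
#' @inheritParams write_bedgraph
#' @param feature Feature-name column content (single string).
#' @return `path`, invisibly.
#' @export
write_igv_track <- function(tab, value_col, path, name = value_col,
                            feature = name) {
  keep <- is.finite(tab[[value_col]])
  df <- data.frame(Chromosome = tab$chrom[keep],
                   Start = tab$start[keep],
                   End = tab$end[keep],
                   Feature = feature,
                   value = tab[[value_col]][keep])
  names(df)[5L] <- name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' FASTA output is wrapped at 60 columns.
#'
#' @param path FASTA file.
#' @return For `read_genome_fasta`, a [Biostrings::DNAStringSet] with
#'   names truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_genome_fasta
#' @param genome Named [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  writeXStringSet(genome, path, width = 60L)
  invisible(path)
}
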