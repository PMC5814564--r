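#' Two-sided Fisher's exact test for one window against the library totals
#'
#' Tests whether a window's share of reads differs between the two
#' libraries, on the 2x2 table
#' `[[c_ligand, total_ligand - c_ligand], [c_control, total_control -
#' c_control]]`. The two-sided p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with the conventional
#' `1 + 1e-7` relative tolerance for ties, as in [stats::fisher.test()]).
#' Vectorised over `c_ligand`/`c_control` for per-window use.
#'
#' @param c_ligand,c_control Window read counts (vectors).
#' @param total_ligand,total_control Library totals (scalars or vectors),
#'   each at least the corresponding window count and positive.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_window(5, 5, 100, 100)   # symmetric table -> 1
#' @export
fisher_window <- function(c_ligand, c_control, total_ligand, total_control) {
  n <- max(length(c_ligand), length(c_control))
  a <- rep_len(as.numeric(c_ligand), n)
  b <- rep_len(as.numeric(c_control), n)
  A <- rep_len(as.numeric(total_ligand), n)
  B <- rep_len(as.numeric(total_control), n)
  if (any(A <= 0) || any(B <= 0)) stop("library totals must be positive")
  if (any(a < 0) || any(b < 0)) stop("window counts must be non-negative")
  if (any(a > A) || any(b > B)) stop("window counts exceed library totals")
  vapply(seq_len(n), function(i) {
    k <- a[i] + b[i]
    lo <- max(0, k - B[i])
    hi <- min(k, A[i])
    d <- dhyper(lo:hi, A[i], B[i], k)
    dobs <- d[a[i] - lo + 1L]
    min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }, numeric(1L))
}

#' Per-window depletion ratio, fold change and Fisher's exact p
#'
#' The depletion ratio of a window is the mapped-read count of the
#' G4-ligand library divided by that of the control library; windows with
#' zero control reads are flagged invalid (`valid = FALSE`) and their
#' ratio is `NA` rather than imputed. `fold_change` is the same quantity
#' after optional library-size normalisation (ligand counts rescaled by
#' `total_control / total_ligand`); with `normalize = FALSE` (default,
#' matching raw-count analysis) it equals the ratio.
#'
#' @param counts Paired count table ([window_counts()] /
#'   [simulate_window_counts()]). Library totals are taken from the
#'   table's attributes when present, else from column sums.
#' @param normalize Apply library-size normalisation to `fold_change`?
#' @param compute_fisher Compute the per-window Fisher's exact p-value
#'   ([fisher_window()] against the library totals)? Default `TRUE`.
#' @param fdr Also append Benjamini-Hochberg `q_value` ([bh_fdr()])?
#'   Off by default: the calling criteria use the ratio, not p.
#' @return The input table with columns `ratio`, `fold_change`,
#'   `fisher_p` (if computed), `q_value` (if `fdr`) and `valid` appended;
#'   attributes `total_control`/`total_ligand` carry the totals used.
#' @export
window_stats <- function(counts, normalize = FALSE, compute_fisher = TRUE,
                         fdr = FALSE) {
  .check_counts(counts)
  total_c <- attr(counts, "total_control")
  total_l <- attr(counts, "total_ligand")
  if (is.null(total_c)) total_c <- sum(counts$count_control)
  if (is.null(total_l)) total_l <- sum(counts$count_ligand)
  valid <- counts$count_control > 0
  ratio <- ifelse(valid, counts$count_ligand / counts$count_control,
                  NA_real_)
  scale <- if (normalize) total_c / total_l else 1
  fold <- ifelse(valid,
                 (counts$count_ligand * scale) / counts$count_control,
                 NA_real_)
  out <- counts
  out$ratio <- ratio
  out$fold_change <- fold
  if (compute_fisher) {
    out$fisher_p <- fisher_window(counts$count_ligand, counts$count_control,
                                  total_l, total_c)
    if (fdr) out$q_value <- bh_fdr(out$fisher_p)
  }
  out$valid <- valid
  attr(out, "total_control") <- total_c
  attr(out, "total_ligand") <- total_l
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, monotone in p.
#'
#' @param p P-values in `(0, 1]`; values outside are an error.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Correlation between PQS density and the depletion ratio
#'
#' The association between per-window PQS counts and ligand/control
#' depletion ratios; its strengthening with window size motivates calling
#' clusters on large (10 kbp) windows. Only valid windows (finite ratio)
#' enter; a zero-variance input yields `NA` with a warning rather than 0.
#'
#' @param pqs_counts Integer vector of per-window PQS counts.
#' @param ratio Numeric vector of per-window depletion ratios (`NA` for
#'   invalid windows), parallel to `pqs_counts`.
#' @param method `"pearson"` (default) or `"spearman"` for a
#'   rank-correlation alternative.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pqs_ratio_correlation <- function(pqs_counts, ratio,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(pqs_counts) == length(ratio))
  ok <- is.finite(ratio) & is.finite(pqs_counts)
  if (sum(ok) < 3L) stop("fewer than 3 valid windows")
  x <- pqs_counts[ok]
  y <- ratio[ok]
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}
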