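#' Per-marker call rate and minor allele frequency
#'
#' Call rate is the non-missing fraction of lines; allele frequency is
#' computed on non-missing calls only, each heterozygote contributing one
#' copy of each allele. Monomorphic markers have maf 0; all-missing markers
#' have call rate 0 and undefined (NA) maf.
#'
#' @param geno Genotype matrix, lines x markers, calls 0/1/2/NA (copies of
#'   allele 1).
#' @return data.frame with columns \code{marker}, \code{call_rate},
#'   \code{maf}, \code{p1} (allele-1 frequency), \code{polymorphic}.
#' @export
marker_stats <- function(geno) {
  if (nrow(geno) < 1L) stop("at least one line is required")
  n_called <- colSums(!is.na(geno))
  p1 <- colSums(geno, na.rm = TRUE) / (2 * n_called)
  p1[n_called == 0L] <- NA_real_
  maf <- pmin(p1, 1 - p1)
  data.frame(marker = colnames(geno),
             call_rate = n_called / nrow(geno),
             maf = maf, p1 = p1,
             polymorphic = !is.na(maf) & maf > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a variety-panel genotype matrix
#'
#' Keeps codominant markers with minor allele frequency at or above
#' \code{maf_min} and with a missing-data fraction strictly below
#' \code{missing_max}; lines are untouched.
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param missing_max Maximum missing fraction (exclusive).
#' @return The filtered genotype matrix, with a \code{"qc_report"} attribute
#'   counting markers removed per rule.
#' @export
filter_variety_panel <- function(geno, maf_min = 0.01, missing_max = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  st <- marker_stats(geno)
  miss <- colMeans(is.na(geno))
  fail_maf <- is.na(st$maf) | st$maf < maf_min
  fail_miss <- miss >= missing_max
  keep <- !fail_maf & !fail_miss
  out <- geno[, keep, drop = FALSE]
  attr(out, "qc_report") <- c(removed_maf = sum(fail_maf),
                              removed_missing = sum(fail_miss),
                              kept = sum(keep))
  out
}

## Markers perfectly correlated: identical calls over jointly non-missing
## lines, allowing a global allele flip (x vs 2 - x). At least one jointly
## non-missing line is required.
.perfectly_correlated <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(FALSE)
  all(a[ok] == b[ok]) || all(a[ok] == 2L - b[ok])
}

#' Filter a MAGIC genotype matrix for association analysis
#'
#' Applies the analysis filters in a fixed order: (1) lines with a call rate
#' below \code{line_success_min} are deleted; (2) markers with call rate at or
#' below \code{success_min} or minor allele frequency at or below
#' \code{maf_min} are removed; (3) of every pair of remaining markers that
#' correlate perfectly (identical genotype patterns over jointly non-missing
#' lines, allowing a global allele relabelling), the marker later in map order
#' is removed, unmapped markers ordering after mapped ones lexicographically.
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param success_min Marker call-rate threshold (strict: kept if >).
#' @param maf_min Marker maf threshold (strict: kept if >).
#' @param line_success_min Line call-rate threshold (kept if >=).
#' @param map Optional genetic map ordering the duplicate pruning.
#' @return Filtered genotype matrix with a \code{"qc_report"} attribute
#'   (lines removed, markers removed per rule).
#' @export
filter_magic_panel <- function(geno, success_min = 0.91, maf_min = 0.05,
                               line_success_min = 0.75, map = NULL) {
  line_cr <- rowMeans(!is.na(geno))
  keep_lines <- line_cr >= line_success_min
  g <- geno[keep_lines, , drop = FALSE]
  st <- marker_stats(g)
  keep_m <- st$call_rate > success_min & !is.na(st$maf) & st$maf > maf_min
  g <- g[, keep_m, drop = FALSE]
  ord <- .map_order(colnames(g), map)
  g <- g[, ord, drop = FALSE]
  # prune perfect duplicates, keeping the first in map order; complete
  # matrices are deduplicated by a canonical (flip-invariant) pattern hash,
  # matrices with missing data need the exact pairwise joint-pattern test
  drop <- rep(FALSE, ncol(g))
  if (ncol(g) > 1L) {
    if (!anyNA(g)) {
      pat <- apply(g, 2L, paste, collapse = "")
      flip <- apply(2L - g, 2L, paste, collapse = "")
      drop <- duplicated(pmin(pat, flip))
    } else {
      for (i in seq_len(ncol(g) - 1L)) {
        if (drop[i]) next
        for (j in seq.int(i + 1L, ncol(g))) {
          if (!drop[j] && .perfectly_correlated(g[, i], g[, j])) drop[j] <- TRUE
        }
      }
    }
  }
  out <- g[, !drop, drop = FALSE]
  attr(out, "qc_report") <- c(removed_lines = sum(!keep_lines),
                              removed_marker_qc = sum(!keep_m),
                              removed_duplicates = sum(drop),
                              kept_lines = nrow(out), kept_markers = ncol(out))
  out
}

## order marker ids by map position; unmapped markers after mapped ones,
## lexicographically
.map_order <- function(markers, map) {
  if (is.null(map)) return(order(rep(0L, length(markers)), markers))
  idx <- match(markers, map$marker)
  mapped <- !is.na(idx)
  chrom <- rep(NA_character_, length(markers)); pos <- rep(NA_real_, length(markers))
  chrom[mapped] <- map$chrom[idx[mapped]]
  pos[mapped] <- map$pos_cM[idx[mapped]]
  order(!mapped, chrom, pos, markers)
}

#' Expected heterozygosity and segregating-marker summary
#'
#' Per biallelic marker, expected heterozygosity under random mating is
#' \code{He = 1 - p^2 - (1 - p)^2 = 2 p (1 - p)} with \code{p} the allele-1
#' frequency among non-missing calls in the chosen line subset. The summary
#' reports the mean over markers (markers all-missing within the subset are
#' excluded and counted) and the number of segregating markers
#' (\code{0 < p < 1}).
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param line_subset Optional character vector of line ids (default: all).
#' @return An object of class \code{diversity_summary}: list with
#'   \code{mean_He}, \code{segregating}, \code{n_markers},
#'   \code{n_excluded_all_missing}, \code{n_lines} and per-marker \code{He}.
#' @export
expected_heterozygosity <- function(geno, line_subset = NULL) {
  if (!is.null(line_subset)) {
    missing_lines <- setdiff(line_subset, rownames(geno))
    if (length(missing_lines)) stop("unknown lines: ", paste(missing_lines, collapse = ", "))
    geno <- geno[line_subset, , drop = FALSE]
  }
  if (nrow(geno) < 1L) stop("line subset is empty")
  st <- marker_stats(geno)
  He <- 2 * st$p1 * (1 - st$p1)
  usable <- !is.na(He)
  out <- list(mean_He = mean(He[usable]),
              segregating = sum(usable & st$p1 > 0 & st$p1 < 1),
              n_markers = sum(usable),
              n_excluded_all_missing = sum(!usable),
              n_lines = nrow(geno),
              He = stats::setNames(He, st$marker))
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Diversity over %d lines, %d markers (%d all-missing excluded)\n",
              x$n_lines, x$n_markers, x$n_excluded_all_missing))
  cat(sprintf("  mean expected heterozygosity: %.3f\n", x$mean_He))
  cat(sprintf("  segregating markers:          %d\n", x$segregating))
  invisible(x)
}

#' Diversity captured by a panel relative to a reference panel
#'
#' Ratio of mean expected heterozygosities and fraction of the reference
#' panel's segregating markers, both reported as percentages rounded to the
#' nearest integer (the scale on which such comparisons are quoted).
#'
#' @param subset_summary,reference_summary \code{diversity_summary} objects,
#'   or lists with elements \code{mean_He} and \code{segregating} (printed
#'   summary values can be supplied directly).
#' @return List with \code{he_ratio_pct}, \code{segregating_pct} and the
#'   unrounded \code{he_ratio}, \code{segregating_ratio}.
#' @export
diversity_ratio <- function(subset_summary, reference_summary) {
  he_s <- subset_summary$mean_He; he_r <- reference_summary$mean_He
  seg_s <- subset_summary$segregating; seg_r <- reference_summary$segregating
  if (is.null(he_r) || he_r <= 0 || is.null(seg_r) || seg_r <= 0)
    stop("reference panel heterozygosity and segregating count must be positive")
  list(he_ratio = he_s / he_r,
       segregating_ratio = seg_s / seg_r,
       he_ratio_pct = round(100 * he_s / he_r),
       segregating_pct = round(100 * seg_s / seg_r))
}
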