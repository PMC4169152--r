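#' Two-locus haplotype counts from inbred-line genotypes
#'
#' Recombinant inbred lines are treated as inbred: only lines homozygous and
#' non-missing at both markers are used, each contributing its single
#' two-locus haplotype. Lines heterozygous at either marker are excluded
#' (residual heterozygosity in advanced RILs is small enough that no phasing
#' is attempted).
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param markerA,markerB Marker ids.
#' @return 2 x 2 integer matrix of haplotype counts; rows index the allele at
#'   \code{markerA} (\code{"1"}, \code{"0"}), columns at \code{markerB}.
#' @export
haplotype_counts <- function(geno, markerA, markerB) {
  a <- geno[, markerA]; b <- geno[, markerB]
  ok <- !is.na(a) & !is.na(b) & a != 1L & b != 1L
  if (sum(ok) < 2L)
    stop("insufficient data: fewer than 2 doubly homozygous lines for pair (",
         markerA, ", ", markerB, ")")
  ha <- a[ok] / 2L; hb <- b[ok] / 2L   # 0/1 allele per line
  tab <- table(factor(ha, levels = c(1, 0)), factor(hb, levels = c(1, 0)))
  out <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(A = c("1", "0"), B = c("1", "0")))
  out
}

#' Linkage-disequilibrium coefficients from a 2 x 2 haplotype table
#'
#' With haplotype frequencies \code{p_AB} etc. and allele frequencies
#' \code{p_A}, \code{p_B}: \code{D = p_AB - p_A p_B};
#' \code{r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))}; \code{D' = |D| / Dmax}
#' with \code{Dmax = min(p_A (1 - p_B), (1 - p_A) p_B)} when \code{D > 0} and
#' \code{min(p_A p_B, (1 - p_A)(1 - p_B))} otherwise. D' is reported as a
#' magnitude in [0, 1].
#'
#' @param table 2 x 2 haplotype count matrix as from
#'   \code{\link{haplotype_counts}} (rows: allele at A = 1, 0; columns same
#'   for B).
#' @return List with \code{D}, \code{Dprime}, \code{r2}, \code{p_A},
#'   \code{p_B}, \code{n}.
#' @export
ld_pair <- function(table) {
  n <- sum(table)
  if (n < 1L) stop("empty haplotype table")
  p <- table / n
  p_A <- p[1L, 1L] + p[1L, 2L]
  p_B <- p[1L, 1L] + p[2L, 1L]
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    stop("undefined LD: monomorphic margin")
  D <- p[1L, 1L] - p_A * p_B
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  Dmax <- if (D > 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
          else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, Dprime = Dprime, r2 = r2, p_A = p_A, p_B = p_B, n = n)
}

#' All-pairs linkage disequilibrium over a marker set
#'
#' Computes D, D' and r-squared for every marker pair from inbred-line
#' haplotypes, annotated with genetic distance where both markers map to the
#' same chromosome (distance is undefined, NA, between chromosomes). Pairs
#' whose LD is undefined (monomorphic margin or too few doubly homozygous
#' lines) are flagged, not dropped.
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param markers Optional marker subset (default: all columns).
#' @param map Optional genetic map for distance annotation.
#' @return An object of class \code{ld_pairs}: a long-format data.frame with
#'   columns \code{markerA}, \code{markerB}, \code{distance_cM}, \code{D},
#'   \code{Dprime}, \code{r2}, \code{n}, \code{defined}.
#' @export
ld_matrix <- function(geno, markers = NULL, map = NULL) {
  if (is.null(markers)) markers <- colnames(geno)
  k <- length(markers)
  if (k < 2L) stop("at least 2 markers are required")
  idx <- utils::combn(k, 2L)
  np <- ncol(idx)
  res <- data.frame(markerA = markers[idx[1L, ]], markerB = markers[idx[2L, ]],
                    distance_cM = NA_real_, D = NA_real_, Dprime = NA_real_,
                    r2 = NA_real_, n = NA_integer_, defined = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    ca <- map$chrom[match(res$markerA, map$marker)]
    cb <- map$chrom[match(res$markerB, map$marker)]
    pa <- map$pos_cM[match(res$markerA, map$marker)]
    pb <- map$pos_cM[match(res$markerB, map$marker)]
    same <- !is.na(ca) & !is.na(cb) & ca == cb
    res$distance_cM[same] <- abs(pa[same] - pb[same])
  }
  G <- geno[, markers, drop = FALSE]
  hom <- !is.na(G) & G != 1L
  H <- G / 2L
  for (e in seq_len(np)) {
    i <- idx[1L, e]; j <- idx[2L, e]
    ok <- hom[, i] & hom[, j]
    n_ok <- sum(ok)
    if (n_ok < 2L) next
    n11 <- sum(H[ok, i] & H[ok, j])
    nA <- sum(H[ok, i]); nB <- sum(H[ok, j])
    tab <- matrix(as.integer(c(n11, nB - n11, nA - n11, n_ok - nA - nB + n11)),
                  2L, 2L)
    ld <- tryCatch(ld_pair(tab), error = function(e) NULL)
    if (is.null(ld)) next
    res$D[e] <- ld$D; res$Dprime[e] <- ld$Dprime; res$r2[e] <- ld$r2
    res$n[e] <- n_ok; res$defined[e] <- TRUE
  }
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Square LD heatmap matrix (D' above, r-squared below the diagonal)
#'
#' Arranges pairwise LD as a dense numeric matrix in map order with D' above
#' the diagonal, r-squared below and 1 on the diagonal, the layout used for
#' genome-wide LD heatmaps.
#'
#' @param pairs An \code{ld_pairs} table.
#' @param markers Marker ordering (default: order of appearance).
#' @return Square numeric matrix with NA where LD was undefined.
#' @export
ld_heatmap_matrix <- function(pairs, markers = NULL) {
  if (is.null(markers)) markers <- unique(c(pairs$markerA, pairs$markerB))
  k <- length(markers)
  M <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  diag(M) <- 1
  ia <- match(pairs$markerA, markers); ib <- match(pairs$markerB, markers)
  up_r <- pmin(ia, ib); up_c <- pmax(ia, ib)
  M[cbind(up_r, up_c)] <- pairs$Dprime   # above diagonal
  M[cbind(up_c, up_r)] <- pairs$r2       # below diagonal
  M
}

#' Concatenate chromosomes onto one padded genome coordinate
#'
#' For genome-wide displays, each chromosome is padded to a fixed nominal
#' length and chromosomes are laid end to end in genome order (1A, 1B, 1D,
#' 2A, ..., 7D), so a marker's global position is
#' \code{(chromosome index) * pad + within-chromosome cM}. If any chromosome
#' exceeds the pad length a warning is issued and the pad grows to the
#' longest chromosome. Unmapped markers are excluded and reported.
#'
#' @param map Genetic map (\code{marker}, \code{chrom}, \code{pos_cM}).
#' @param pad_to_cM Nominal per-chromosome length (default 250 cM).
#' @return data.frame \code{marker}, \code{chrom}, \code{pos_cM},
#'   \code{global_cM}, with attribute \code{"excluded"} listing unmapped
#'   markers.
#' @export
concat_map_padded <- function(map, pad_to_cM = 250) {
  unmapped <- is.na(map$chrom) | is.na(map$pos_cM)
  mp <- map[!unmapped, , drop = FALSE]
  chroms <- sort(unique(mp$chrom))
  max_len <- max(tapply(mp$pos_cM, mp$chrom, max))
  if (max_len > pad_to_cM) {
    warning("chromosome length ", round(max_len, 2), " cM exceeds pad ",
            pad_to_cM, " cM; padding to the longest chromosome")
    pad_to_cM <- max_len
  }
  ci <- match(mp$chrom, chroms) - 1L
  out <- data.frame(marker = mp$marker, chrom = mp$chrom, pos_cM = mp$pos_cM,
                    global_cM = ci * pad_to_cM + mp$pos_cM,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- map$marker[unmapped]
  attr(out, "pad_cM") <- pad_to_cM
  out
}

#' LD decay against genetic distance with lowess smoothing
#'
#' Intra-chromosome pairs only (distance defined). The smoother is lowess
#' with a small span (default 0.1) — tricube-weighted local linear fits with
#' three robustifying iterations. With fewer than 10 usable pairs only the
#' raw scatter is returned.
#'
#' @param pairs An \code{ld_pairs} table.
#' @param statistic \code{"r2"} or \code{"Dprime"}.
#' @param smoothing_fraction lowess span.
#' @return An object of class \code{ld_decay}: list with \code{scatter}
#'   (distance, statistic), \code{curve} (lowess output, or NULL),
#'   \code{statistic}, \code{smoothing_fraction}.
#' @export
ld_decay <- function(pairs, statistic = c("r2", "Dprime"),
                     smoothing_fraction = 0.1) {
  statistic <- match.arg(statistic)
  ok <- pairs$defined & !is.na(pairs$distance_cM)
  sc <- data.frame(distance_cM = pairs$distance_cM[ok],
                   value = pairs[[statistic]][ok])
  sc <- sc[order(sc$distance_cM), , drop = FALSE]
  curve <- NULL
  if (nrow(sc) >= 10L) {
    curve <- stats::lowess(sc$distance_cM, sc$value, f = smoothing_fraction,
                           iter = 3L)
  } else {
    warning("fewer than 10 intra-chromosome pairs: returning raw scatter only")
  }
  out <- list(scatter = sc, curve = curve, statistic = statistic,
              smoothing_fraction = smoothing_fraction)
  class(out) <- "ld_decay"
  out
}

#' Smoothed LD at a given distance
#'
#' Linear interpolation of the lowess curve of an \code{ld_decay} object.
#'
#' @param decay An \code{ld_decay} object with a fitted curve.
#' @param distance_cM Distances at which to evaluate.
#' @return Numeric vector of smoothed statistic values.
#' @export
ld_at <- function(decay, distance_cM) {
  if (is.null(decay$curve)) stop("no smoothed curve available")
  stats::approx(decay$curve$x, decay$curve$y, xout = distance_cM, rule = 2L)$y
}

#' @export
plot.ld_decay <- function(x, ...) {
  lab <- if (x$statistic == "r2") expression(r^2) else "D'"
  graphics::plot(x$scatter$distance_cM, x$scatter$value, pch = 16,
                 col = grDevices::adjustcolor("grey40", 0.4), cex = 0.5,
                 xlab = "distance (cM)", ylab = lab, ...)
  if (!is.null(x$curve)) graphics::lines(x$curve, col = "red3", lwd = 2)
  invisible(x)
}
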