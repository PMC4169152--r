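#' Pedigree-aware single-marker association scan
#'
#' Tests each marker's dosage against the phenotype while accounting for the
#' population's crossing structure with random intercepts for funnel and for
#' cross (eight-way F1 individual) within funnel. Variance components are
#' estimated once under the null mixed model (lme4, maximum likelihood); each
#' marker is then tested with a 1-df likelihood-ratio chi-square conditional
#' on those components, computed by whitened regression — the standard
#' two-stage scheme for genome scans under a fixed covariance. Should the
#' mixed-model fit fail, the scan falls back to funnel strata as fixed
#' effects with per-marker F-tests, and says so in the metadata.
#'
#' Missing genotype dosages are mean-imputed per marker; lines with missing
#' phenotype or strata are dropped. A constant phenotype yields p = 1
#' everywhere with a flag.
#'
#' @param geno Genotype matrix, lines x markers (0/1/2/NA).
#' @param phenotype Named numeric vector over lines (binary traits are
#'   analyzed on the linear scale, as line means).
#' @param strata data.frame with columns \code{line}, \code{funnel},
#'   \code{cross}, as from \code{\link{derive_strata}}.
#' @param map Optional genetic map for chromosome/position annotation.
#' @param covariate_markers Optional marker ids fitted as fixed covariates.
#' @param exclude_markers Optional marker ids not to test (covariates are
#'   always excluded).
#' @param method \code{"lmm"} (default) or \code{"fixed"}.
#' @return An object of class \code{magic_scan}: list with \code{result}
#'   (data.frame: marker, chrom, pos_cM, effect, pvalue, minus_log10_p,
#'   n_called, flag) and \code{meta} (model description, n lines/markers,
#'   variance components, covariates).
#' @export
magic_scan <- function(geno, phenotype, strata, map = NULL,
                       covariate_markers = NULL, exclude_markers = NULL,
                       method = c("lmm", "fixed")) {
  method <- match.arg(method)
  lines <- intersect(rownames(geno),
                     intersect(names(phenotype)[!is.na(phenotype)], strata$line))
  if (length(lines) < 30L)
    stop("fewer than 30 lines with phenotype and strata: scan not attempted")
  y <- as.numeric(phenotype[lines])
  si <- strata[match(lines, strata$line), ]
  funnel <- factor(si$funnel)
  cross <- factor(paste(si$funnel, si$cross, sep = ":"))
  G <- geno[lines, , drop = FALSE]
  test_markers <- setdiff(colnames(G), c(covariate_markers, exclude_markers))
  n <- length(lines)

  n_called <- colSums(!is.na(G[, test_markers, drop = FALSE]))
  X <- .dosage_impute(G[, test_markers, drop = FALSE])
  C <- if (length(covariate_markers))
    .dosage_impute(G[, covariate_markers, drop = FALSE]) else NULL

  flag <- rep("", length(test_markers))
  if (stats::var(y) == 0) {
    res <- .scan_frame(test_markers, map, effect = 0, pvalue = 1,
                       mlp = 0, n_called = n_called,
                       flag = "constant_phenotype")
    return(.scan_object(res, method = "none", n = n, note = "constant phenotype"))
  }

  vc <- NULL
  used_method <- method
  if (method == "lmm") {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(.fit_null_lmm(y, funnel, cross, C))),
      error = function(e) NULL)
    if (is.null(fit)) used_method <- "fixed_fallback" else vc <- fit
  }

  if (used_method == "lmm") {
    wh <- .whiten(vc, funnel, cross)
    X0 <- cbind(`(Intercept)` = rep(1, n), C)
    yw <- wh(y); X0w <- wh(X0); Xw <- wh(X)
    stat <- .marker_lrt(yw, X0w, Xw)
    pv <- stats::pchisq(stat$lrt, df = 1L, lower.tail = FALSE)
    mlp <- -stats::pchisq(stat$lrt, df = 1L, lower.tail = FALSE, log.p = TRUE) / log(10)
  } else {
    X0 <- if (nlevels(funnel) > 1L) cbind(stats::model.matrix(~funnel), C)
          else cbind(`(Intercept)` = rep(1, n), C)
    stat <- .marker_lrt(y, X0, X)
    df2 <- n - qr(X0)$rank - 1L
    Fst <- stat$lrt / ((stat$rss1) / df2) # lrt slot holds RSS0 - RSS1 here
    pv <- stats::pf(Fst, 1L, df2, lower.tail = FALSE)
    mlp <- -stats::pf(Fst, 1L, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  undef <- stat$degenerate
  flag[undef] <- "monomorphic"
  pv[undef] <- NA_real_; mlp[undef] <- NA_real_
  res <- .scan_frame(test_markers, map, effect = stat$beta, pvalue = pv,
                     mlp = mlp, n_called = n_called, flag = flag)
  .scan_object(res, method = used_method, n = n, varcomp = vc$varcomp,
               covariates = covariate_markers)
}

.dosage_impute <- function(G) {
  X <- G
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- cm[nas[, 2L]]
  X
}

.fit_null_lmm <- function(y, funnel, cross, C) {
  dat <- data.frame(y = y, funnel = funnel, cross = cross)
  rhs <- "1"
  if (!is.null(C)) {
    cn <- paste0("cov", seq_len(ncol(C)))
    dat[cn] <- as.data.frame(C)
    rhs <- paste(c("1", cn), collapse = " + ")
  }
  form <- stats::as.formula(paste("y ~", rhs, "+ (1 | funnel) + (1 | cross)"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(form, data = dat, REML = FALSE, control = ctrl)
  v <- as.data.frame(lme4::VarCorr(fit))
  s2 <- stats::setNames(v$vcov, v$grp)
  list(varcomp = c(funnel = unname(s2["funnel"]), cross = unname(s2["cross"]),
                   residual = unname(s2["Residual"])))
}

## Whitening operator for the block covariance
## V = s2f J_funnel + s2c J_cross + s2e I (crosses nested in funnels):
## returns a function mapping vectors/matrices x to V^{-1/2} x.
.whiten <- function(vc, funnel, cross) {
  s2 <- vc$varcomp
  blocks <- split(seq_along(funnel), funnel, drop = TRUE)
  chols <- lapply(blocks, function(ix) {
    k <- length(ix)
    V <- matrix(s2[["funnel"]], k, k)
    cr <- as.character(cross[ix])
    V <- V + s2[["cross"]] * outer(cr, cr, "==")
    diag(V) <- diag(V) + s2[["residual"]]
    chol(V)
  })
  function(x) {
    x <- as.matrix(x)
    out <- x
    for (b in seq_along(blocks)) {
      ix <- blocks[[b]]
      out[ix, ] <- backsolve(chols[[b]], x[ix, , drop = FALSE], transpose = TRUE)
    }
    out
  }
}

## Per-marker regression y ~ X0 + x_m, all markers at once.
## Returns beta, RSS1, and lrt = RSS0 - RSS1 (chi-square under fixed V when
## inputs are whitened; numerator sum of squares for the F-test otherwise).
.marker_lrt <- function(y, X0, X) {
  q0 <- qr(X0)
  ry <- qr.resid(q0, y)
  RX <- qr.resid(q0, X)
  rss0 <- sum(ry^2)
  cp <- as.numeric(crossprod(RX, ry))
  gss <- colSums(RX^2)
  degenerate <- gss < 1e-10
  gss[degenerate] <- NA_real_
  beta <- cp / gss
  dlt <- cp^2 / gss
  list(beta = beta, rss1 = rss0 - dlt, lrt = dlt, degenerate = degenerate,
       rss0 = rss0)
}

.scan_frame <- function(markers, map, effect, pvalue, mlp, n_called, flag) {
  chrom <- rep(NA_character_, length(markers))
  pos <- rep(NA_real_, length(markers))
  if (!is.null(map)) {
    mi <- match(markers, map$marker)
    chrom[!is.na(mi)] <- map$chrom[mi[!is.na(mi)]]
    pos[!is.na(mi)] <- map$pos_cM[mi[!is.na(mi)]]
  }
  data.frame(marker = markers, chrom = chrom, pos_cM = pos,
             effect = effect, pvalue = pvalue, minus_log10_p = mlp,
             n_called = n_called, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

.scan_object <- function(res, method, n, varcomp = NULL, covariates = NULL,
                         note = NULL) {
  out <- list(result = res,
              meta = list(model = "dosage fixed effect + (1|funnel) + (1|cross)",
                          method = method, n_lines = n,
                          n_markers = nrow(res), varcomp = varcomp,
                          covariates = covariates, note = note))
  class(out) <- "magic_scan"
  out
}

#' @export
print.magic_scan <- function(x, ...) {
  cat("MAGIC single-marker association scan\n")
  cat(sprintf("  %d markers, %d lines; method: %s\n",
              x$meta$n_markers, x$meta$n_lines, x$meta$method))
  if (!is.null(x$meta$varcomp))
    cat(sprintf("  variance components: funnel %.4g, cross %.4g, residual %.4g\n",
                x$meta$varcomp[["funnel"]], x$meta$varcomp[["cross"]],
                x$meta$varcomp[["residual"]]))
  if (length(x$meta$covariates))
    cat("  covariate markers:", paste(x$meta$covariates, collapse = ", "), "\n")
  ok <- !is.na(x$result$minus_log10_p)
  if (any(ok)) {
    top <- x$result[ok, ][which.max(x$result$minus_log10_p[ok]), ]
    cat(sprintf("  peak: %s (-log10 p = %.2f%s)\n", top$marker,
                top$minus_log10_p,
                if (!is.na(top$pos_cM)) sprintf(", %s %.2f cM", top$chrom, top$pos_cM) else ""))
  }
  invisible(x)
}

#' @export
summary.magic_scan <- function(object, alpha = 0.01, ...) {
  thr <- bonferroni_threshold(alpha, sum(!is.na(object$result$pvalue)))
  sig <- significant_markers(object, thr)
  cat(sprintf("Bonferroni %.0f%% threshold: -log10 p = %.2f; %d significant marker(s)\n",
              100 * alpha, thr, nrow(sig)))
  if (nrow(sig)) print(utils::head(sig, 10L))
  invisible(sig)
}

#' @export
plot.magic_scan <- function(x, threshold = NULL, ...) {
  res <- x$result[!is.na(x$result$minus_log10_p), ]
  if (all(is.na(res$pos_cM))) {
    graphics::plot(seq_len(nrow(res)), res$minus_log10_p, pch = 16, cex = 0.6,
                   xlab = "marker index", ylab = expression(-log[10](p)), ...)
  } else {
    mapped <- res[!is.na(res$pos_cM), ]
    pm <- concat_map_padded(data.frame(marker = mapped$marker,
                                       chrom = mapped$chrom,
                                       pos_cM = mapped$pos_cM))
    gx <- pm$global_cM[match(mapped$marker, pm$marker)]
    chrom_i <- match(mapped$chrom, sort(unique(mapped$chrom)))
    graphics::plot(gx, mapped$minus_log10_p, pch = 16, cex = 0.6,
                   col = c("grey25", "steelblue")[1L + chrom_i %% 2L],
                   xlab = "padded genome position (cM)",
                   ylab = expression(-log[10](p)), ...)
  }
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red3", lty = 2)
  invisible(x)
}

#' Bonferroni-corrected significance threshold on the -log10 scale
#'
#' \code{-log10(alpha / n_tests)}, reported to two decimals by default
#' (pass \code{digits = NULL} for the unrounded value).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @param digits Decimal places, or NULL for no rounding.
#' @return The threshold on the -log10 p scale.
#' @examples
#' bonferroni_threshold(0.01, 8920)  # 5.95
#' @export
bonferroni_threshold <- function(alpha, n_tests, digits = 2L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  x <- -log10(alpha / n_tests)
  if (is.null(digits)) x else round(x, digits)
}

#' Markers exceeding a significance threshold
#'
#' @param scan A \code{magic_scan}.
#' @param threshold Threshold on the -log10 p scale (strict).
#' @return The scan result rows with \code{minus_log10_p} strictly above the
#'   threshold, sorted in decreasing significance.
#' @export
significant_markers <- function(scan, threshold) {
  res <- scan$result
  keep <- !is.na(res$minus_log10_p) & res$minus_log10_p > threshold
  out <- res[keep, , drop = FALSE]
  out[order(-out$minus_log10_p), , drop = FALSE]
}

#' Support interval around a scan peak
#'
#' The interval spanned by the mapped markers immediately flanking the peak
#' on its chromosome (the markers adjacent in map order). At a chromosome
#' end the interval is one-sided and flagged.
#'
#' @param scan A \code{magic_scan} (used to locate the peak and for marker
#'   annotation).
#' @param map Genetic map.
#' @param peak_marker Peak marker id; defaults to the marker with the largest
#'   \code{minus_log10_p} (ties broken by map order).
#' @return List with \code{peak}, \code{peak_cM}, \code{chrom}, \code{left},
#'   \code{left_cM}, \code{right}, \code{right_cM}, \code{width_cM},
#'   \code{one_sided}.
#' @export
support_interval <- function(scan, map, peak_marker = NULL) {
  res <- scan$result
  if (is.null(peak_marker)) {
    ok <- !is.na(res$minus_log10_p)
    best <- res$minus_log10_p == max(res$minus_log10_p[ok]) & ok
    cand <- res$marker[best]
    cand <- cand[order(match(cand, map$marker))]
    peak_marker <- cand[1L]
  }
  mi <- match(peak_marker, map$marker)
  if (is.na(mi)) stop("peak marker ", peak_marker, " is not on the map")
  ch <- map$chrom[mi]; pp <- map$pos_cM[mi]
  onch <- map[map$chrom == ch, , drop = FALSE]
  left <- onch[onch$pos_cM < pp, , drop = FALSE]
  right <- onch[onch$pos_cM > pp, , drop = FALSE]
  li <- if (nrow(left)) which.max(left$pos_cM) else NA_integer_
  ri <- if (nrow(right)) which.min(right$pos_cM) else NA_integer_
  one_sided <- is.na(li) || is.na(ri)
  if (is.na(li) && is.na(ri))
    warning("single-marker chromosome: support interval undefined")
  list(peak = peak_marker, peak_cM = pp, chrom = ch,
       left = if (!is.na(li)) left$marker[li] else NA_character_,
       left_cM = if (!is.na(li)) left$pos_cM[li] else NA_real_,
       right = if (!is.na(ri)) right$marker[ri] else NA_character_,
       right_cM = if (!is.na(ri)) right$pos_cM[ri] else NA_real_,
       width_cM = if (!one_sided) right$pos_cM[ri] - left$pos_cM[li] else NA_real_,
       one_sided = one_sided)
}

#' Phenotype-by-genotype concordance table for a diagnostic marker
#'
#' Cross-tabulates observed phenotype classes against genotype classes at one
#' marker and counts the lines whose observed phenotype disagrees with the
#' phenotype predicted from their genotype by a diagnostic rule.
#'
#' @param genotype Genotype calls at the marker (0/1/2/NA), named by line.
#' @param phenotype Observed phenotype (0/1/NA), named by line.
#' @param rule Named vector mapping genotype classes to predicted phenotypes,
#'   e.g. \code{c("0" = 0, "1" = 0, "2" = 1)} for a recessive allele-1 trait.
#' @return An object of class \code{concordance_table}: list with
#'   \code{table} (phenotype x genotype counts), \code{discordant},
#'   \code{pct_discordant}, \code{n_classified}, \code{n_excluded}.
#' @export
concordance_table <- function(genotype, phenotype, rule = c("0" = 0, "1" = 0, "2" = 1)) {
  lines <- intersect(names(genotype), names(phenotype))
  g <- genotype[lines]; p <- phenotype[lines]
  ok <- !is.na(g) & !is.na(p)
  gc <- as.character(g[ok])
  if (!all(gc %in% names(rule)))
    stop("rule must map every observed genotype class; missing: ",
         paste(setdiff(unique(gc), names(rule)), collapse = ", "))
  pred <- rule[gc]
  tab <- table(phenotype = factor(p[ok], levels = sort(unique(unname(rule)))),
               genotype = factor(gc, levels = names(rule)))
  disc <- sum(p[ok] != pred)
  out <- list(table = tab, discordant = disc,
              pct_discordant = 100 * disc / sum(ok),
              n_classified = sum(ok),
              n_excluded = length(lines) - sum(ok), rule = rule)
  class(out) <- "concordance_table"
  out
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Diagnostic-marker concordance\n")
  print(x$table)
  cat(sprintf("  discordant: %d of %d classified lines (%.1f%%); %d excluded\n",
              x$discordant, x$n_classified, x$pct_discordant, x$n_excluded))
  invisible(x)
}

#' Rescan with the peak marker as a fixed covariate
#'
#' Repeats the association scan with the peak marker's dosage as a fixed
#' covariate; the peak itself is excluded from testing. With a single causal
#' locus this removes all significant associations.
#'
#' @inheritParams magic_scan
#' @param peak_marker Marker id to condition on.
#' @return A \code{magic_scan} without the peak marker.
#' @export
covariate_rescan <- function(geno, phenotype, strata, peak_marker, map = NULL,
                             method = c("lmm", "fixed")) {
  if (!peak_marker %in% colnames(geno)) stop("peak marker not in genotypes")
  magic_scan(geno, phenotype, strata, map = map,
             covariate_markers = peak_marker, method = match.arg(method))
}
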