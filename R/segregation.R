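#' Segregation model for a monogenic recessive trait under selfing
#'
#' Describes a single recessive gene at allele frequency \code{q} in a
#' random-mated base population, advanced by \code{t} generations of selfing.
#' At the base (t = 0) genotypes are at Hardy-Weinberg proportions; each
#' selfing generation halves heterozygosity, half of the lost heterozygotes
#' becoming recessive homozygotes.
#'
#' @param q Recessive allele frequency in (0, 1).
#' @param t Number of selfing generations (integer >= 0).
#' @return An object of class \code{segregation_model}.
#' @examples
#' expected_ratio(segregation_model(q = 0.125, t = 3))  # 7.98
#' @export
segregation_model <- function(q, t) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  t <- as.integer(t)
  if (t < 0L) stop("t must be a non-negative integer")
  structure(list(q = q, t = t), class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  f <- recessive_class_freq(x)
  cat(sprintf("Recessive trait, q = %.4g, %d selfing generation(s)\n", x$q, x$t))
  cat(sprintf("  recessive-class frequency: %.6f\n", f))
  cat(sprintf("  expected dominant:recessive ratio: %.2f:1\n", (1 - f) / f))
  invisible(x)
}

#' Expected frequency of the recessive phenotypic class
#'
#' With allele frequency \code{q} and \code{t} selfing generations from a
#' random-mated base, heterozygote frequency decays by \code{2^-t} and half
#' of the lost heterozygotes end up recessive homozygotes, so the
#' recessive-class frequency is \code{q^2 + q(1 - q)(1 - 2^-t)}: \code{q^2}
#' at t = 0 (pure random mating) rising to \code{q} in the inbred limit.
#'
#' @param model A \code{segregation_model}.
#' @return Frequency in (0, 1).
#' @export
recessive_class_freq <- function(model) {
  q <- model$q; t <- model$t
  q^2 + q * (1 - q) * (1 - 2^(-t))
}

#' Expected dominant:recessive ratio
#'
#' @param model A \code{segregation_model}.
#' @param digits Decimal places for the displayed ratio (default 2).
#' @return List with \code{ratio} (rounded for display) and
#'   \code{ratio_exact}.
#' @export
expected_ratio <- function(model, digits = 2L) {
  f <- recessive_class_freq(model)
  if (f <= 0) stop("recessive-class frequency is zero: ratio undefined")
  list(ratio = round((1 - f) / f, digits), ratio_exact = (1 - f) / f)
}

#' Observed dominant:recessive ratio
#'
#' @param dominant,recessive Non-negative observed class counts.
#' @param digits Decimal places for the displayed ratio (default 2).
#' @return List with \code{ratio} and \code{ratio_exact}.
#' @export
observed_ratio <- function(dominant, recessive, digits = 2L) {
  if (dominant < 0 || recessive < 0 || dominant + recessive <= 0)
    stop("counts must be non-negative with a positive total")
  if (recessive == 0) stop("no recessive-class individuals: ratio is infinite")
  list(ratio = round(dominant / recessive, digits),
       ratio_exact = dominant / recessive)
}

#' Chi-square goodness of fit of observed class counts to the model
#'
#' Pearson chi-square (1 df, no continuity correction) of the observed
#' dominant/recessive counts against the model-expected two-class split.
#'
#' @param dominant,recessive Observed class counts.
#' @param model A \code{segregation_model}.
#' @return List with \code{statistic}, \code{p_value}, \code{df},
#'   \code{expected} (expected counts).
#' @export
gof_chisq <- function(dominant, recessive, model) {
  n <- dominant + recessive
  if (n <= 0) stop("total count must be positive")
  f <- recessive_class_freq(model)
  expected <- c(dominant = (1 - f) * n, recessive = f * n)
  if (any(expected < 5)) warning("expected class count below 5: chi-square approximation is poor")
  ct <- suppressWarnings(stats::chisq.test(c(dominant, recessive), p = c(1 - f, f)))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), expected = expected)
}
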