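#' Generate a random genetic map
#'
#' Marker positions are drawn uniformly on each chromosome and sorted.
#' With up to 21 chromosomes the hexaploid wheat naming convention is used
#' (1A, 1B, 1D, 2A, ..., 7D); beyond that, chromosomes are numbered.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers per chromosome.
#' @param chromosome_length_cM Chromosome length in centiMorgans.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_cM}, sorted by chromosome then position.
#' @export
generate_map <- function(n_chromosomes, markers_per_chromosome,
                         chromosome_length_cM = 150, seed = 1L) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chromosome_length_cM > 0)
  chroms <- if (n_chromosomes <= 21L)
    paste0(rep(1:7, each = 3L), c("A", "B", "D"))[seq_len(n_chromosomes)]
  else sprintf("chr%02d", seq_len(n_chromosomes))
  .with_seed(seed, {
    maps <- lapply(chroms, function(ch) {
      pos <- sort(stats::runif(markers_per_chromosome, 0, chromosome_length_cM))
      data.frame(marker = sprintf("%s_m%03d", ch, seq_along(pos)),
                 chrom = ch, pos_cM = pos, stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

#' Generate an inbred founder panel over a map
#'
#' Founders are fully homozygous, so each is a single haplotype of biallelic
#' markers coded 0/1. Per marker, the number of founders carrying allele 1 is
#' drawn according to \code{allele_freq_spec}, and the carriers are sampled at
#' random. Founder-private markers (allele 1 in exactly one designated
#' founder, emulating variety-specific SNPs) can be forced via
#' \code{private_allele_spec}.
#'
#' @param map Genetic map from \code{\link{generate_map}}.
#' @param n_founders Number of founders (>= 2); ids default to letters.
#' @param allele_freq_spec Either \code{NULL} (carrier counts uniform on
#'   1..\code{floor(n_founders/2)}), a single fraction in (0,1) (carrier count
#'   \code{round(n * frac)}, at least 1), or an integer vector of per-marker
#'   carrier counts.
#' @param private_allele_spec Optional data.frame with columns \code{marker}
#'   and \code{founder} forcing those markers to carry allele 1 in exactly
#'   that founder.
#' @param seed Integer seed.
#' @return Matrix founders x markers with values in \{0, 1\}; row names are
#'   founder ids, column names marker ids.
#' @export
generate_founders <- function(map, n_founders = 8L, allele_freq_spec = NULL,
                              private_allele_spec = NULL, seed = 1L) {
  n <- as.integer(n_founders)
  if (n < 2L) stop("at least 2 founders are required")
  ids <- .as_founders(n)
  m <- nrow(map)
  counts <- if (is.null(allele_freq_spec)) NULL
  else if (is.function(allele_freq_spec)) as.integer(allele_freq_spec(m))
  else if (length(allele_freq_spec) == 1L && allele_freq_spec > 0 &&
           allele_freq_spec < 1) rep.int(max(1L, as.integer(round(n * allele_freq_spec))), m)
  else as.integer(rep_len(allele_freq_spec, m))
  .with_seed(seed, {
    if (is.null(counts)) counts <- sample.int(max(1L, n %/% 2L), m, replace = TRUE)
    if (any(counts < 1L) || any(counts > n - 1L))
      stop("invalid allele_freq_spec: carrier counts must lie in [1, n_founders - 1] ",
           "(monomorphic markers are not allowed)")
    P <- matrix(0L, n, m, dimnames = list(ids, map$marker))
    for (j in seq_len(m)) P[sample.int(n, counts[j]), j] <- 1L
    if (!is.null(private_allele_spec)) {
      ps <- as.data.frame(private_allele_spec)
      if (!all(c("marker", "founder") %in% names(ps)))
        stop("private_allele_spec needs columns 'marker' and 'founder'")
      if (anyDuplicated(ps$marker))
        stop("invalid private_allele_spec: a marker can be private to only one founder")
      if (!all(ps$marker %in% map$marker)) stop("private marker not on the map")
      if (!all(ps$founder %in% ids)) stop("private founder not in the panel")
      jj <- match(ps$marker, map$marker)
      P[, jj] <- 0L
      P[cbind(match(ps$founder, ids), jj)] <- 1L
    }
    P
  })
}

## Per-marker recombination fractions from a map: Haldane map function between
## adjacent markers, 0.5 at chromosome starts (independent chromosomes and a
## random start haplotype fall out of the same switch process).
.rec_fractions <- function(map) {
  ord_ok <- all(unlist(tapply(map$pos_cM, factor(map$chrom, levels = unique(map$chrom)),
                              function(p) !is.unsorted(p))))
  if (!ord_ok) stop("map is not sorted by position within chromosomes")
  m <- nrow(map)
  r <- numeric(m)
  first <- !duplicated(map$chrom)
  d <- c(0, diff(map$pos_cM))
  r <- (1 - exp(-2 * d / 100)) / 2
  r[first] <- 0.5
  r
}

## Batched meiosis: H1, H2 are k x m parental haplotype matrices (any atomic
## content: alleles or founder indices); returns one gamete per row.
.meiosis_batch <- function(H1, H2, r) {
  k <- nrow(H1); m <- ncol(H1)
  G <- H1
  state <- rep(FALSE, k)
  for (j in seq_len(m)) {
    state <- xor(state, stats::runif(k) < r[j])
    if (any(state)) G[state, j] <- H2[state, j]
  }
  G
}

#' Simulate one gamete from a diploid parent
#'
#' Meiosis under the Haldane (no-interference) map function: recombination
#' between adjacent markers \code{d} cM apart occurs with probability
#' \code{(1 - exp(-2 d / 100)) / 2}, independently across intervals;
#' chromosomes assort independently and the starting haplotype is random.
#'
#' @param parent A list with components \code{h1} and \code{h2}, haplotype
#'   vectors aligned to the map.
#' @param map Genetic map (sorted within chromosomes).
#' @param seed Optional integer seed.
#' @return A haplotype vector of the same length and content type.
#' @export
simulate_gamete <- function(parent, map, seed = NULL) {
  stopifnot(length(parent$h1) == nrow(map), length(parent$h2) == nrow(map))
  r <- .rec_fractions(map)
  .with_seed(seed,
    .meiosis_batch(matrix(parent$h1, 1L), matrix(parent$h2, 1L), r)[1L, ])
}

#' Cross two diploid individuals
#'
#' The offspring receives one independently simulated gamete from each parent.
#'
#' @param parent1,parent2 Diploid individuals (lists with \code{h1},
#'   \code{h2}).
#' @param map Genetic map shared by the parents.
#' @param seed Optional integer seed.
#' @return A diploid individual: list with \code{h1} (from \code{parent1})
#'   and \code{h2} (from \code{parent2}).
#' @export
make_cross <- function(parent1, parent2, map, seed = NULL) {
  .with_seed(seed, list(h1 = simulate_gamete(parent1, map),
                        h2 = simulate_gamete(parent2, map)))
}

#' Self a diploid individual
#'
#' The offspring receives two independent gametes from the same parent.
#'
#' @param line Diploid individual (list with \code{h1}, \code{h2}).
#' @inheritParams make_cross
#' @return A diploid individual.
#' @export
self_cross <- function(line, map, seed = NULL) {
  .with_seed(seed, list(h1 = simulate_gamete(line, map),
                        h2 = simulate_gamete(line, map)))
}

#' Simulate a MAGIC population through the funnel and single seed descent
#'
#' Executes the full crossing scheme: two-way F1s (fully heterozygous where
#' founders differ), four-way individuals, one eight-way F1 per RIL, then
#' \code{ssd_generations} selfings by single seed descent, all under Haldane
#' meiosis. Descent is tracked at the founder level, so every allele in every
#' line traces exactly to the founder carrying it; residual heterozygosity is
#' retained (lines are not forced homozygous).
#'
#' @param plan A \code{cross_plan}.
#' @param pedigree A \code{magic_pedigree} built from the plan.
#' @param founders Founder panel matrix from \code{\link{generate_founders}}
#'   (rows must cover the plan's founders, columns must match the map).
#' @param map Genetic map.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param drop_double_dwarfs Optional list \code{list(markers = c(m1, m2),
#'   allele = 1)}: lines homozygous for the designated allele at both loci are
#'   flagged (mirroring elimination of extreme dwarf lines); off by default.
#' @return An object of class \code{magic_sim}: list with \code{geno}
#'   (lines x markers, 0/1/2 copies of allele 1), \code{mosaic} (list of two
#'   lines x markers integer matrices of founder-of-origin per haplotype),
#'   \code{founder_ids}, \code{map}, \code{pedigree},
#'   \code{het_by_generation} (mean per-line heterozygous fraction, F1
#'   onward) and \code{dropped_dwarfs} (line ids, if requested).
#' @export
simulate_magic <- function(plan, pedigree, founders, map, seed = 1L,
                           drop_double_dwarfs = NULL) {
  if (!all(plan$founders %in% rownames(founders)))
    stop("founder panel does not cover the plan's founders")
  if (!identical(colnames(founders), map$marker))
    stop("founder panel columns must match the map markers, in order")
  fam_ids <- unique(pedigree$family_id)
  if (!all(fam_ids %in% plan$eightways$id))
    stop("pedigree references eight-way families absent from the plan")
  t_ssd <- attr(pedigree, "ssd_generations")
  lines <- pedigree_lines(pedigree)
  fam_of_line <- pedigree$family_id[match(lines, pedigree$line_id)]
  m <- nrow(map)
  r <- .rec_fractions(map)
  fid <- rownames(founders)
  P <- founders[, , drop = FALSE]

  # founder composition of each family: eightway -> 2 fourways -> 4 twoways
  comp <- t(vapply(fam_ids, function(id) {
    fw <- unlist(strsplit(id, "__", fixed = TRUE))
    tw <- unlist(lapply(fw, strsplit, split = "_", fixed = TRUE))
    fs <- unlist(strsplit(unlist(tw), "x", fixed = TRUE))
    match(fs, fid)  # f1..f8 in funnel order: ((f1xf2)x(f3xf4)) x ((f5xf6)x(f7xf8))
  }, integer(8L)))

  .with_seed(seed, {
    nf <- length(fam_ids)
    const <- function(k) matrix(comp[, k], nf, m)
    # four-way plants: one per side of each family's eight-way cross
    plantA_h1 <- .meiosis_batch(const(1L), const(2L), r)
    plantA_h2 <- .meiosis_batch(const(3L), const(4L), r)
    plantB_h1 <- .meiosis_batch(const(5L), const(6L), r)
    plantB_h2 <- .meiosis_batch(const(7L), const(8L), r)
    # eight-way F1, one per RIL
    fi <- match(fam_of_line, fam_ids)
    h1 <- .meiosis_batch(plantA_h1[fi, , drop = FALSE],
                         plantA_h2[fi, , drop = FALSE], r)
    h2 <- .meiosis_batch(plantB_h1[fi, , drop = FALSE],
                         plantB_h2[fi, , drop = FALSE], r)
    het <- numeric(t_ssd + 1L)
    allele <- function(H) matrix(P[cbind(as.vector(H), rep(seq_len(m), each = nrow(H)))],
                                 nrow(H), m)
    het[1L] <- mean(allele(h1) != allele(h2))
    if (t_ssd > 0L) for (g in seq_len(t_ssd)) {
      nh1 <- .meiosis_batch(h1, h2, r)
      nh2 <- .meiosis_batch(h1, h2, r)
      h1 <- nh1; h2 <- nh2
      het[g + 1L] <- mean(allele(h1) != allele(h2))
    }
    A1 <- allele(h1); A2 <- allele(h2)
    geno <- A1 + A2
    dimnames(geno) <- list(lines, map$marker)
    dimnames(h1) <- dimnames(h2) <- list(lines, map$marker)
    dropped <- character()
    if (!is.null(drop_double_dwarfs)) {
      mk <- drop_double_dwarfs$markers
      al <- if (is.null(drop_double_dwarfs$allele)) 1L else drop_double_dwarfs$allele
      hom <- if (al == 1L) geno[, mk, drop = FALSE] == 2L
             else geno[, mk, drop = FALSE] == 0L
      dropped <- lines[rowSums(hom) == length(mk)]
    }
    out <- list(geno = geno,
                mosaic = list(h1 = h1, h2 = h2),
                founder_ids = fid, founders = P, map = map,
                pedigree = pedigree,
                het_by_generation = stats::setNames(het, paste0("F", seq_len(t_ssd + 1L))),
                dropped_dwarfs = dropped, seed = seed)
    class(out) <- "magic_sim"
    out
  })
}

#' @export
print.magic_sim <- function(x, ...) {
  cat("Simulated MAGIC population\n")
  cat(sprintf("  %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat(sprintf("  founders: %s\n", paste(x$founder_ids, collapse = " ")))
  t_ssd <- length(x$het_by_generation) - 1L
  cat(sprintf("  SSD generations: %d (terminal F%d); mean residual heterozygosity %.4f\n",
              t_ssd, t_ssd + 1L, x$het_by_generation[length(x$het_by_generation)]))
  invisible(x)
}

#' Mean founder-of-origin share per founder
#'
#' Fraction of haplotype-marker cells descending from each founder; under the
#' replicated funnel each founder is expected to contribute 1/8.
#'
#' @param sim A \code{magic_sim}.
#' @return Named numeric vector of shares summing to 1.
#' @export
founder_shares <- function(sim) {
  tab <- table(factor(c(sim$mosaic$h1, sim$mosaic$h2),
                      levels = seq_along(sim$founder_ids)))
  stats::setNames(as.numeric(tab) / sum(tab), sim$founder_ids)
}

#' Score a monogenic recessive trait
#'
#' Phenotype is 1 only for lines homozygous for the designated allele at the
#' causal marker; heterozygotes and other homozygotes score 0, and lines with
#' a missing genotype get a missing phenotype.
#'
#' @param x A \code{magic_sim} or a genotype matrix (0/1/2/NA).
#' @param causal_marker Marker id carrying the causal polymorphism.
#' @param carrier_allele The recessive allele (0 or 1; default 1), i.e.
#'   phenotype 1 requires dosage 2 of allele 1 (or 0 of it when
#'   \code{carrier_allele = 0}).
#' @return Named integer vector (0/1/NA) over lines.
#' @export
attach_recessive_trait <- function(x, causal_marker, carrier_allele = 1L) {
  geno <- if (inherits(x, "magic_sim")) x$geno else x
  if (!causal_marker %in% colnames(geno)) stop("causal marker not found")
  g <- geno[, causal_marker]
  if (length(unique(g[!is.na(g)])) < 2L)
    warning("causal marker is monomorphic: the trait will not segregate")
  ph <- if (carrier_allele == 1L) as.integer(g == 2L) else as.integer(g == 0L)
  stats::setNames(ph, rownames(geno))
}

#' Degrade a genotype matrix with missingness and genotyping error
#'
#' Each call is independently set missing with probability
#' \code{missing_rate}; each surviving call is replaced with a uniformly
#' chosen different genotype state with probability \code{error_rate}.
#'
#' @param geno Genotype matrix (0/1/2/NA).
#' @param missing_rate,error_rate Probabilities in [0, 1].
#' @param seed Optional integer seed.
#' @return Degraded genotype matrix of the same shape.
#' @export
degrade <- function(geno, missing_rate = 0, error_rate = 0, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, error_rate >= 0, error_rate <= 1)
  .with_seed(seed, {
    out <- geno
    n <- length(out)
    if (missing_rate > 0) out[stats::runif(n) < missing_rate] <- NA
    if (error_rate > 0) {
      hit <- which(!is.na(out) & stats::runif(n) < error_rate)
      if (length(hit)) {
        shift <- sample.int(2L, length(hit), replace = TRUE)  # 1 or 2 steps mod 3
        out[hit] <- (out[hit] + shift) %% 3L
      }
    }
    out
  })
}

#' Simulate a complete MAGIC study at a chosen scale
#'
#' Convenience wrapper chaining design enumeration, replicated eight-way
#' selection (each four-way used twice), RIL allocation, pedigree
#' construction and forward simulation. Defaults echo the analyzed study
#' scale at desk size: 8 founders, 21 chromosomes of 150 cM, 700 F7 lines.
#'
#' @param n_lines Number of RILs.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_cM Map shape.
#' @param ssd_generations Selfing generations after the eight-way F1.
#' @param allele_freq_spec,private_allele_spec Passed to
#'   \code{\link{generate_founders}}.
#' @param seed Integer seed driving every stochastic step.
#' @return A \code{magic_sim}, with the \code{cross_plan} attached as
#'   \code{$plan}.
#' @export
simulate_magic_study <- function(n_lines = 700L, n_chromosomes = 21L,
                                 markers_per_chromosome = 240L,
                                 chromosome_length_cM = 150,
                                 ssd_generations = 6L,
                                 allele_freq_spec = NULL,
                                 private_allele_spec = NULL, seed = 1L) {
  fw <- enumerate_four_way(8L)
  ew <- enumerate_eight_way(fw)
  plan <- select_replicated_eight_ways(ew, fw, per_fourway_usage = 2L, seed = seed)
  alloc <- allocate_rils(plan$eightways$id, n_lines)
  alloc <- alloc[alloc > 0L]
  ped <- build_pedigree(plan, alloc, ssd_generations)
  map <- generate_map(n_chromosomes, markers_per_chromosome,
                      chromosome_length_cM, seed = seed + 1L)
  panel <- generate_founders(map, 8L, allele_freq_spec, private_allele_spec,
                             seed = seed + 2L)
  sim <- simulate_magic(plan, ped, panel, map, seed = seed + 3L)
  sim$plan <- plan
  sim
}
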