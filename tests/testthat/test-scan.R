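strata200 <- derive_strata(small_sim$pedigree)

test_that("a fully penetrant recessive locus tops the scan and is localized", {
  causal <- small_sim$map$marker[50]  # private to founder A
  ph <- attach_recessive_trait(small_sim, causal)
  sc <- magic_scan(small_sim$geno, ph, strata200, map = small_sim$map)
  expect_s3_class(sc, "magic_scan")
  expect_equal(sc$meta$method, "lmm")
  res <- sc$result
  ok <- !is.na(res$pvalue)
  expect_true(all(res$pvalue[ok] > 0 & res$pvalue[ok] <= 1))
  expect_true(all(res$minus_log10_p[ok] >= 0))
  peak <- res$marker[which.max(res$minus_log10_p)]
  expect_equal(peak, causal)
  thr <- bonferroni_threshold(0.01, sum(ok))
  expect_gt(max(res$minus_log10_p, na.rm = TRUE), thr)
  # the support interval brackets the causal position
  si <- support_interval(sc, small_sim$map)
  expect_equal(si$peak, causal)
  expect_false(si$one_sided)
  expect_lt(si$left_cM, si$peak_cM)
  expect_gt(si$right_cM, si$peak_cM)
  expect_equal(si$width_cM, si$right_cM - si$left_cM)
})

test_that("a constant phenotype yields no associations, flagged", {
  ph <- stats::setNames(rep(1, nrow(small_sim$geno)), rownames(small_sim$geno))
  sc <- magic_scan(small_sim$geno, ph, strata200)
  expect_true(all(sc$result$pvalue == 1))
  expect_true(all(sc$result$flag == "constant_phenotype"))
})

test_that("scan preconditions and monomorphic markers are handled", {
  ph <- attach_recessive_trait(small_sim, small_sim$map$marker[50])
  expect_error(magic_scan(small_sim$geno[1:10, ], ph, strata200),
               "fewer than 30")
  gm <- cbind(small_sim$geno, mono = rep(2L, nrow(small_sim$geno)))
  sc <- magic_scan(gm, ph, strata200)
  row <- sc$result[sc$result$marker == "mono", ]
  expect_true(is.na(row$pvalue))
  expect_equal(row$flag, "monomorphic")
})

test_that("Bonferroni thresholds follow the closed form", {
  expect_equal(bonferroni_threshold(0.01, 8920), 5.95)
  expect_equal(bonferroni_threshold(0.01, 1621), 5.21)
  expect_equal(bonferroni_threshold(0.05, 1), 1.3)
  expect_equal(bonferroni_threshold(0.01, 8920, digits = NULL),
               -log10(0.01 / 8920), tolerance = 1e-12)
  expect_error(bonferroni_threshold(0, 10), "alpha")
})

test_that("significant-marker extraction filters strictly and sorts", {
  sc <- list(result = data.frame(marker = c("a", "b", "c", "d"),
                                 minus_log10_p = c(2, 7, NA, 9)))
  class(sc) <- "magic_scan"
  got <- significant_markers(sc, 5)
  expect_equal(got$marker, c("d", "b"))
  expect_equal(nrow(significant_markers(sc, 10)), 0)
  empty <- list(result = data.frame(marker = character(),
                                    minus_log10_p = numeric()))
  class(empty) <- "magic_scan"
  expect_equal(nrow(significant_markers(empty, 1)), 0)
})

test_that("support intervals span the adjacent mapped flanking markers", {
  map <- data.frame(marker = c("l2", "l1", "peak", "r1", "r2"),
                    chrom = "5A", pos_cM = c(120, 139.76, 140.59, 147.26, 150))
  sc <- list(result = data.frame(marker = map$marker, minus_log10_p = c(1, 5, 9, 4, 1)))
  class(sc) <- "magic_scan"
  si <- support_interval(sc, map)
  expect_equal(si$peak, "peak")
  expect_equal(si$left, "l1"); expect_equal(si$right, "r1")
  expect_equal(si$width_cM, 147.26 - 139.76)
  # immediate neighbours at +/- 1 cM give a 2 cM interval
  map2 <- data.frame(marker = c("a", "b", "c"), chrom = "1A", pos_cM = c(9, 10, 11))
  sc2 <- list(result = data.frame(marker = map2$marker, minus_log10_p = c(1, 8, 2)))
  class(sc2) <- "magic_scan"
  expect_equal(support_interval(sc2, map2)$width_cM, 2)
  # chromosome end: one-sided, flagged
  sc3 <- list(result = data.frame(marker = map2$marker, minus_log10_p = c(8, 2, 1)))
  class(sc3) <- "magic_scan"
  si3 <- support_interval(sc3, map2)
  expect_true(si3$one_sided)
  expect_true(is.na(si3$width_cM))
  # single-marker chromosome: warned, undefined both sides
  map4 <- data.frame(marker = "solo", chrom = "2B", pos_cM = 5)
  sc4 <- list(result = data.frame(marker = "solo", minus_log10_p = 3))
  class(sc4) <- "magic_scan"
  expect_warning(si4 <- support_interval(sc4, map4), "single-marker")
  expect_true(si4$one_sided)
})

test_that("concordance tables count discordant lines against the rule", {
  # a perfectly diagnostic marker
  g <- stats::setNames(c(rep(0, 6), rep(2, 4)), paste0("l", 1:10))
  p <- stats::setNames(c(rep(0, 6), rep(1, 4)), paste0("l", 1:10))
  ct <- concordance_table(g, p)
  expect_equal(ct$discordant, 0)
  # hand count on a toy table with every mismatch type, plus exclusions
  g2 <- stats::setNames(c(0, 0, 1, 2, 2, 2, 0, 1, NA, 2), paste0("l", 1:10))
  p2 <- stats::setNames(c(0, 1, 0, 1, 1, 0, 0, 1, 1, NA), paste0("l", 1:10))
  ct2 <- concordance_table(g2, p2)
  expect_equal(ct2$n_classified, 8)
  expect_equal(ct2$n_excluded, 2)
  expect_equal(ct2$discordant, 3)  # l2 (0->0 but 1), l6 (2->1 but 0), l8 (1->0 but 1)
  expect_equal(ct2$pct_discordant, 100 * 3 / 8)
  expect_error(concordance_table(g2, p2, rule = c("0" = 0, "2" = 1)),
               "every observed genotype class")
})

test_that("conditioning on the causal marker removes the signal", {
  causal <- small_sim$map$marker[50]
  ph <- attach_recessive_trait(small_sim, causal)
  rs <- covariate_rescan(small_sim$geno, ph, strata200, peak_marker = causal,
                         map = small_sim$map)
  expect_false(causal %in% rs$result$marker)   # peak excluded from testing
  expect_equal(rs$meta$covariates, causal)
  thr <- bonferroni_threshold(0.01, nrow(rs$result))
  expect_lt(max(rs$result$minus_log10_p, na.rm = TRUE), thr)
})

test_that("an orthogonal covariate leaves the scan essentially unchanged", {
  causal <- small_sim$map$marker[50]
  ph <- attach_recessive_trait(small_sim, causal)
  # covariate on another chromosome, unlinked to the trait
  cov_mk <- small_sim$map$marker[100]
  expect_true(small_sim$map$chrom[100] != small_sim$map$chrom[50])
  sc0 <- magic_scan(small_sim$geno, ph, strata200, map = small_sim$map)
  sc1 <- magic_scan(small_sim$geno, ph, strata200, map = small_sim$map,
                    covariate_markers = cov_mk)
  shared <- intersect(sc0$result$marker, sc1$result$marker)
  a <- sc0$result$minus_log10_p[match(shared, sc0$result$marker)]
  b <- sc1$result$minus_log10_p[match(shared, sc1$result$marker)]
  ok <- !is.na(a) & !is.na(b)
  expect_gt(stats::cor(a[ok], b[ok], method = "spearman"), 0.95)
})

test_that("funnel stratification controls confounding that a naive scan inherits", {
  # few large families make the family-mean confounding strong
  alloc <- allocate_rils(PLAN8$eightways$id[1:10], 300)
  ped <- build_pedigree(PLAN8, alloc, 6)
  map <- generate_map(2, 30, 120, seed = 881)
  panel <- generate_founders(map, 8, seed = 882)
  sim <- simulate_magic(PLAN8, ped, panel, map, seed = 883)
  strat <- derive_strata(ped)
  fam <- factor(strat$funnel)
  set.seed(314)
  # a strong between-funnel effect with no marker effect
  y <- stats::setNames(rnorm(nlevels(fam), sd = 1.5)[as.integer(fam)] +
                         rnorm(nrow(sim$geno), sd = 0.5),
                       strat$line)
  sc_mixed <- magic_scan(sim$geno, y, strat, map = map)
  naive_strata <- data.frame(line = strat$line, funnel = "all", cross = strat$line)
  sc_naive <- magic_scan(sim$geno, y, naive_strata, map = map)
  t1_mixed <- mean(sc_mixed$result$pvalue < 0.05, na.rm = TRUE)
  t1_naive <- mean(sc_naive$result$pvalue < 0.05, na.rm = TRUE)
  expect_gt(t1_naive, 0.15)              # naive scan inflates badly
  m <- sum(!is.na(sc_mixed$result$pvalue))
  ci <- 1.96 * sqrt(0.05 * 0.95 / m)
  expect_lt(t1_mixed, 0.05 + ci + 0.02)  # stratified scan near nominal
})

test_that("the fixed-effects fallback method produces a usable scan", {
  causal <- small_sim$map$marker[50]
  ph <- attach_recessive_trait(small_sim, causal)
  sc <- magic_scan(small_sim$geno, ph, strata200, map = small_sim$map,
                   method = "fixed")
  expect_equal(sc$meta$method, "fixed")
  expect_equal(sc$result$marker[which.max(sc$result$minus_log10_p)], causal)
})

test_that("exchange formats round-trip", {
  dir <- withr::local_tempdir()
  g <- small_sim$geno[1:10, 1:8]
  write_genotypes(g, file.path(dir, "g.tsv"))
  expect_equal(read_genotypes(file.path(dir, "g.tsv")), g)
  write_map(small_sim$map, file.path(dir, "map.tsv"))
  expect_equal(read_map(file.path(dir, "map.tsv")), small_sim$map,
               tolerance = 1e-9)
  ph <- attach_recessive_trait(small_sim, small_sim$map$marker[50])
  write_phenotype(ph, file.path(dir, "ph.tsv"))
  expect_equal(read_phenotype(file.path(dir, "ph.tsv")), ph)
  write_pedigree(small_sim$pedigree, file.path(dir, "ped.tsv"))
  ped2 <- read_pedigree(file.path(dir, "ped.tsv"))
  expect_equal(attr(ped2, "ssd_generations"), 6)
  expect_equal(as.data.frame(ped2), as.data.frame(small_sim$pedigree))
})
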