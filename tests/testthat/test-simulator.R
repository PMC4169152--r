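test_that("map generation is deterministic with the requested shape", {
  map <- generate_map(21, 100, 150, seed = 1)
  expect_equal(nrow(map), 2100)
  expect_equal(unique(map$chrom), paste0(rep(1:7, each = 3), c("A", "B", "D")))
  expect_true(all(map$pos_cM >= 0 & map$pos_cM <= 150))
  expect_false(is.unsorted(map$pos_cM[map$chrom == "1A"]))
  expect_identical(map, generate_map(21, 100, 150, seed = 1))
  one <- generate_map(1, 1, 80, seed = 3)
  expect_true(one$pos_cM >= 0 && one$pos_cM <= 80)
})

test_that("founder panels are homozygous, biallelic, and honour private alleles", {
  map <- generate_map(2, 30, 100, seed = 2)
  P <- generate_founders(map, 8, seed = 4)
  expect_equal(dim(P), c(8, 60))
  expect_true(all(P %in% c(0L, 1L)))
  counts <- colSums(P)
  expect_true(all(counts >= 1 & counts <= 7))
  # allele frequency spec 1/8: exactly one carrier everywhere
  P1 <- generate_founders(map, 8, allele_freq_spec = 1 / 8, seed = 4)
  expect_true(all(colSums(P1) == 1))
  # private allele forced into the designated founder only
  ps <- data.frame(marker = map$marker[7], founder = "H")
  Pp <- generate_founders(map, 8, private_allele_spec = ps, seed = 4)
  expect_equal(unname(Pp[, map$marker[7]]), c(rep(0L, 7), 1L))
  expect_error(generate_founders(map, 8, allele_freq_spec = 8, seed = 1),
               "monomorphic")
  expect_error(generate_founders(map, 8,
                                 private_allele_spec = data.frame(
                                   marker = map$marker[c(1, 1)],
                                   founder = c("A", "B"))),
               "only one founder")
})

test_that("meiosis respects the map: no recombination at zero distance,
           homozygotes breed true, crossover rate is one per Morgan", {
  # two markers at the same position never recombine
  map0 <- data.frame(marker = c("a", "b"), chrom = "1A", pos_cM = c(10, 10))
  parent <- list(h1 = c(0, 0), h2 = c(1, 1))
  for (s in 1:50) {
    g <- simulate_gamete(parent, map0, seed = s)
    expect_true(all(g == 0) || all(g == 1))
  }
  # homozygous parent: gamete equals the haplotype
  maph <- generate_map(2, 20, 100, seed = 6)
  hom <- list(h1 = rep(1, 40), h2 = rep(1, 40))
  expect_equal(simulate_gamete(hom, maph, seed = 1), rep(1, 40))
  # observed crossovers on a dense 100 cM chromosome: ~1 per gamete
  mapd <- data.frame(marker = sprintf("m%03d", 0:200), chrom = "1A",
                     pos_cM = seq(0, 100, by = 0.5))
  r <- magicwheat:::.rec_fractions(mapd)
  k <- 10000
  H1 <- matrix(1L, k, 201); H2 <- matrix(2L, k, 201)
  set.seed(11)
  G <- magicwheat:::.meiosis_batch(H1, H2, r)
  xo <- rowSums(G[, -1] != G[, -201])
  expect_equal(mean(xo), 1.0, tolerance = 0.03)
  # unsorted map is rejected
  bad <- data.frame(marker = c("a", "b"), chrom = "1A", pos_cM = c(5, 1))
  expect_error(simulate_gamete(parent, bad, seed = 1), "sorted")
})

test_that("crossing and selfing produce Mendelian offspring", {
  map <- generate_map(1, 10, 50, seed = 8)
  inbredA <- list(h1 = rep(0, 10), h2 = rep(0, 10))
  inbredB <- list(h1 = rep(1, 10), h2 = rep(1, 10))
  f1 <- make_cross(inbredA, inbredB, map, seed = 9)
  expect_true(all(f1$h1 + f1$h2 == 1))  # heterozygous wherever parents differ
  selfed <- self_cross(inbredB, map, seed = 10)
  expect_identical(selfed, inbredB)
  # selfing a single heterozygous marker: 1:2:1 within binomial error
  map1 <- data.frame(marker = "m", chrom = "1A", pos_cM = 0)
  r <- magicwheat:::.rec_fractions(map1)
  set.seed(12)
  g1 <- magicwheat:::.meiosis_batch(matrix(0L, 1e4, 1), matrix(1L, 1e4, 1), r)
  g2 <- magicwheat:::.meiosis_batch(matrix(0L, 1e4, 1), matrix(1L, 1e4, 1), r)
  geno <- as.vector(g1 + g2)
  frac <- table(factor(geno, 0:2)) / 1e4
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < 3 * sqrt(0.25 * 0.75 / 1e4) + 0.01))
})

test_that("the funnel simulation tracks descent exactly and is seed-reproducible", {
  sim <- small_sim
  expect_s3_class(sim, "magic_sim")
  expect_equal(dim(sim$geno), c(200, 120))
  expect_true(all(sim$geno %in% 0:2))
  # every allele traces to the founder the mosaic claims
  P <- sim$founders
  m <- ncol(sim$geno)
  A1 <- matrix(P[cbind(as.vector(sim$mosaic$h1), rep(seq_len(m), each = 200))], 200, m)
  A2 <- matrix(P[cbind(as.vector(sim$mosaic$h2), rep(seq_len(m), each = 200))], 200, m)
  expect_identical(unname(sim$geno), A1 + A2)
  # founder-private allele: carriers' mosaic points at that founder
  pm <- sim$map$marker[5]  # private to H (founder index 8)
  carriers <- sim$geno[, pm] > 0
  expect_true(all(sim$mosaic$h1[carriers, pm] == 8 | sim$mosaic$h2[carriers, pm] == 8))
  expect_equal(mean(sim$geno[, pm]) / 2, 0.125, tolerance = 0.35)
  # determinism
  sim2 <- simulate_magic(sim$plan, sim$pedigree, sim$founders, sim$map, seed = 204)
  expect_identical(sim2$geno, sim$geno)
  expect_identical(sim2$mosaic, sim$mosaic)
})

test_that("heterozygosity roughly halves per selfing generation in a small run", {
  h <- small_sim$het_by_generation
  expect_equal(length(h), 7)
  slope <- unname(stats::coef(stats::lm(log2(h) ~ seq_along(h)))[2])
  expect_equal(slope, -1, tolerance = 0.1)
  expect_lt(h["F7"], 0.03)  # F7 residual heterozygosity is small
})

test_that("recessive trait scoring follows strict homozygosity", {
  g <- matrix(c(0, 1, 2, NA), 4, 1, dimnames = list(paste0("l", 1:4), "mk"))
  ph <- attach_recessive_trait(g, "mk")
  expect_equal(unname(ph), c(0, 0, 1, NA))
  ph0 <- attach_recessive_trait(g, "mk", carrier_allele = 0)
  expect_equal(unname(ph0), c(1, 0, 0, NA))
  allhom <- matrix(2, 3, 1, dimnames = list(paste0("l", 1:3), "mk"))
  expect_warning(ph2 <- attach_recessive_trait(allhom, "mk"), "monomorphic")
  expect_true(all(ph2 == 1))
  expect_error(attach_recessive_trait(g, "absent"), "not found")
})

test_that("degradation applies missingness and error at the requested rates", {
  g <- small_sim$geno
  expect_identical(degrade(g, 0, 0, seed = 1), g)
  expect_true(all(is.na(degrade(g, 1, 0, seed = 1))))
  d <- degrade(g, 0.07, 0.02, seed = 2)
  expect_equal(mean(is.na(d)), 0.07, tolerance = 0.01)
  chg <- d != g & !is.na(d)
  expect_lt(abs(mean(chg, na.rm = TRUE) / (1 - 0.07) - 0.02), 0.004)
  expect_true(all(d[chg] != g[chg]))  # errors always move to another state
})
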