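# Shared fixtures, built once per test run.

# full eight-founder design (enumeration is deterministic)
FW8 <- enumerate_four_way(8)
EW8 <- enumerate_eight_way(FW8)
PLAN8 <- select_replicated_eight_ways(EW8, FW8, per_fourway_usage = 2L, seed = 101)

# small simulated population reused across QC/LD/scan unit tests
small_sim <- local({
  alloc <- allocate_rils(PLAN8$eightways$id[1:40], 200)  # 5 RILs per family
  ped <- build_pedigree(PLAN8, alloc, ssd_generations = 6L)
  map <- generate_map(3, 40, 120, seed = 202)
  panel <- generate_founders(map, 8,
                             private_allele_spec = data.frame(
                               marker = map$marker[c(5, 50)],
                               founder = c("H", "A")),
                             seed = 203)
  sim <- simulate_magic(PLAN8, ped, panel, map, seed = 204)
  sim$plan <- PLAN8
  sim
})

# brute-force enumeration oracles, independent of the package's enumerators
oracle_two_way <- function(n) {
  f <- LETTERS[seq_len(n)]
  out <- character()
  for (a in f) for (b in f) if (a < b) out <- c(out, paste(a, b))
  unique(out)
}

oracle_four_way <- function(n) {
  f <- LETTERS[seq_len(n)]
  out <- character()
  if (n < 4) return(out)
  quads <- utils::combn(f, 4, simplify = FALSE)
  for (q in quads) {
    # 3 pairings of 4 founders into two disjoint pairs
    pairings <- list(list(c(q[1], q[2]), c(q[3], q[4])),
                     list(c(q[1], q[3]), c(q[2], q[4])),
                     list(c(q[1], q[4]), c(q[2], q[3])))
    for (p in pairings)
      out <- c(out, paste(sort(c(paste(p[[1]], collapse = ""),
                                 paste(p[[2]], collapse = ""))), collapse = "|"))
  }
  unique(out)
}

# independent LD computation from a raw list of two-locus haplotypes
oracle_ld <- function(hapA, hapB) {
  n <- length(hapA)
  pAB <- mean(hapA == 1 & hapB == 1)
  pA <- mean(hapA == 1); pB <- mean(hapB == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = if (D == 0) 0 else abs(D) / Dmax, r2 = r2)
}
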