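# Brute-force oracles for gamete and offspring distributions, independent of
# the package's closed-form kernels: enumerate every germline conversion
# outcome of a diploid genotype, then every Mendelian allele pick.

# conversion outcomes of one diploid locus genotype: list of (alleles, prob)
oracle_conversion_outcomes <- function(lg, h, r) {
  a <- sort(strsplit(lg, "", fixed = TRUE)[[1]])
  if (identical(a, c("D", "W"))) {
    list(list(alleles = c("D", "D"), p = h),
         list(alleles = c("D", "R"), p = r),
         list(alleles = c("D", "W"), p = 1 - h - r))
  } else {
    list(list(alleles = a, p = 1))
  }
}

oracle_gametes <- function(lg, h, r) {
  out <- c(W = 0, D = 0, R = 0)
  for (st in oracle_conversion_outcomes(lg, h, r)) {
    for (al in st$alleles) out[al] <- out[al] + st$p / 2
  }
  out
}

# offspring distribution at one locus by full enumeration over conversion
# states and the 2x2 Mendelian picks
oracle_offspring_locus <- function(mother_lg, father_lg, h, r) {
  out <- stats::setNames(numeric(6), drivesim::LOCUS_GENOTYPES)
  for (ms in oracle_conversion_outcomes(mother_lg, h, r)) {
    for (fs in oracle_conversion_outcomes(father_lg, h, r)) {
      for (i in 1:2) for (j in 1:2) {
        child <- drivesim::canonical_locus_genotype(
          paste0(ms$alleles[i], fs$alleles[j]))
        out[child] <- out[child] + ms$p * fs$p / 4
      }
    }
  }
  out
}
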