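# Alleles, diploid locus genotypes and gamete/offspring distributions under
# homing conversion and resistance-allele formation.

#' Allele and locus-genotype codes
#'
#' Each target locus carries one of three alleles: `W` (wild type), `D`
#' (drive) or `R` (cleavage-resistant "resistance" allele created by
#' error-prone repair). A diploid locus genotype is an unordered pair of
#' alleles, giving six states.
#'
#' @format Character vectors of allele codes and canonical locus genotypes.
#' @name allele_codes
NULL

#' @rdname allele_codes
#' @export
ALLELES <- c("W", "D", "R")

#' @rdname allele_codes
#' @export
LOCUS_GENOTYPES <- c("WW", "WD", "WR", "DD", "DR", "RR")

#' Canonicalise a locus genotype
#'
#' Locus genotypes are unordered allele pairs; `"DW"` and `"WD"` denote the
#' same state. The canonical form orders alleles `W < D < R`.
#'
#' @param x character vector of two-letter locus genotypes.
#' @return character vector of canonical genotypes (one of
#'   [LOCUS_GENOTYPES]).
#' @export
#' @examples
#' canonical_locus_genotype(c("DW", "RD", "WW"))
canonical_locus_genotype <- function(x) {
  vapply(x, function(g) {
    a <- strsplit(g, "", fixed = TRUE)[[1]]
    if (length(a) != 2L || !all(a %in% ALLELES)) {
      stop("invalid locus genotype: '", g, "'", call. = FALSE)
    }
    paste(a[order(match(a, ALLELES))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a genotype into per-locus canonical form
#'
#' A genotype is an ordered tuple of locus genotypes: two loci for the binary
#' expression designs (locus A = transactivator, locus B = effector), one
#' locus for single-drive designs. Accepts `"WD/WW"` strings or character
#' vectors like `c("WD", "WW")`.
#'
#' @param g genotype as a slash-separated string or character vector.
#' @return character vector of canonical locus genotypes.
#' @export
as_genotype <- function(g) {
  if (length(g) == 1L && grepl("/", g, fixed = TRUE)) {
    g <- strsplit(g, "/", fixed = TRUE)[[1]]
  }
  canonical_locus_genotype(g)
}

check_conversion_rates <- function(h, r) {
  if (length(h) != 1L || length(r) != 1L || is.na(h) || is.na(r) ||
      h < 0 || r < 0 || h > 1 || r > 1 || h + r > 1) {
    stop("homing efficiency and resistance formation must lie in [0,1] with h + r <= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Gamete allele distribution at one locus
#'
#' Homing acts only in drive/wild-type (`WD`) heterozygotes: during
#' gametogenesis the wild-type target is converted to a drive allele with
#' probability `h` (homing efficiency), to a cleavage-resistant allele with
#' probability `r` (resistance-allele formation), and is left intact
#' otherwise; segregation is then Mendelian. All other genotypes segregate
#' Mendelianly; resistance alleles are never re-cut. The resulting marginal
#' gamete probabilities for `WD` are `pW = (1 - h - r)/2`, `pD = (1 + h)/2`,
#' `pR = r/2`.
#'
#' @param locus_genotype a single locus genotype (any allele order).
#' @param h homing efficiency in `[0, 1]`.
#' @param r resistance-allele formation probability, with `h + r <= 1`.
#' @return named numeric vector `c(W=, D=, R=)` summing to 1.
#' @export
#' @examples
#' gamete_distribution("WD", h = 0.9, r = 0.05)
gamete_distribution <- function(locus_genotype, h, r) {
  check_conversion_rates(h, r)
  lg <- canonical_locus_genotype(locus_genotype)
  gamete_matrix(h, r)[lg, ]
}

# 6 x 3 matrix of gamete probabilities, rows LOCUS_GENOTYPES, cols ALLELES
gamete_matrix <- function(h, r) {
  m <- rbind(
    WW = c(1, 0, 0),
    WD = c((1 - h - r) / 2, (1 + h) / 2, r / 2),
    WR = c(0.5, 0, 0.5),
    DD = c(0, 1, 0),
    DR = c(0, 0.5, 0.5),
    RR = c(0, 0, 1)
  )
  colnames(m) <- ALLELES
  m
}

# For allele indices i, j (into ALLELES), index of the unordered genotype in
# LOCUS_GENOTYPES.
pair_index <- local({
  idx <- matrix(0L, 3, 3)
  k <- 0L
  for (i in 1:3) for (j in i:3) {
    k <- k + 1L
    idx[i, j] <- k
    idx[j, i] <- k
  }
  stopifnot(k == 6L)
  idx
})

# 6 x 6 x 6 array: offspring locus-genotype distribution given mother and
# father locus genotypes (rows/cols in LOCUS_GENOTYPES order).
locus_offspring_kernel <- function(h, r) {
  G <- gamete_matrix(h, r)
  K <- array(0, c(6, 6, 6),
             dimnames = list(LOCUS_GENOTYPES, LOCUS_GENOTYPES, LOCUS_GENOTYPES))
  for (gm in 1:6) {
    for (gf in 1:6) {
      p <- outer(G[gm, ], G[gf, ])
      for (i in 1:3) for (j in 1:3) {
        k <- pair_index[i, j]
        K[gm, gf, k] <- K[gm, gf, k] + p[i, j]
      }
    }
  }
  K
}

#' Offspring genotype distribution for a mating pair
#'
#' The exact distribution of offspring genotypes for one mother/father pair:
#' the product over loci (unlinked, independently segregating) of the outer
#' product of the parental gamete distributions, collapsed over allele order.
#' This kernel is both the analytical oracle and the sampling kernel used for
#' aggregated multinomial egg generation in the life cycle.
#'
#' @param mother,father genotypes (see [as_genotype()]); must have the same
#'   number of loci.
#' @inheritParams gamete_distribution
#' @return named numeric vector over offspring genotypes (names like
#'   `"WD/WW"`), summing to 1.
#' @export
#' @examples
#' offspring_distribution("WD", "WW", h = 0.9, r = 0.05)
offspring_distribution <- function(mother, father, h, r) {
  mo <- as_genotype(mother)
  fa <- as_genotype(father)
  if (length(mo) != length(fa)) {
    stop("mother and father must share the same design (locus count)", call. = FALSE)
  }
  K <- locus_offspring_kernel(h, r)
  per_locus <- lapply(seq_along(mo), function(l) K[mo[l], fa[l], ])
  if (length(per_locus) == 1L) {
    return(per_locus[[1]])
  }
  a <- per_locus[[1]]
  b <- per_locus[[2]]
  out <- as.vector(outer(a, b))  # locus A varies fastest
  names(out) <- as.vector(outer(names(a), names(b), paste, sep = "/"))
  out
}

#' Number of distinct drives carried by a genotype
#'
#' Counts the loci at which at least one drive (`D`) allele is present. Used
#' as the exponent of the dominant per-drive unintended costs: each drive a
#' genotype carries imposes its cost once, independent of copy number.
#'
#' @param g a genotype (see [as_genotype()]).
#' @return integer 0, 1 or 2.
#' @export
#' @examples
#' count_drive_types("DD/WW")  # 1
count_drive_types <- function(g) {
  sum(grepl("D", as_genotype(g), fixed = TRUE))
}

# Per-locus drive allele copy number (0, 1, 2) for each canonical genotype.
drive_copies <- c(WW = 0L, WD = 1L, WR = 0L, DD = 2L, DR = 1L, RR = 0L)
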