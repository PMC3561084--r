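#' Simulate biallelic SNP genotypes down a pedigree
#'
#' Founders are drawn in Hardy-Weinberg equilibrium at minor allele
#' frequencies sampled uniformly from `maf_range`; non-founders receive one
#' allele from each parent by Mendelian gene dropping (SNPs are independent,
#' so transmission is Bernoulli(g/2) per parent and locus). Optional
#' genotype missingness is applied uniformly at random.
#'
#' @param pedigree pedigree data frame from [simulate_pedigree()] (all rows,
#'   observed or not, are genotyped; subset afterwards if needed).
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed optional integer seed.
#' @return list with
#'   \item{dosage}{integer matrix individuals x SNPs (0/1/2 copies of the
#'     minor allele, `NA` where missing)}
#'   \item{map}{data frame `snp`, `chr`, `pos`, `ref`, `alt`, `maf` (the
#'     sampled population frequency of the coded ALT allele)}
#' @export
simulate_genotypes <- function(pedigree, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  n <- nrow(pedigree)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- matrix(NA_integer_, n, n_snps, dimnames = list(pedigree$iid, NULL))
  founder <- pedigree$father == "0"
  n_founder <- sum(founder)
  G[founder, ] <- stats::rbinom(n_founder * n_snps, 2L,
                                rep(maf, each = n_founder))
  # gene dropping in pedigree order (parents always precede offspring)
  kids <- which(!founder)
  fa <- match(pedigree$father[kids], pedigree$iid)
  mo <- match(pedigree$mother[kids], pedigree$iid)
  if (any(is.na(fa)) || any(is.na(mo)))
    stop("non-founder with parent missing from the pedigree")
  for (j in seq_along(kids)) {
    from_fa <- stats::rbinom(n_snps, 1L, G[fa[j], ] / 2)
    from_mo <- stats::rbinom(n_snps, 1L, G[mo[j], ] / 2)
    G[kids[j], ] <- from_fa + from_mo
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(G)) < missing_rate
    G[drop] <- NA_integer_
  }
  map <- data.frame(snp = sprintf("snp%05d", seq_len(n_snps)),
                    chr = 1L,
                    pos = seq_len(n_snps) * 1000L,
                    ref = "A", alt = "G",
                    maf = maf, stringsAsFactors = FALSE)
  colnames(G) <- map$snp
  list(dosage = G, map = map)
}
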