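#' The seven-haplotype MHC catalog
#'
#' The crested ibis MHC Core Region carries two polymorphic loci, the class II
#' `DAB` locus (four alleles) and the major class I `UAA` locus (two alleles),
#' that are inherited as a tightly linked block.  Seven multilocus haplotypes
#' (HT01--HT07) are defined by the observed `DAB`--`UAA` allele combinations;
#' the copy-number structure of the class II IIalpha/beta units is determined
#' by the `DAB` allele alone, so each haplotype also carries an ordered set of
#' unit labels.
#'
#' @return A data frame with one row per haplotype and columns
#'   `id` (HT01--HT07), `dab` (`*01`--`*04`), `uaa` (`*01` or `*02`) and
#'   `units` (comma-separated IIalpha/beta unit labels, subset of
#'   DA, DB1, DB2, DB3).
#' @examples
#' mhc_haplotype_catalog()
#' @export
mhc_haplotype_catalog <- function() {
  cat <- data.frame(
    id  = c("HT01", "HT02", "HT03", "HT04", "HT05", "HT06", "HT07"),
    dab = c("*01", "*02", "*03", "*04", "*04", "*02", "*03"),
    uaa = c("*01", "*01", "*02", "*01", "*02", "*02", "*01"),
    units = c("DA,DB1,DB2,DB3", "DA,DB2,DB3", "DA,DB3", "DA", "DA",
              "DA,DB2,DB3", "DA,DB3"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(paste(cat$dab, cat$uaa)))
  cat
}

#' Look up the haplotype carrying a given DAB--UAA allele combination
#'
#' @param dab,uaa single allele labels (e.g. `"*02"`, `"*01"`).
#' @param catalog haplotype catalog, as from [mhc_haplotype_catalog()].
#' @return The haplotype id, or `NA_character_` if the combination is not in
#'   the catalog (one of the eight DAB x UAA combinations, `*01`--`*02`, was
#'   never observed and has no haplotype).
#' @export
haplotype_for_alleles <- function(dab, uaa, catalog = mhc_haplotype_catalog()) {
  i <- which(catalog$dab == dab & catalog$uaa == uaa)
  if (length(i) == 0L) NA_character_ else catalog$id[i]
}

#' Enumerate diplotypes compatible with an unphased two-locus genotype
#'
#' Given unordered allele pairs at `DAB` and `UAA`, lists every unordered pair
#' of catalog haplotypes that would produce exactly that genotype.  Under the
#' seven-haplotype catalog a genotype is compatible with one diplotype (at
#' most one locus heterozygous, or one of the two phase resolutions involves
#' an undefined allele combination) or two (doubly heterozygous with both
#' resolutions defined).
#'
#' @param dab,uaa character vectors of length 2, unordered allele pairs.
#' @param catalog haplotype catalog.
#' @return A list of length-2 character vectors of haplotype ids (each sorted),
#'   possibly empty.
#' @export
compatible_diplotypes <- function(dab, uaa, catalog = mhc_haplotype_catalog()) {
  stopifnot(length(dab) == 2L, length(uaa) == 2L)
  check_allele <- function(a, valid, locus) {
    bad <- setdiff(a, valid)
    if (length(bad))
      stop(sprintf("unknown %s allele(s): %s", locus,
                   paste(bad, collapse = ", ")))
  }
  check_allele(dab, unique(catalog$dab), "DAB")
  check_allele(uaa, unique(catalog$uaa), "UAA")
  # two phase resolutions: (dab1-uaa1, dab2-uaa2) and (dab1-uaa2, dab2-uaa1)
  res <- list(cbind(dab, uaa), cbind(dab, rev(uaa)))
  out <- list()
  for (r in res) {
    h <- c(haplotype_for_alleles(r[1, 1], r[1, 2], catalog),
           haplotype_for_alleles(r[2, 1], r[2, 2], catalog))
    if (!anyNA(h)) out <- c(out, list(sort(h)))
  }
  unique(out)
}
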