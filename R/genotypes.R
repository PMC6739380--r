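#' Genotype state vocabulary
#'
#' The four genotype states used throughout the package.
#'
#' @return Character vector `c("hom_ref", "het", "hom_alt", "missing")`.
#' @export
gt_states <- function() c("hom_ref", "het", "hom_alt", "missing")

#' Build a variant key
#'
#' Variants are identified by `chrom:pos:ref:alt` throughout the package.
#' Keys must be unique within any variant table.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (integer-like).
#' @param ref Reference allele.
#' @param alt Alternate allele.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant table
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (1-based, as in
#'   VCF; biallelic: one alt per row).
#' @param known_id Optional dbSNP-style identifier (`NA` when absent).
#' @return A `data.frame` with columns `chrom, pos, ref, alt, known_id, key`.
#' @export
variant_table <- function(chrom, pos, ref, alt, known_id = NA_character_) {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("variant pos must be >= 1")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  v <- data.frame(chrom = as.character(chrom), pos = pos,
                  ref = as.character(ref), alt = as.character(alt),
                  known_id = rep_len(as.character(known_id), length(chrom)),
                  stringsAsFactors = FALSE)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  if (anyDuplicated(v$key)) {
    stop("duplicate variant key(s): ",
         paste(unique(v$key[duplicated(v$key)]), collapse = ", "))
  }
  v
}

# state from a pair of allele codes (0 = ref, 1 = alt, NA = missing)
state_from_codes <- function(a1, a2) {
  s <- rep("missing", length(a1))
  ok <- !is.na(a1) & !is.na(a2)
  n_alt <- a1 + a2
  s[ok & n_alt == 0L] <- "hom_ref"
  s[ok & n_alt == 1L] <- "het"
  s[ok & n_alt == 2L] <- "hom_alt"
  s
}

#' Is a genotype state a carrier state?
#'
#' Carriers hold at least one alternate allele (`het` or `hom_alt`).
#'
#' @param state Character vector of genotype states.
#' @return Logical vector; `missing` and `hom_ref` are `FALSE`.
#' @export
is_carrier <- function(state) state %in% c("het", "hom_alt")

#' Genotype state matrix
#'
#' Reshape a long genotype table into a variants x samples character matrix of
#' states, the container the segregation caller operates on.
#'
#' @param genotypes Long genotype `data.frame` with columns `key`, `sample_id`,
#'   `state` (as produced by [read_vcf()] or [simulate_cohort()]).
#' @param keys Optional row order (defaults to unique keys in order seen).
#' @param samples Optional column order.
#' @return Character matrix with `dimnames = list(keys, samples)`; pairs not
#'   present in `genotypes` are `"missing"`.
#' @export
genotype_state_matrix <- function(genotypes, keys = NULL, samples = NULL) {
  if (is.null(keys)) keys <- unique(genotypes$key)
  if (is.null(samples)) samples <- unique(genotypes$sample_id)
  m <- matrix("missing", nrow = length(keys), ncol = length(samples),
              dimnames = list(keys, samples))
  i <- match(genotypes$key, keys)
  j <- match(genotypes$sample_id, samples)
  sel <- !is.na(i) & !is.na(j)
  m[cbind(i[sel], j[sel])] <- genotypes$state[sel]
  m
}
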