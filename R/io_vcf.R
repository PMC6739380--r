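#' Read a multi-sample VCF
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a biallelic variant table and a
#' long genotype table. Multiallelic records are split into one biallelic
#' variant per alternate allele with allele-specific alt depths taken from the
#' matching AD entry. FORMAT fields that are absent stay `NA`, never zero.
#'
#' Genotype state is resolved per split record: alleles equal to the focal
#' alternate count as alt, the reference allele as ref, and any other
#' alternate allele of the original record is treated as non-carrier for the
#' focal variant. `depth` is DP when present, else the AD sum.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A list with elements `variants` (see [variant_table()]),
#'   `genotypes` (columns `key, sample_id, state, depth, alt_depth, gq`) and
#'   `samples`.
#' @seealso [write_vcf()] for the matching writer.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_vcf_layout(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)
  samples <- samples[samples != "FORMAT"]

  if (nrow(fix) == 0L) {
    return(list(
      variants = variant_table(character(), integer(), character(), character()),
      genotypes = data.frame(key = character(), sample_id = character(),
                             state = character(), depth = integer(),
                             alt_depth = integer(), gq = numeric(),
                             stringsAsFactors = FALSE),
      samples = samples))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)     # source record per split variant
  aix <- sequence(n_alt)                    # focal alt index within record

  variants <- variant_table(
    chrom = fix$CHROM[rec], pos = fix$POS[rec], ref = fix$REF[rec],
    alt = unlist(alts),
    known_id = ifelse(is.na(fix$ID[rec]) | fix$ID[rec] == ".",
                      NA_character_, fix$ID[rec]))

  nv <- nrow(variants)
  ns <- length(samples)
  long_rec <- rep(rec, each = ns)
  long_aix <- rep(aix, each = ns)
  long_smp <- rep(samples, times = nv)
  long_key <- rep(variants$key, each = ns)

  gt_str <- gt[cbind(long_rec, match(long_smp, samples))]
  codes <- parse_gt_strings(gt_str, long_aix)

  ad_mat <- NULL
  if (!is.null(ad)) {
    ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
    dim(ad_split) <- dim(ad)
  }
  alt_depth <- rep(NA_integer_, length(long_rec))
  depth <- as.integer(dp[cbind(long_rec, match(long_smp, samples))])
  if (!is.null(ad)) {
    for (u in seq_along(long_rec)) {
      v <- ad_split[[long_rec[u], match(long_smp[u], samples)]]
      if (length(v) >= long_aix[u] + 1L && v[1] != ".") {
        a <- suppressWarnings(as.integer(v))
        alt_depth[u] <- a[long_aix[u] + 1L]
        if (is.na(depth[u])) depth[u] <- sum(a, na.rm = TRUE)
      }
    }
  }

  genotypes <- data.frame(
    key = long_key, sample_id = long_smp,
    state = state_from_codes(codes$a1, codes$a2),
    depth = depth, alt_depth = alt_depth,
    gq = as.numeric(gq[cbind(long_rec, match(long_smp, samples))]),
    stringsAsFactors = FALSE)
  bad <- !is.na(genotypes$alt_depth) & !is.na(genotypes$depth) &
    genotypes$alt_depth > genotypes$depth
  if (any(bad)) genotypes$depth[bad] <- genotypes$alt_depth[bad]

  list(variants = variants, genotypes = genotypes, samples = samples)
}

# GT strings like "0/1", "1|2", "./." -> codes relative to focal alt index.
parse_gt_strings <- function(gt_str, focal_alt) {
  parts <- strsplit(ifelse(is.na(gt_str), ".", gt_str), "[/|]")
  a1 <- vapply(parts, function(p) p[1], "")
  a2 <- vapply(parts, function(p) if (length(p) > 1L) p[2] else p[1], "")
  code <- function(a, focal) {
    out <- rep(NA_integer_, length(a))
    num <- suppressWarnings(as.integer(a))
    out[!is.na(num) & num == focal] <- 1L
    out[!is.na(num) & num != focal] <- 0L
    out
  }
  list(a1 = code(a1, focal_alt), a2 = code(a2, focal_alt))
}

# Cheap structural validation so malformed input fails with a line number
# before vcfR sees it.
validate_vcf_layout <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) {
    stop("malformed VCF header in ", path, ": expected exactly one #CHROM line",
         if (length(hdr) == 0L) " (none found)" else
           paste0(" (lines ", paste(hdr, collapse = ", "), ")"))
  }
  ncol_hdr <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  ragged <- body[nf != ncol_hdr]
  if (length(ragged)) {
    stop("ragged VCF record at line ", ragged[1], " of ", path,
         ": ", nf[match(ragged[1], body)], " fields, header has ", ncol_hdr)
  }
  invisible(TRUE)
}

#' Write a multi-sample VCF
#'
#' Deterministic plain-text VCF v4.2 writer for the containers produced by
#' [read_vcf()] and [simulate_cohort()]. Genotypes are emitted as
#' `GT:DP:AD:GQ`; missing values become `.`. Output carries no timestamps, so
#' identical inputs give byte-identical files.
#'
#' @param variants Variant table (see [variant_table()]).
#' @param genotypes Long genotype table (`key, sample_id, state, depth,
#'   alt_depth, gq`).
#' @param path Output path.
#' @param samples Sample column order; defaults to order of appearance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, samples = NULL) {
  if (is.null(samples)) samples <- unique(genotypes$sample_id)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sibseg",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  gt_of <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  g <- genotypes
  i <- match(g$key, variants$key)
  j <- match(g$sample_id, samples)
  cell <- matrix("./.:.:.:.", nrow = nrow(variants), ncol = length(samples))
  ref_depth <- ifelse(is.na(g$depth) | is.na(g$alt_depth), NA_integer_,
                      g$depth - g$alt_depth)
  fmt1 <- paste(
    gt_of[g$state],
    ifelse(is.na(g$depth), ".", g$depth),
    ifelse(is.na(g$alt_depth), ".", paste0(ref_depth, ",", g$alt_depth)),
    ifelse(is.na(g$gq), ".", g$gq),
    sep = ":")
  cell[cbind(i, j)] <- fmt1

  rows <- paste(variants$chrom, variants$pos,
                ifelse(is.na(variants$known_id), ".", variants$known_id),
                variants$ref, variants$alt, ".", "PASS", ".", "GT:DP:AD:GQ",
                sep = "\t")
  if (length(samples)) {
    rows <- paste(rows, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
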