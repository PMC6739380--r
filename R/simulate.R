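#' Synthetic cohort configuration
#'
#' Defaults mirror the discordant-sibling study design the package targets:
#' four unrelated families, one affected sibling each, five non-affected
#' siblings in total (one family contributes two), exome-like depth around
#' 105x, and segregating variants planted to be confirmed in exactly three of
#' the four families and absent from the opposite phenotype group.
#'
#' @param n_families Number of families (default 4).
#' @param affected_per_family,nonaffected_per_family Sibling counts per
#'   family (scalar or vector of length `n_families`; defaults 1 and
#'   `c(2, 1, 1, 1)`).
#' @param n_background Number of Hardy-Weinberg background variants
#'   (default 500).
#' @param freq_range Uniform range for background alternate-allele
#'   frequencies (default `c(0.05, 0.5)`; the alternate allele is the minor
#'   allele except for reference-minor-fated variants, which draw from
#'   `c(0.55, 0.95)`).
#' @param planted Named integer vector: planted segregating variants per
#'   (model, group) combination.
#' @param k_planted Families in which each planted variant satisfies its
#'   model (default 3).
#' @param missingness Per-call missing-genotype probability (default 0).
#' @param depth_mean,depth_size Negative-binomial read-depth parameters
#'   (mean 105, size 8).
#' @param gq_high,gq_low Genotype qualities assigned to normal and
#'   low-quality-fated calls (90 and 5).
#' @param stage_fractions Named fractions of background variants fated to die
#'   at each cascade stage; the remainder survive. Proportions echo a typical
#'   exome flowchart (about a quarter on unconfirmed transcripts, a fifth in
#'   UTRs, half of annotated variants synonymous).
#' @param novel_frac Fraction of background variants with no catalogue id and
#'   no GMAF (default 0.05).
#' @param n_decoy_sets,set_size Gene-set collection shape: decoy sets of
#'   `set_size` random genes plus one planted pathway containing every
#'   planted gene (default 19 decoys of 15 genes).
#' @param seed Mandatory integer seed; everything downstream is reproducible
#'   from it.
#' @return A list of class `sibseg_sim_config`.
#' @export
sim_config <- function(n_families = 4,
                       affected_per_family = 1,
                       nonaffected_per_family = c(2, 1, 1, 1),
                       n_background = 500,
                       freq_range = c(0.05, 0.5),
                       planted = c(recessive_affected = 3,
                                   dominant_affected = 3,
                                   recessive_non_affected = 3,
                                   dominant_non_affected = 3),
                       k_planted = 3,
                       missingness = 0,
                       depth_mean = 105, depth_size = 8,
                       gq_high = 90, gq_low = 5,
                       stage_fractions = c(low_quality = 0.05,
                                           unconfirmed = 0.25,
                                           utr = 0.18,
                                           unannotated = 0.02,
                                           low_alt_cov = 0.08,
                                           synonymous = 0.25,
                                           ref_minor = 0.05),
                       novel_frac = 0.05,
                       n_decoy_sets = 19, set_size = 15,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (k_planted > n_families) stop("infeasible: k_planted > n_families")
  if (sum(stage_fractions) > 1) stop("stage_fractions must sum to <= 1")
  affected_per_family <- rep_len(affected_per_family, n_families)
  nonaffected_per_family <- rep_len(nonaffected_per_family, n_families)
  if (any(affected_per_family < 1) || any(nonaffected_per_family < 1)) {
    stop("the discordant design needs >= 1 sibling per phenotype per family")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sibseg_sim_config"
  cfg
}

sim_pedigree <- function(cfg) {
  rows <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- paste0("F", f)
    ids <- c(paste0(fam, "_A", seq_len(cfg$affected_per_family[f])),
             paste0(fam, "_U", seq_len(cfg$nonaffected_per_family[f])))
    ph <- c(rep("affected", cfg$affected_per_family[f]),
            rep("non_affected", cfg$nonaffected_per_family[f]))
    rows[[f]] <- data.frame(family_id = fam, individual_id = ids,
                            sex = rep_len(c("2", "1"), length(ids)),
                            phenotype = ph, stringsAsFactors = FALSE)
  }
  as_pedigree(do.call(rbind, rows))
}

#' Simulate a discordant-sibling exome cohort with ground truth
#'
#' Generates a multi-sample genotype cohort in which background variants are
#' drawn per individual from Hardy-Weinberg proportions at a variant-specific
#' allele frequency, planted variants are forced to satisfy their
#' (model, group) specification in `k_planted` families and fail it both in
#' the remaining family and throughout the opposite group, and annotations
#' are constructed so that a configured fraction of background variants dies
#' at each cascade stage. The returned truth manifest records, for every
#' emitted variant, its category, planted specification and realized filter
#' fate (the first cascade stage whose predicate its drawn data fails,
#' re-derived per variant from the construction - so a background variant
#' that happens to draw no alternate alleles is honestly fated to the
#' quality stage).
#'
#' @param config A [sim_config()].
#' @return An object of class `sibseg_sim`: list with `variants`, `genotypes`
#'   (long table), `states` (matrix), `pedigree`, `annotations`, `genesets`,
#'   `curated_genes` (the planted genes, usable as a curated-list stand-in),
#'   `manifest` (`key, gene, category, model, group, families, fate`) and
#'   `config`.
#' @seealso [write_cohort()] to materialize the standard file formats.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  ped <- sim_pedigree(cfg)
  samples <- ped$individual_id
  ns <- length(samples)
  fams <- unique(ped$family_id)

  combos <- data.frame(
    model = sub("_(affected|non_affected)$", "", names(cfg$planted)),
    group = sub("^(recessive|dominant)_", "", names(cfg$planted)),
    n = as.integer(cfg$planted), stringsAsFactors = FALSE)
  if (!all(combos$model %in% c("recessive", "dominant")) ||
      !all(combos$group %in% c("affected", "non_affected"))) {
    stop("planted names must be <model>_<group>")
  }
  n_pl <- sum(combos$n)
  nv <- cfg$n_background + n_pl

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- variant_table(
    chrom = paste0("chr", 1 + (seq_len(nv) - 1) %% 22),
    pos = 10000L + seq_len(nv) * 13L,
    ref = ref, alt = alt,
    known_id = sprintf("rs%06d", 100000L + seq_len(nv)))
  genes <- sprintf("GENE%04d", seq_len(nv))

  is_planted <- c(rep(FALSE, cfg$n_background), rep(TRUE, n_pl))
  fate_names <- names(cfg$stage_fractions)
  fate <- rep("survive", nv)
  if (cfg$n_background > 0) {
    fate[!is_planted] <- sample(
      c(fate_names, "survive"), cfg$n_background, replace = TRUE,
      prob = c(cfg$stage_fractions, 1 - sum(cfg$stage_fractions)))
  }
  novel <- !is_planted & runif(nv) < cfg$novel_frac
  variants$known_id[novel] <- NA_character_

  f_alt <- runif(nv, cfg$freq_range[1], cfg$freq_range[2])
  f_alt[fate == "ref_minor"] <- runif(sum(fate == "ref_minor"), 0.55, 0.95)

  # genotype codes 0/1/2 (alt-allele count), HWE iid per individual
  codes <- matrix(NA_integer_, nv, ns, dimnames = list(variants$key, samples))
  bg <- which(!is_planted)
  if (length(bg)) {
    codes[bg, ] <- rbinom(length(bg) * ns, 2L, rep(f_alt[bg], ns))
  }

  # planted variants: forced genotype patterns
  manifest_model <- manifest_group <- manifest_fams <- rep(NA_character_, nv)
  pi <- cfg$n_background
  for (ci in seq_len(nrow(combos))) {
    for (r in seq_len(combos$n[ci])) {
      pi <- pi + 1L
      model <- combos$model[ci]
      group <- combos$group[ci]
      conf <- sort(sample(fams, cfg$k_planted))
      grp_cols <- ped$individual_id[ped$phenotype == group]
      opp_cols <- setdiff(samples, grp_cols)
      codes[pi, opp_cols] <- 0L
      for (fam in fams) {
        memb <- intersect(grp_cols,
                          ped$individual_id[ped$family_id == fam])
        codes[pi, memb] <- if (fam %in% conf) {
          if (model == "recessive") 2L else 1L
        } else {
          if (model == "recessive") 1L else 0L
        }
      }
      manifest_model[pi] <- model
      manifest_group[pi] <- group
      manifest_fams[pi] <- paste(conf, collapse = ",")
    }
  }

  if (cfg$missingness > 0) {
    drop <- matrix(runif(nv * ns) < cfg$missingness, nv, ns)
    codes[drop] <- NA_integer_
  }

  # depths, alt depths, genotype qualities
  depth <- matrix(rnbinom(nv * ns, size = cfg$depth_size, mu = cfg$depth_mean),
                  nv, ns)
  alt_depth <- matrix(0L, nv, ns)
  het <- which(codes == 1L)
  alt_depth[het] <- rbinom(length(het), depth[het], 0.5)
  hom <- which(codes == 2L)
  alt_depth[hom] <- depth[hom]
  alt_depth[is.na(codes)] <- NA_integer_
  depth[is.na(codes)] <- NA_integer_
  gq <- matrix(cfg$gq_high, nv, ns)
  gq[fate == "low_quality", ] <- cfg$gq_low
  gq[is.na(codes)] <- NA_real_

  # force stage-specific evidence
  lac <- which(fate == "low_alt_cov")
  if (length(lac)) {
    depth[lac, ] <- pmin(depth[lac, ], 28L)
    alt_depth[lac, ] <- pmin(alt_depth[lac, ], depth[lac, ])
  }
  need_cov <- which(fate %in% c("synonymous", "ref_minor", "survive"))
  for (i in need_cov) {
    carriers <- which(!is.na(codes[i, ]) & codes[i, ] >= 1L)
    if (!length(carriers)) next
    j <- carriers[which.max(alt_depth[i, carriers])]
    if (is.na(alt_depth[i, j]) || alt_depth[i, j] <= 30L) {
      alt_depth[i, j] <- 35L
      depth[i, j] <- max(depth[i, j], 70L, na.rm = TRUE)
    }
  }

  # annotations (unannotated-fated variants are left out)
  nonsyn_terms <- c("nonsynonymous SNV", "stopgain", "stoploss",
                    "frameshift deletion", "nonframeshift insertion")
  consequence <- sample(nonsyn_terms, nv, replace = TRUE,
                        prob = c(0.9, 0.03, 0.02, 0.03, 0.02))
  consequence[fate == "synonymous"] <- "synonymous SNV"
  ann <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, known_id = variants$known_id, gene = genes,
    transcript_status = ifelse(fate == "unconfirmed", "unconfirmed",
                               "confirmed"),
    region = ifelse(fate == "utr", rep_len(c("utr3", "utr5"), nv), "coding"),
    consequence = consequence,
    gmaf = round(pmin(f_alt, 1 - f_alt), 4),
    alt_pop_freq = round(f_alt, 4),
    cadd = round(runif(nv, 0, 40), 2),
    dann = round(runif(nv), 3),
    provean = round(runif(nv, -10, 2), 2),
    stringsAsFactors = FALSE)
  ann$gmaf[novel] <- NA_real_
  ann$key <- variants$key
  ann$novel <- is.na(ann$gmaf) & is.na(ann$known_id)
  ann <- ann[fate != "unannotated", , drop = FALSE]

  realized <- vapply(seq_len(nv), function(i) {
    ai <- match(variants$key[i], ann$key)
    realized_fate(codes[i, ], gq[i, ], alt_depth[i, ],
                  if (is.na(ai)) NULL else ann[ai, ])
  }, "")

  manifest <- data.frame(
    key = variants$key, gene = genes,
    category = ifelse(is_planted, "planted", "background"),
    model = manifest_model, group = manifest_group,
    families = manifest_fams, fate = realized, stringsAsFactors = FALSE)

  # gene sets: decoys plus one pathway holding every planted gene
  gs <- list()
  for (s in seq_len(cfg$n_decoy_sets)) {
    g <- sort(sample(genes, min(cfg$set_size, nv)))
    attr(g, "description") <- paste("decoy pathway", s)
    gs[[sprintf("PATHWAY_%03d", s)]] <- g
  }
  # the planted pathway's padding comes from genes whose variants do not
  # survive the cascade, so its true overlap with the post-cascade universe
  # is exactly the planted genes: the enrichment effect size is the full
  # planted gene count
  planted_genes <- genes[is_planted]
  fill <- setdiff(genes[realized != "survive"], planted_genes)
  if (!length(fill)) fill <- setdiff(genes, planted_genes)
  pg <- sort(unique(c(planted_genes,
                      sample(fill, min(length(fill),
                                       max(0, cfg$set_size - length(planted_genes)))))))
  attr(pg, "description") <- "planted enriched pathway"
  gs[["PATHWAY_PLANTED"]] <- pg

  states <- matrix(c("hom_ref", "het", "hom_alt")[codes + 1L], nv, ns,
                   dimnames = dimnames(codes))
  states[is.na(codes)] <- "missing"

  genotypes <- data.frame(
    key = rep(variants$key, ns),
    sample_id = rep(samples, each = nv),
    state = as.vector(states),
    depth = as.vector(depth),
    alt_depth = as.vector(alt_depth),
    gq = as.vector(gq),
    stringsAsFactors = FALSE)

  out <- list(variants = variants, genotypes = genotypes, states = states,
              pedigree = ped, annotations = ann, genesets = gs,
              curated_genes = planted_genes, manifest = manifest,
              allele_freq = setNames(f_alt, variants$key), config = cfg)
  class(out) <- "sibseg_sim"
  out
}

# First cascade stage a variant's drawn data fails, derived from the raw
# per-variant evidence (scalar bookkeeping, independent of the cascade code).
realized_fate <- function(codes, gq, alt_depth, ann,
                          gq_floor = 20, alt_cov = 30) {
  carrier <- !is.na(codes) & codes >= 1L & !is.na(gq) & gq >= gq_floor
  if (!any(carrier)) return("drop_low_quality")
  if (!is.null(ann) && ann$transcript_status == "unconfirmed") {
    return("drop_unconfirmed_transcript")
  }
  if (!is.null(ann) && ann$region != "coding") return("drop_utr")
  if (is.null(ann)) return("functionally_annotated")
  ad <- alt_depth[carrier]
  if (any(!is.na(ad)) && max(ad, na.rm = TRUE) <= alt_cov) {
    return("high_confidence")
  }
  if (normalize_consequence(ann$consequence) == "synonymous") {
    return("non_synonymous")
  }
  if (!is.na(ann$alt_pop_freq) && ann$alt_pop_freq > 0.5) {
    return("drop_minor_in_reference")
  }
  "survive"
}

#' @export
print.sibseg_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d variants (%d planted), %d samples in %d families [seed %d]\n",
              nrow(x$variants), sum(x$manifest$category == "planted"),
              nrow(x$pedigree), length(unique(x$pedigree$family_id)),
              x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to standard file formats
#'
#' Materializes a [simulate_cohort()] result as the pipeline's inputs: a
#' multi-sample VCF, a 6-column PED, an annotation TSV, a GMT, a curated
#' gene list, the truth-manifest TSV, and a JSON run descriptor embedding the
#' full configuration. All outputs are deterministic given the seed.
#'
#' @param sim A `sibseg_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    curated = file.path(dir, "curated_genes.txt"),
    manifest = file.path(dir, "truth_manifest.tsv"),
    config = file.path(dir, "sim_config.json"))
  write_vcf(sim$variants, sim$genotypes, paths["vcf"],
            samples = sim$pedigree$individual_id)
  write_pedigree(sim$pedigree, paths["ped"])
  write_annotations(sim$annotations, paths["annotations"])
  write_genesets(sim$genesets, paths["gmt"])
  writeLines(sim$curated_genes, paths["curated"])
  utils::write.table(sim$manifest, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
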