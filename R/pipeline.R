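#' Pipeline configuration
#'
#' Collects input paths and the thresholds of every stage. Defaults match the
#' package-wide conventions: genotype-quality floor 20, strict alternate
#' coverage 30, rare-variant GMAF ceiling 1\%, k = 3 family confirmation,
#' same-model exclusivity, q <= 0.05 enrichment cutoff with overlap
#' similarity 0.375.
#'
#' @param vcf,ped,annotations,gmt,curated Input file paths (`curated` may be
#'   `NULL`).
#' @param out_dir Output directory for all intermediates and the report.
#' @param gq_floor,alt_cov,gmaf_rare QC thresholds.
#' @param k,exclusivity,member_rule Segregation settings (see [seg_config()]).
#' @param q_cutoff,similarity_cutoff,similarity_metric Enrichment settings.
#' @param min_set_size,max_set_size ORA set-size window.
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic; the seed covers any future resampling extension).
#' @return A list of class `sibseg_run_config`.
#' @export
pipeline_config <- function(vcf, ped, annotations, gmt = NULL, curated = NULL,
                            out_dir = "sibseg_run",
                            gq_floor = 20, alt_cov = 30, gmaf_rare = 0.01,
                            k = 3, exclusivity = "same_model",
                            member_rule = "all",
                            q_cutoff = 0.05, similarity_cutoff = 0.375,
                            similarity_metric = "overlap",
                            min_set_size = 3, max_set_size = 500,
                            seed = 1L) {
  for (p in c(vcf, ped, annotations, gmt, curated)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  cfg <- list(vcf = vcf, ped = ped, annotations = annotations, gmt = gmt,
              curated = curated, out_dir = out_dir, gq_floor = gq_floor,
              alt_cov = alt_cov, gmaf_rare = gmaf_rare, k = k,
              exclusivity = exclusivity, member_rule = member_rule,
              q_cutoff = q_cutoff, similarity_cutoff = similarity_cutoff,
              similarity_metric = similarity_metric,
              min_set_size = min_set_size, max_set_size = max_set_size,
              seed = as.integer(seed))
  class(cfg) <- "sibseg_run_config"
  cfg
}

#' Run the full prioritization pipeline
#'
#' Orchestrates the whole workflow: read inputs, apply the filter cascade,
#' call segregating variants in both phenotype groups under both inheritance
#' models, summarize per (group, model) against the curated gene list, run
#' over-representation analysis per group (universe = genes with at least one
#' post-cascade variant), and build enrichment maps. All intermediates are
#' written under `config$out_dir` as TSV (plus SIF networks and a JSON echo of
#' the effective configuration); a deterministic text report renders the
#' results.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `sibseg_report`: list with `qc`, `trace`,
#'   `calls`, `summary`, `enrichment` (per group), `maps` (per group),
#'   `config`, `files` (paths written), `version`.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[sibseg] ", ...)

  log_stage("reading inputs")
  cohort <- read_vcf(config$vcf)
  ped <- read_pedigree(config$ped)
  ann <- read_annotations(config$annotations)
  genesets <- if (!is.null(config$gmt)) read_genesets(config$gmt) else NULL
  curated <- if (!is.null(config$curated)) read_gene_list(config$curated)
             else character()

  log_stage("filter cascade on ", nrow(cohort$variants), " variants")
  cc <- cascade_config(gq_floor = config$gq_floor, alt_cov = config$alt_cov)
  filt <- run_filter_cascade(cohort$variants, cohort$genotypes, ann, cc)

  depth_mat <- NULL
  if (nrow(cohort$variants)) {
    dm <- cohort$genotypes
    depth_mat <- matrix(NA_real_, nrow(cohort$variants), length(cohort$samples),
                        dimnames = list(cohort$variants$key, cohort$samples))
    depth_mat[cbind(match(dm$key, rownames(depth_mat)),
                    match(dm$sample_id, colnames(depth_mat)))] <- dm$depth
  }
  qc <- qc_report(depth_mat, titv = titv_ratio(cohort$variants))

  log_stage("segregation (k=", config$k, ", exclusivity=", config$exclusivity, ")")
  scfg <- seg_config(k = config$k, exclusivity = config$exclusivity,
                     member_rule = config$member_rule)
  genes_of <- setNames(ann$gene, ann$key)
  calls <- if (length(filt$surviving)) {
    states <- genotype_state_matrix(filt$genotypes, keys = filt$surviving,
                                    samples = ped$individual_id)
    segregate(states, ped, scfg, genes = genes_of)
  } else {
    segregate(matrix("missing", 0, nrow(ped),
                     dimnames = list(NULL, ped$individual_id)), ped, scfg)
  }
  summary_tab <- summarize_calls(calls, curated)

  enrichment <- list()
  maps <- list()
  if (!is.null(genesets)) {
    universe <- unique(genes_of[filt$surviving])
    universe <- universe[!is.na(universe)]
    for (g in c("affected", "non_affected")) {
      q_genes <- unique(calls$gene[calls$group == g & !is.na(calls$gene)])
      if (!length(q_genes) || !length(universe)) next
      log_stage("enrichment for ", g, " (", length(q_genes), " genes)")
      res <- run_ora(q_genes, genesets, universe,
                     min_size = config$min_set_size,
                     max_size = config$max_set_size)
      enrichment[[g]] <- res
      maps[[g]] <- build_enrichment_map(res, genesets,
                                        q_cutoff = config$q_cutoff,
                                        similarity_cutoff = config$similarity_cutoff,
                                        metric = config$similarity_metric)
    }
  }

  files <- c(trace = file.path(config$out_dir, "filter_trace.tsv"),
             calls = file.path(config$out_dir, "segregation_calls.tsv"),
             summary = file.path(config$out_dir, "group_summary.tsv"),
             config = file.path(config$out_dir, "run_config.json"),
             report = file.path(config$out_dir, "report.txt"))
  write_filter_trace(filt, files["trace"])
  write_calls(calls, files["calls"])
  utils::write.table(summary_tab, files["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (g in names(enrichment)) {
    ep <- file.path(config$out_dir, paste0("enrichment_", g, ".tsv"))
    write_enrichment(enrichment[[g]], ep)
    files[paste0("enrichment_", g)] <- ep
    sp <- file.path(config$out_dir, paste0("network_", g, ".sif"))
    write_sif(maps[[g]], sp)
    files[paste0("network_", g)] <- sp
  }
  jsonlite::write_json(unclass(config), files["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  report <- list(qc = qc, trace = filt$trace, counters = filt$counters,
                 calls = calls, summary = summary_tab,
                 enrichment = enrichment, maps = maps, config = config,
                 files = files,
                 version = as.character(utils::packageVersion("sibseg")))
  class(report) <- "sibseg_report"
  writeLines(report_render(report), files["report"])
  report
}

#' Render a run report as text
#'
#' Deterministic plain-text rendering: the same report object always gives
#' identical bytes. Summary percentages print as integers; breakdown-style
#' fractions with one decimal.
#'
#' @param report A `sibseg_report`.
#' @return Character vector of lines.
#' @export
report_render <- function(report) {
  ln <- c(paste0("sibseg run report (package version ", report$version, ")"),
          "")
  ln <- c(ln, "== Coverage QC ==")
  if (!is.na(report$qc$mean_depth)) {
    ln <- c(ln, sprintf("mean depth %.1f | >=20X fraction %s%% | uniformity %s%%",
                        report$qc$mean_depth,
                        fmt_pct(report$qc$frac_min_cov, 1, 1),
                        fmt_pct(report$qc$uniformity, 1, 1)),
            paste0("uniformity definition: ", report$qc$uniformity_definition))
  } else {
    ln <- c(ln, "no depth data")
  }
  tv <- report$qc$titv
  ln <- c(ln, if (!is.null(tv) && !is.na(tv))
    sprintf("Ti/Tv %.2f (%d transitions / %d transversions)",
            as.numeric(tv), attr(tv, "ti"), attr(tv, "tv"))
    else "Ti/Tv undefined (no transversions)")

  ln <- c(ln, "", "== Filter cascade ==")
  total <- report$trace$remaining[1]
  for (i in seq_len(nrow(report$trace))) {
    ln <- c(ln, sprintf("%-28s [%d]%s", report$trace$stage[i],
                        report$trace$remaining[i],
                        if (report$trace$removed[i] > 0)
                          sprintf(" removed %d", report$trace$removed[i])
                        else ""))
  }

  ln <- c(ln, "", "== Segregation summary ==",
          sprintf("k = %d, exclusivity = %s, member rule = %s",
                  report$config$k, report$config$exclusivity,
                  report$config$member_rule))
  if (nrow(report$summary)) {
    for (i in seq_len(nrow(report$summary))) {
      s <- report$summary[i, ]
      ln <- c(ln, sprintf("%s / %s: %d genes, %d variants, curated %d (%s%%)",
                          s$group, s$model, s$n_genes, s$n_variants,
                          s$n_curated, fmt_pct(s$n_curated, s$n_genes, 0)))
    }
  } else {
    ln <- c(ln, "no segregating variants called")
  }

  for (g in names(report$enrichment)) {
    res <- report$enrichment[[g]]
    ln <- c(ln, "", paste0("== Enrichment: ", g, " =="))
    top <- utils::head(res, 5)
    if (nrow(top)) {
      ln <- c(ln, sprintf("%s k=%d/%d p=%.3g q=%.3g", top$set_id, top$k,
                          top$K, top$p, top$q))
    } else {
      ln <- c(ln, "no sets tested")
    }
    m <- report$maps[[g]]
    if (!is.null(m)) {
      ln <- c(ln, sprintf("map: %d node(s), %d edge(s) (%s >= %.3f, q <= %g)",
                          nrow(m$nodes), nrow(m$edges), m$metric,
                          m$similarity_cutoff, m$q_cutoff))
    }
  }
  ln
}

#' @export
print.sibseg_report <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}
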