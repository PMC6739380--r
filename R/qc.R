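#' Consequence term dictionary
#'
#' Shipped synonym dictionary mapping annotation consequence vocabulary
#' (ANNOVAR- and Sequence-Ontology-style terms) onto the seven consequence
#' classes used by the cascade: `synonymous, missense, nonsense, frameshift,
#' inframe, stop_loss, stop_gain`. Every key maps to exactly one class.
#'
#' @return Named character vector: `names` are lower-case vocabulary terms,
#'   values are classes.
#' @export
consequence_dictionary <- function() {
  c("synonymous snv" = "synonymous",
    "synonymous" = "synonymous",
    "synonymous_variant" = "synonymous",
    "nonsynonymous snv" = "missense",
    "missense" = "missense",
    "missense_variant" = "missense",
    "nonsense" = "nonsense",
    "nonsense_variant" = "nonsense",
    "stopgain" = "stop_gain",
    "stopgain snv" = "stop_gain",
    "stop_gained" = "stop_gain",
    "stop_gain" = "stop_gain",
    "stoploss" = "stop_loss",
    "stoploss snv" = "stop_loss",
    "stop_lost" = "stop_loss",
    "stop_loss" = "stop_loss",
    "frameshift" = "frameshift",
    "frameshift deletion" = "frameshift",
    "frameshift insertion" = "frameshift",
    "frameshift_variant" = "frameshift",
    "nonframeshift deletion" = "inframe",
    "nonframeshift insertion" = "inframe",
    "inframe" = "inframe",
    "inframe_deletion" = "inframe",
    "inframe_insertion" = "inframe")
}

#' Normalize a consequence term
#'
#' Maps free-text consequence vocabulary onto the fixed consequence classes
#' via [consequence_dictionary()] (case-insensitive). Unknown terms are never
#' silently classed as synonymous: in strict mode they raise an error naming
#' the term, otherwise they return `"unclassified"`.
#'
#' @param term Character vector of consequence terms.
#' @param strict Error on unknown terms (default `TRUE`).
#' @return Character vector of classes.
#' @export
normalize_consequence <- function(term, strict = TRUE) {
  dict <- consequence_dictionary()
  cls <- unname(dict[tolower(trimws(term))])
  if (anyNA(cls)) {
    if (strict) {
      stop("unclassified consequence term(s): ",
           paste(unique(term[is.na(cls)]), collapse = ", "))
    }
    cls[is.na(cls)] <- "unclassified"
  }
  cls
}

#' Frequency class of an annotated variant
#'
#' `novel` iff both the global minor allele frequency and the known identifier
#' are absent; else `rare` iff GMAF <= `rare_max` (boundary inclusive: a GMAF
#' of exactly 1\% is rare); else `common`. The three classes partition every
#' annotated variant. A known variant with missing GMAF is classed `common`
#' (catalogued but frequency unknown).
#'
#' @param gmaf Numeric vector of global minor allele frequencies in
#'   `[0, 0.5]`, `NA` when absent.
#' @param known_id Identifier vector, `NA` when absent.
#' @param rare_max Rare-variant GMAF ceiling (default 0.01).
#' @return Character vector in `{common, rare, novel}`.
#' @export
frequency_class <- function(gmaf, known_id = NA_character_, rare_max = 0.01) {
  if (any(!is.na(gmaf) & (gmaf < 0 | gmaf > 0.5))) {
    stop("gmaf outside [0, 0.5]")
  }
  known_id <- rep_len(known_id, length(gmaf))
  ifelse(is.na(gmaf) & is.na(known_id), "novel",
  ifelse(!is.na(gmaf) & gmaf <= rare_max, "rare", "common"))
}

#' High-confidence test on alternate-allele coverage
#'
#' A variant is high confidence when the alternate-supporting read depth,
#' aggregated over its carrier samples, strictly exceeds `threshold` (the
#' conventional floor is 30, strict: exactly 30 fails). The aggregation over
#' carriers is configurable because published filters rarely state it.
#'
#' @param alt_depth Alt-supporting depths, one per genotype call.
#' @param state Matching genotype states; only carriers (`het`/`hom_alt`)
#'   count.
#' @param threshold Strict lower bound (default 30).
#' @param agg Aggregate over carriers: `"max"` (default), `"min"` or `"sum"`.
#' @param on_missing When carriers exist but none has an alt depth: `"keep"`
#'   (fail-open, default) or `"drop"` (fail-closed).
#' @return Single logical; `FALSE` when there are no carriers at all.
#' @export
high_confidence <- function(alt_depth, state, threshold = 30,
                            agg = c("max", "min", "sum"),
                            on_missing = c("keep", "drop")) {
  agg <- match.arg(agg)
  on_missing <- match.arg(on_missing)
  d <- alt_depth[is_carrier(state)]
  if (!length(d)) return(FALSE)          # no carriers: no alt evidence at all
  d <- d[!is.na(d)]
  if (!length(d)) return(on_missing == "keep")
  x <- switch(agg, max = max(d), min = min(d), sum = sum(d))
  x > threshold
}

#' Reference-minor-allele exclusion test
#'
#' Sites where the reference genome carries the population-minor allele yield
#' systematic spurious calls. A variant is excluded when its alternate-allele
#' population frequency strictly exceeds 0.5; a tie at exactly 0.5 is kept,
#' and a missing frequency keeps the variant (the cascade counts these).
#'
#' @param alt_pop_freq Population frequency of the alternate allele.
#' @return Logical vector: `TRUE` = exclude.
#' @export
minor_in_reference <- function(alt_pop_freq) {
  !is.na(alt_pop_freq) & alt_pop_freq > 0.5
}

#' Filter cascade configuration
#'
#' @param gq_floor Genotype-quality floor; calls with GQ below it are masked
#'   to missing before any other stage (default 20).
#' @param alt_cov Strict alternate-coverage threshold (default 30).
#' @param alt_cov_agg Carrier aggregation for [high_confidence()].
#' @param alt_cov_missing Fail-open/fail-closed when alt depths are absent.
#' @param strict_consequence Error on unknown consequence terms.
#' @param exclude_sex_chrom Drop X/Y variants up front (default `FALSE`; sex
#'   chromosomes are otherwise treated as autosomal).
#' @return A list of class `sibseg_cascade_config`.
#' @export
cascade_config <- function(gq_floor = 20, alt_cov = 30,
                           alt_cov_agg = c("max", "min", "sum"),
                           alt_cov_missing = c("keep", "drop"),
                           strict_consequence = TRUE,
                           exclude_sex_chrom = FALSE) {
  cfg <- list(gq_floor = gq_floor, alt_cov = alt_cov,
              alt_cov_agg = match.arg(alt_cov_agg),
              alt_cov_missing = match.arg(alt_cov_missing),
              strict_consequence = strict_consequence,
              exclude_sex_chrom = exclude_sex_chrom)
  class(cfg) <- "sibseg_cascade_config"
  cfg
}

cascade_stages <- function() {
  c("total", "drop_low_quality", "drop_unconfirmed_transcript", "drop_utr",
    "functionally_annotated", "high_confidence", "non_synonymous",
    "drop_minor_in_reference")
}

#' Run the variant filter cascade
#'
#' Applies the fixed-order filter cascade and keeps an auditable per-stage
#' ledger of remaining variants:
#' `total -> drop_low_quality -> drop_unconfirmed_transcript -> drop_utr ->
#' functionally_annotated -> high_confidence -> non_synonymous ->
#' drop_minor_in_reference`.
#'
#' Stage semantics: calls below the GQ floor are masked to missing and
#' variants left without any alt-carrying call are dropped (this also catches
#' sites monomorphic in the cohort); variants on unconfirmed transcripts and
#' in 5'/3' UTRs are dropped; the `functionally_annotated` checkpoint drops
#' variants with no annotation row at all; then the strict alternate-coverage
#' test, synonymous exclusion, and reference-minor-allele exclusion.
#'
#' @param variants Variant table.
#' @param genotypes Long genotype table.
#' @param annotations Annotation data frame (see [read_annotations()]); need
#'   not cover all variants.
#' @param config A [cascade_config()].
#' @return An object of class `sibseg_filter`: list with `surviving` (keys),
#'   `trace` (data frame `stage, remaining, removed`; counts non-increasing),
#'   `genotypes` (GQ-masked long table) and `counters` (named integer vector
#'   of warning counters).
#' @export
run_filter_cascade <- function(variants, genotypes, annotations,
                               config = cascade_config()) {
  keys <- variants$key
  trace_n <- integer(0)
  counters <- c(missing_alt_depth = 0L, missing_alt_pop_freq = 0L,
                unclassified_consequence = 0L, masked_low_gq = 0L)

  if (config$exclude_sex_chrom) {
    sex <- variants$chrom %in% c("X", "Y", "chrX", "chrY")
    keys <- keys[!sex]
  }
  trace_n["total"] <- length(keys)

  g <- genotypes
  low <- !is.na(g$gq) & g$gq < config$gq_floor & g$state != "missing"
  counters["masked_low_gq"] <- sum(low)
  g$state[low] <- "missing"

  # stage: drop_low_quality -- no usable alt evidence left
  carrier_keys <- unique(g$key[is_carrier(g$state)])
  keys <- keys[keys %in% carrier_keys]
  trace_n["drop_low_quality"] <- length(keys)

  ai <- match(keys, annotations$key)
  status <- annotations$transcript_status[ai]
  keys <- keys[is.na(status) | status != "unconfirmed"]
  trace_n["drop_unconfirmed_transcript"] <- length(keys)

  ai <- match(keys, annotations$key)
  region <- annotations$region[ai]
  keys <- keys[is.na(region) | region == "coding"]
  trace_n["drop_utr"] <- length(keys)

  ai <- match(keys, annotations$key)
  keys <- keys[!is.na(ai)]
  trace_n["functionally_annotated"] <- length(keys)

  gk <- g[g$key %in% keys, , drop = FALSE]
  split_idx <- split(seq_len(nrow(gk)), gk$key)
  hc <- vapply(keys, function(k) {
    i <- split_idx[[k]]
    if (is.null(i)) return(config$alt_cov_missing == "keep")
    high_confidence(gk$alt_depth[i], gk$state[i], threshold = config$alt_cov,
                    agg = config$alt_cov_agg,
                    on_missing = config$alt_cov_missing)
  }, TRUE)
  no_ad <- vapply(keys, function(k) {
    i <- split_idx[[k]]
    is.null(i) || !any(!is.na(gk$alt_depth[i]) & is_carrier(gk$state[i]))
  }, TRUE)
  counters["missing_alt_depth"] <- sum(no_ad)
  keys <- keys[hc]
  trace_n["high_confidence"] <- length(keys)

  ai <- match(keys, annotations$key)
  cls <- normalize_consequence(annotations$consequence[ai],
                               strict = config$strict_consequence)
  counters["unclassified_consequence"] <- sum(cls == "unclassified")
  keys <- keys[cls != "synonymous"]
  trace_n["non_synonymous"] <- length(keys)

  ai <- match(keys, annotations$key)
  apf <- annotations$alt_pop_freq[ai]
  counters["missing_alt_pop_freq"] <- sum(is.na(apf))
  keys <- keys[!minor_in_reference(apf)]
  trace_n["drop_minor_in_reference"] <- length(keys)

  trace <- data.frame(stage = cascade_stages(),
                      remaining = as.integer(trace_n[cascade_stages()]),
                      stringsAsFactors = FALSE)
  trace$removed <- c(0L, -diff(trace$remaining))
  out <- list(surviving = keys, trace = trace, genotypes = g,
              counters = counters, config = config)
  class(out) <- "sibseg_filter"
  out
}

#' @export
print.sibseg_filter <- function(x, ...) {
  cat("Variant filter cascade\n")
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("  %-28s [%d]%s\n", x$trace$stage[i], x$trace$remaining[i],
                if (x$trace$removed[i] > 0)
                  sprintf("  (-%d)", x$trace$removed[i]) else ""))
  }
  invisible(x)
}

#' Write a filter trace as TSV
#'
#' @param trace Trace data frame (from a `sibseg_filter` object) or the
#'   object itself.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  if (inherits(trace, "sibseg_filter")) trace <- trace$trace
  utils::write.table(trace[, c("stage", "remaining", "removed")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconcile printed filter-stage counts
#'
#' Turns a partially specified stage ledger (some stages report how many
#' variants were removed, others how many remained) into a full trace by
#' running the subtraction forward, and checks every stage where both a
#' printed and a computed value exist.
#'
#' @param stage_counts Data frame with columns `stage`, `removed`,
#'   `remaining` (either may be `NA` per row), ordered as in the cascade.
#' @return Data frame `stage, removed, remaining, printed_remaining,
#'   consistent`.
#' @export
reconcile_filter_counts <- function(stage_counts) {
  sc <- stage_counts
  n <- nrow(sc)
  remaining <- integer(n)
  remaining[1] <- sc$remaining[1]
  if (is.na(remaining[1])) stop("first stage must state a remaining count")
  for (i in seq_len(n)[-1]) {
    remaining[i] <- if (!is.na(sc$removed[i])) {
      remaining[i - 1] - sc$removed[i]
    } else if (!is.na(sc$remaining[i])) {
      sc$remaining[i]
    } else remaining[i - 1]
  }
  if (any(diff(remaining) > 0)) stop("stage counts increase along the cascade")
  data.frame(stage = sc$stage,
             removed = c(0L, remaining[-n] - remaining[-1]),
             remaining = remaining,
             printed_remaining = sc$remaining,
             consistent = is.na(sc$remaining) | sc$remaining == remaining,
             stringsAsFactors = FALSE)
}

#' Variant-type accounting summary
#'
#' Computes the percentage breakdown of a variant-type count table: the
#' synonymous / non-synonymous split of functionally annotated variants, the
#' six-way non-synonymous partition check, and the rare / novel / indel
#' fractions of all variants. Percentages are half-up rounded to one decimal,
#' matching the conventional printing of such tables.
#'
#' @param counts Data frame with columns `category`, `count`, using the
#'   categories of [paper_fixtures()]`$variant_type_counts`.
#' @return List with `pct_synonymous`, `pct_non_synonymous`,
#'   `nonsyn_subtype_sum`, `nonsyn_partition_ok`, `n_indel`, `pct_rare`,
#'   `pct_novel`, `pct_indel`.
#' @export
variant_type_summary <- function(counts) {
  x <- setNames(counts$count, counts$category)
  subtypes <- c("missense", "nonsense", "frameshift", "inframe",
                "stop_loss", "stop_gain")
  n_indel <- unname(x["deletion"] + x["insertion"])
  list(
    pct_synonymous = round_half_up(100 * x[["synonymous"]] / x[["functionally_annotated"]], 1),
    pct_non_synonymous = round_half_up(100 * x[["non_synonymous"]] / x[["functionally_annotated"]], 1),
    nonsyn_subtype_sum = unname(sum(x[subtypes])),
    nonsyn_partition_ok = sum(x[subtypes]) == x[["non_synonymous"]],
    n_indel = n_indel,
    pct_rare = round_half_up(100 * x[["rare"]] / x[["all_variants"]], 1),
    pct_novel = round_half_up(100 * x[["novel"]] / x[["all_variants"]], 1),
    pct_indel = round_half_up(100 * n_indel / x[["all_variants"]], 1))
}

#' Transition/transversion ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); all other single-base substitutions are transversions.
#' Indels and multi-base alleles are ignored.
#'
#' @param variants Variant table (columns `ref`, `alt`).
#' @return The Ti/Tv ratio (numeric), with attributes `ti` and `tv` carrying
#'   the counts. `NA` when there are no transversions (undefined).
#' @export
titv_ratio <- function(variants) {
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  r <- variants$ref[snv]
  a <- variants$alt[snv]
  ti <- sum((r == "A" & a == "G") | (r == "G" & a == "A") |
            (r == "C" & a == "T") | (r == "T" & a == "C"))
  tv <- sum(snv) - ti
  ratio <- if (tv == 0L) NA_real_ else ti / tv
  structure(ratio, ti = ti, tv = tv)
}

#' Exome coverage QC report
#'
#' Summarizes a per-target depth matrix: per-sample mean depth, fraction of
#' targets covered at >= 20X, and uniformity. Uniformity is not defined
#' consistently across platforms; here it is declared as the fraction of
#' targets with depth >= 0.2 x the sample's mean depth.
#'
#' @param depths Numeric matrix, targets in rows, samples in columns.
#' @param titv Optional cohort Ti/Tv ratio (e.g. from [titv_ratio()]).
#' @param min_cov Coverage floor for the covered fraction (default 20).
#' @return Object of class `sibseg_qc`: list with `per_sample` (data frame
#'   `sample, mean_depth, frac_min_cov, uniformity`), `mean_depth`,
#'   `frac_min_cov`, `uniformity` (cohort means), `titv`,
#'   `uniformity_definition`.
#' @export
qc_report <- function(depths, titv = NULL, min_cov = 20) {
  if (is.null(depths) || !length(depths)) {
    out <- list(per_sample = NULL, mean_depth = NA_real_,
                frac_min_cov = NA_real_, uniformity = NA_real_,
                titv = titv,
                uniformity_definition = "fraction of targets with depth >= 0.2 x mean depth")
    class(out) <- "sibseg_qc"
    return(out)
  }
  depths <- as.matrix(depths)
  per <- data.frame(
    sample = colnames(depths) %||% paste0("S", seq_len(ncol(depths))),
    mean_depth = colMeans(depths, na.rm = TRUE),
    frac_min_cov = colMeans(depths >= min_cov, na.rm = TRUE),
    stringsAsFactors = FALSE)
  per$uniformity <- vapply(seq_len(ncol(depths)), function(j) {
    mean(depths[, j] >= 0.2 * per$mean_depth[j], na.rm = TRUE)
  }, 0)
  out <- list(per_sample = per,
              mean_depth = mean(per$mean_depth),
              frac_min_cov = mean(per$frac_min_cov),
              uniformity = mean(per$uniformity),
              titv = titv,
              uniformity_definition = "fraction of targets with depth >= 0.2 x mean depth")
  class(out) <- "sibseg_qc"
  out
}

#' @export
print.sibseg_qc <- function(x, ...) {
  cat("Coverage QC (uniformity =", x$uniformity_definition, ")\n")
  cat(sprintf("  mean depth %.1f, >=20X fraction %.3f, uniformity %.3f\n",
              x$mean_depth, x$frac_min_cov, x$uniformity))
  if (!is.null(x$titv) && !is.na(x$titv)) {
    cat(sprintf("  Ti/Tv %.2f\n", as.numeric(x$titv)))
  }
  invisible(x)
}

#' Half-up rounding
#'
#' Rounds away from the banker's rule used by [round()]: 0.5 always rounds
#' up, which is how the summary percentages in the worked examples print.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Format a fraction as a printed percentage
#'
#' @param num,den Numerator and denominator.
#' @param digits Decimal places (0 for summary percentages, 1 for
#'   breakdown-style fractions).
#' @return Character, e.g. `"49.5"` or `"57"`.
#' @export
fmt_pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_character_)
  formatC(round_half_up(100 * num / den, digits),
          format = "f", digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
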