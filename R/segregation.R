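#' Segregation configuration
#'
#' @param k Minimum number of confirming families (default 3, the k-of-N
#'   rule with N = 4).
#' @param exclusivity How a call is checked against the opposite phenotype
#'   group: `"same_model"` (default; the opposite group must not itself be
#'   confirmable under the call's model), `"any_model"` (must not be
#'   confirmable under either model) or `"none"`.
#' @param member_rule Within a family, must `"all"` same-group members satisfy
#'   the model (default, the strict reading of "shared"), or just `"any"`.
#' @return A list of class `sibseg_seg_config`.
#' @export
seg_config <- function(k = 3,
                       exclusivity = c("same_model", "any_model", "none"),
                       member_rule = c("all", "any")) {
  if (k < 1) stop("k must be >= 1")
  cfg <- list(k = as.integer(k), exclusivity = match.arg(exclusivity),
              member_rule = match.arg(member_rule))
  class(cfg) <- "sibseg_seg_config"
  cfg
}

#' Does a family satisfy an inheritance model?
#'
#' Recessive model ("shared homozygosity"): every phenotype-group member of
#' the family is homozygous for the alternate allele. Dominant model ("shared
#' variant"): every group member carries at least one alternate allele. A
#' missing genotype in a group member makes the family fail (conservative);
#' with `member_rule = "any"` a single satisfying member suffices.
#'
#' @param states Named character vector of genotype states for one variant,
#'   names = individual ids.
#' @param pedigree A `sibseg_pedigree`.
#' @param family_id Family to test.
#' @param group `"affected"` or `"non_affected"`.
#' @param model `"recessive"` or `"dominant"`.
#' @param member_rule See [seg_config()].
#' @return Single logical.
#' @export
family_satisfies <- function(states, pedigree, family_id, group,
                             model = c("recessive", "dominant"),
                             member_rule = c("all", "any")) {
  model <- match.arg(model)
  member_rule <- match.arg(member_rule)
  if (!family_id %in% pedigree$family_id) {
    stop("family not in pedigree: ", family_id)
  }
  members <- pedigree$individual_id[pedigree$family_id == family_id &
                                      pedigree$phenotype == group]
  if (!length(members)) return(FALSE)
  s <- states[members]
  ok <- if (model == "recessive") !is.na(s) & s == "hom_alt" else
    !is.na(s) & is_carrier(s)
  if (member_rule == "all") all(ok) else any(ok)
}

# variants x families logical matrix of per-family model satisfaction
family_satisfaction_matrix <- function(states, pedigree, group, model,
                                       member_rule = "all") {
  fams <- unique(pedigree$family_id)
  sat <- if (model == "recessive") states == "hom_alt" else
    matrix(is_carrier(states), nrow(states), ncol(states),
           dimnames = dimnames(states))
  out <- matrix(FALSE, nrow(states), length(fams),
                dimnames = list(rownames(states), fams))
  for (f in fams) {
    members <- pedigree$individual_id[pedigree$family_id == f &
                                        pedigree$phenotype == group]
    members <- intersect(members, colnames(states))
    if (!length(members)) next
    m <- sat[, members, drop = FALSE]
    out[, f] <- if (member_rule == "all") rowSums(m) == length(members) else
      rowSums(m) > 0
  }
  out
}

#' Confirm a variant across families
#'
#' Applies the k-of-N rule to one variant, group and model: a segregation
#' call is emitted iff the model holds in at least `k` families.
#'
#' @inheritParams family_satisfies
#' @param config A [seg_config()].
#' @return `NULL`, or a list with `families` (confirming family ids), `model`,
#'   `group`.
#' @export
confirm_across_families <- function(states, pedigree, group, model,
                                    config = seg_config()) {
  fams <- unique(pedigree$family_id)
  sat <- vapply(fams, function(f) {
    family_satisfies(states, pedigree, f, group, model,
                     member_rule = config$member_rule)
  }, TRUE)
  if (sum(sat) < config$k) return(NULL)
  list(families = fams[sat], model = model, group = group)
}

#' Model assignment with recessive precedence
#'
#' A variant confirmed under the recessive model (homozygous-alternate in at
#' least `k` families) is reported as recessive; otherwise, if confirmed as a
#' shared variant, dominant. A variant never appears under both models for
#' the same group.
#'
#' @param n_recessive,n_dominant Numbers of confirming families per model.
#' @param k Confirmation threshold.
#' @return `"recessive"`, `"dominant"` or `NA_character_` (vectorized).
#' @export
assign_model <- function(n_recessive, n_dominant, k = 3) {
  ifelse(n_recessive >= k, "recessive",
         ifelse(n_dominant >= k, "dominant", NA_character_))
}

#' Call segregating variants in a cohort
#'
#' For each variant and each phenotype group, counts the families in which
#' the recessive and dominant models hold, assigns a model with recessive
#' precedence ([assign_model()]), applies the k-of-N confirmation rule and the
#' configured group-exclusivity check.
#'
#' @param states Variants x samples genotype state matrix (see
#'   [genotype_state_matrix()]).
#' @param pedigree A `sibseg_pedigree`; sample ids must match the matrix
#'   columns.
#' @param config A [seg_config()].
#' @param genes Optional named vector mapping variant keys to gene symbols.
#' @return Data frame of calls: `key, gene, group, model, n_families,
#'   families` (comma-joined ids), `exclusive`.
#' @export
segregate <- function(states, pedigree, config = seg_config(), genes = NULL) {
  groups <- c("affected", "non_affected")
  sat <- list()
  for (g in groups) {
    for (m in c("recessive", "dominant")) {
      sat[[paste(g, m)]] <- family_satisfaction_matrix(
        states, pedigree, g, m, member_rule = config$member_rule)
    }
  }
  k <- config$k
  calls <- list()
  for (g in groups) {
    opp <- setdiff(groups, g)
    n_rec <- rowSums(sat[[paste(g, "recessive")]])
    n_dom <- rowSums(sat[[paste(g, "dominant")]])
    model <- assign_model(n_rec, n_dom, k)
    called <- which(!is.na(model))
    if (!length(called)) next
    fams_of <- function(i, m) {
      s <- sat[[paste(g, m)]][i, ]
      paste(names(s)[s], collapse = ",")
    }
    excl <- vapply(called, function(i) {
      m <- model[i]
      switch(config$exclusivity,
             none = TRUE,
             same_model = rowSums(sat[[paste(opp, m)]][i, , drop = FALSE]) < k,
             any_model =
               rowSums(sat[[paste(opp, "recessive")]][i, , drop = FALSE]) < k &&
               rowSums(sat[[paste(opp, "dominant")]][i, , drop = FALSE]) < k)
    }, TRUE)
    calls[[g]] <- data.frame(
      key = rownames(states)[called],
      group = g,
      model = model[called],
      n_families = ifelse(model[called] == "recessive", n_rec[called],
                          n_dom[called]),
      families = vapply(seq_along(called), function(u)
        fams_of(called[u], model[called[u]]), ""),
      exclusive = excl,
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(key = character(), group = character(), model = character(),
               n_families = integer(), families = character(),
               exclusive = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$gene <- if (!is.null(genes)) unname(genes[out$key]) else
    rep(NA_character_, nrow(out))
  out[, c("key", "gene", "group", "model", "n_families", "families",
          "exclusive")]
}

#' Classify printed genotype-table rows into model blocks
#'
#' Table-fixture mode of the segregation caller: each printed row (one
#' variant's evidence cells across the family columns) is classified from its
#' own cells. A row belongs to the recessive block when every non-missing cell
#' is homozygous-alternate and there are at least `k` of them; otherwise to
#' the dominant block when at least `k` cells carry the alternate allele.
#' Rows confirmed in fewer than `k` families get no call, unless
#' `rescue = TRUE` (default) and the same gene already has a confirmed call
#' under the row's natural model, in which case the row is included and
#' flagged `rescued` (published tables keep such gene-level rows).
#'
#' @param tab Fixture-style data frame (see [paper_fixtures()]) or anything
#'   [parse_genotype_table()] accepts.
#' @param group Phenotype group the table describes (`"affected"` or
#'   `"non_affected"`).
#' @param k Confirmation threshold (default 3).
#' @param rescue Include under-confirmed rows of otherwise-confirmed genes.
#' @return Data frame: `row_id, gene, snp_id, wild_type, group, model,
#'   n_hom_families, n_carrier_families, confirmed, rescued`.
#' @export
segregate_table <- function(tab, group, k = 3, rescue = TRUE) {
  parsed <- parse_genotype_table(tab)
  st <- parsed$states
  n_hom <- rowSums(st == "hom_alt")
  n_car <- rowSums(st == "hom_alt" | st == "het")
  pure_hom <- n_car == n_hom
  natural <- ifelse(pure_hom & n_hom > 0, "recessive", "dominant")
  confirmed <- ifelse(natural == "recessive", n_hom >= k, n_car >= k)

  out <- data.frame(parsed$rows,
                    group = group,
                    model = natural,
                    n_hom_families = n_hom,
                    n_carrier_families = n_car,
                    confirmed = confirmed,
                    rescued = FALSE,
                    stringsAsFactors = FALSE)
  if (rescue) {
    conf_gene_model <- unique(paste(out$gene, out$model)[out$confirmed])
    resc <- !out$confirmed & paste(out$gene, out$model) %in% conf_gene_model &
      out$n_carrier_families > 0
    out$rescued <- resc
  }
  out[out$confirmed | out$rescued, , drop = FALSE]
}

#' Summarize segregation calls per group and model
#'
#' Distinct-gene and variant counts per (group, model), plus the count and
#' percentage of genes on a curated list (typically immune-related genes;
#' membership is an input, never inferred). The percentage is half-up rounded
#' to the nearest integer, as such summaries print.
#'
#' @param calls Call data frame from [segregate()] or [segregate_table()]
#'   (needs columns `gene`, `group`, `model`).
#' @param curated_genes Character vector of curated gene symbols
#'   (case-sensitive match).
#' @return Data frame: `group, model, n_genes, n_variants, n_curated,
#'   pct_curated`.
#' @export
summarize_calls <- function(calls, curated_genes = character()) {
  if (!nrow(calls)) {
    return(data.frame(group = character(), model = character(),
                      n_genes = integer(), n_variants = integer(),
                      n_curated = integer(), pct_curated = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(calls, list(calls$group, calls$model), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    genes <- unique(d$gene)
    n_cur <- sum(genes %in% curated_genes)
    data.frame(group = d$group[1], model = d$model[1],
               n_genes = length(genes), n_variants = nrow(d),
               n_curated = n_cur,
               pct_curated = if (length(genes))
                 round_half_up(100 * n_cur / length(genes)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export calls as a publication-shaped TSV
#'
#' Writes segregation calls in the layout of the worked-example tables:
#' model block, gene, SNP id, wild-type allele where available, then the
#' call metadata.
#'
#' @param calls Call data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- intersect(c("group", "model", "gene", "snp_id", "wild_type", "key",
                      "n_families", "n_hom_families", "n_carrier_families",
                      "families", "exclusive", "confirmed", "rescued"),
                    names(calls))
  ord <- order(calls$group, calls$model, calls$gene)
  utils::write.table(calls[ord, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
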