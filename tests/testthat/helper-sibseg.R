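# Shared builders and independent oracles for the test suite.

# four-family discordant pedigree: family F1 has two non-affected siblings,
# mirroring the worked-example cohort shape
toy_pedigree <- function() {
  as_pedigree(data.frame(
    family_id = c("F1", "F1", "F1", "F2", "F2", "F3", "F3", "F4", "F4"),
    individual_id = c("A1", "U1", "U2", "A2", "U3", "A3", "U4", "A4", "U5"),
    phenotype = c("affected", "non_affected", "non_affected",
                  "affected", "non_affected", "affected", "non_affected",
                  "affected", "non_affected"),
    stringsAsFactors = FALSE))
}

random_states <- function(n_var, ped, seed,
                          probs = c(0.45, 0.3, 0.2, 0.05)) {
  set.seed(seed)
  samples <- ped$individual_id
  matrix(sample(gt_states(), n_var * length(samples), replace = TRUE,
                prob = probs),
         nrow = n_var, dimnames = list(paste0("v", seq_len(n_var)), samples))
}

# brute-force segregation oracle: plain loops, no shared code with segregate()
brute_force_calls <- function(states, ped, k = 3, exclusivity = "same_model") {
  fams <- unique(ped$family_id)
  out <- list()
  for (g in c("affected", "non_affected")) {
    opp <- setdiff(c("affected", "non_affected"), g)
    for (i in seq_len(nrow(states))) {
      sat <- function(group, model) {
        hits <- character(0)
        for (f in fams) {
          members <- ped$individual_id[ped$family_id == f &
                                         ped$phenotype == group]
          s <- states[i, members]
          ok <- if (model == "recessive") all(s == "hom_alt") else
            all(s %in% c("het", "hom_alt"))
          if (ok) hits <- c(hits, f)
        }
        hits
      }
      rec <- sat(g, "recessive")
      dom <- sat(g, "dominant")
      model <- if (length(rec) >= k) "recessive" else
        if (length(dom) >= k) "dominant" else NA
      if (is.na(model)) next
      fams_conf <- if (model == "recessive") rec else dom
      excl <- switch(exclusivity,
                     none = TRUE,
                     same_model = length(sat(opp, model)) < k,
                     any_model = length(sat(opp, "recessive")) < k &&
                       length(sat(opp, "dominant")) < k)
      out[[length(out) + 1]] <- data.frame(
        key = rownames(states)[i], group = g, model = model,
        n_families = length(fams_conf),
        families = paste(fams_conf, collapse = ","),
        exclusive = excl, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(key = character(), group = character(),
                      model = character(), n_families = integer(),
                      families = character(), exclusive = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# exhaustive hypergeometric upper tail by enumerating every draw
enumerate_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the successes
  mean(hits >= k)
}

# sorted comparison of call tables
sort_calls <- function(x) {
  x <- x[order(x$key, x$group), c("key", "group", "model", "n_families",
                                  "families", "exclusive")]
  rownames(x) <- NULL
  x
}

write_mini_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}
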