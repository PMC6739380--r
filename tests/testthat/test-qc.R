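test_that("consequence dictionary is a total single-valued mapping", {
  dict <- consequence_dictionary()
  expect_false(any(duplicated(names(dict))))
  expect_true(all(dict %in% c("synonymous", "missense", "nonsense",
                              "frameshift", "inframe", "stop_loss",
                              "stop_gain")))
  # every key normalizes to its own class, case-insensitively
  for (term in names(dict)) {
    expect_equal(normalize_consequence(toupper(term)), unname(dict[term]))
  }
  expect_equal(normalize_consequence("synonymous SNV"), "synonymous")
  expect_equal(normalize_consequence("frameshift deletion"), "frameshift")
  expect_error(normalize_consequence("weird term"), "weird term")
  expect_equal(normalize_consequence("weird term", strict = FALSE),
               "unclassified")
})

test_that("frequency class partitions annotated variants", {
  expect_equal(frequency_class(0.01, "rs1"), "rare")      # boundary inclusive
  expect_equal(frequency_class(NA, NA), "novel")
  expect_equal(frequency_class(0.30, "rs2"), "common")
  expect_equal(frequency_class(NA, "rs3"), "common")      # catalogued, no GMAF
  expect_error(frequency_class(0.7, "rs4"), "gmaf")
  set.seed(1)
  gmaf <- ifelse(runif(500) < 0.2, NA, runif(500, 0, 0.5))
  ids <- ifelse(runif(500) < 0.3, NA, "rs")
  cls <- frequency_class(gmaf, ids)
  expect_true(all(cls %in% c("common", "rare", "novel")))
  expect_equal(sum(cls == "novel"), sum(is.na(gmaf) & is.na(ids)))
})

test_that("high-confidence coverage test is strict and configurable", {
  st <- c("het", "hom_alt")
  expect_true(high_confidence(c(12, 31), st))
  expect_false(high_confidence(c(30, 4), c("hom_alt", "hom_ref")))
  expect_true(high_confidence(c(1, 1), st, threshold = 0))
  expect_false(high_confidence(c(100, 100), c("hom_ref", "hom_ref")))  # no carriers
  expect_true(high_confidence(c(NA, NA), st, on_missing = "keep"))
  expect_false(high_confidence(c(NA, NA), st, on_missing = "drop"))
  expect_false(high_confidence(c(10, 50), st, agg = "min"))
  expect_true(high_confidence(c(20, 20), st, agg = "sum"))
})

test_that("reference-minor exclusion keeps ties and missing frequencies", {
  expect_true(minor_in_reference(0.8))
  expect_false(minor_in_reference(0.5))
  expect_false(minor_in_reference(NA))
  # uniform alt frequencies: excluded fraction approximates P(freq > 0.5)
  set.seed(7)
  n <- 20000
  f <- runif(n)
  frac <- mean(minor_in_reference(f))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("Ti/Tv counts match a brute-force classification", {
  v <- variant_table(c("1", "1", "1"), 1:3, c("A", "C", "A"),
                     c("G", "T", "C"))
  r <- titv_ratio(v)
  expect_equal(as.numeric(r), 2.0)
  v2 <- variant_table("1", 1, "A", "C")
  expect_equal(as.numeric(titv_ratio(v2)), 0.0)
  expect_true(is.na(titv_ratio(variant_table("1", 1, "A", "G"))))
  # random SNVs vs explicit enumeration of the 12 substitution types
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 300, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  v3 <- variant_table("1", seq_len(300), ref, alt)
  pair <- paste0(ref, alt)
  ti <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  expect_equal(as.numeric(titv_ratio(v3)), ti / (300 - ti))
  expect_equal(attr(titv_ratio(v3), "ti"), ti)
})

test_that("coverage QC summarizes depth matrices", {
  qc <- qc_report(matrix(100, nrow = 50, ncol = 2))
  expect_equal(qc$mean_depth, 100)
  expect_equal(qc$frac_min_cov, 1.0)
  expect_equal(qc$uniformity, 1.0)

  qc2 <- qc_report(matrix(c(rep(0, 25), rep(200, 25)), ncol = 1))
  expect_equal(qc2$mean_depth, 100)
  expect_equal(qc2$frac_min_cov, 0.5)
  expect_equal(qc2$uniformity, 0.5)

  set.seed(5)
  n <- 4000
  qc3 <- qc_report(matrix(rpois(n, 105), ncol = 1))
  expect_lt(abs(qc3$mean_depth - 105), 3 * sqrt(105 / n))

  qc4 <- qc_report(NULL)
  expect_true(is.na(qc4$mean_depth))
})

test_that("cascade leaves untouched a table of clean variants", {
  sim <- simulate_cohort(sim_config(
    seed = 9, n_background = 30,
    stage_fractions = c(low_quality = 0, unconfirmed = 0, utr = 0,
                        unannotated = 0, low_alt_cov = 0, synonymous = 0,
                        ref_minor = 0),
    freq_range = c(0.3, 0.5), novel_frac = 0))
  filt <- run_filter_cascade(sim$variants, sim$genotypes, sim$annotations)
  # every variant that has any alternate evidence sails through all stages
  expect_equal(length(unique(filt$trace$remaining[-1])), 1L)
  expect_true(all(diff(filt$trace$remaining) <= 0))
})

test_that("per-stage removals equal the generator's truth manifest", {
  sim <- simulate_cohort(sim_config(seed = 31, n_background = 400))
  filt <- run_filter_cascade(sim$variants, sim$genotypes, sim$annotations)
  fate <- table(sim$manifest$fate)
  removed <- setNames(filt$trace$removed, filt$trace$stage)
  for (stage in setdiff(names(removed), "total")) {
    exp_rm <- if (stage %in% names(fate)) as.integer(fate[[stage]]) else 0L
    expect_equal(unname(removed[stage]), exp_rm,
                 label = paste("removals at", stage))
  }
  expect_equal(length(filt$surviving), sum(sim$manifest$fate == "survive"))
  expect_setequal(filt$surviving,
                  sim$manifest$key[sim$manifest$fate == "survive"])
})

test_that("filter trace is monotone non-increasing on random inputs", {
  for (seed in 1:8) {
    sim <- simulate_cohort(sim_config(seed = seed, n_background = 60,
                                      missingness = 0.05))
    filt <- run_filter_cascade(sim$variants, sim$genotypes, sim$annotations)
    expect_true(all(diff(filt$trace$remaining) <= 0))
    expect_equal(filt$trace$remaining[1], nrow(sim$variants))
    # deterministic: same inputs give an identical trace
    filt2 <- run_filter_cascade(sim$variants, sim$genotypes, sim$annotations)
    expect_identical(filt$trace, filt2$trace)
  }
})

test_that("empty input yields a zero trace without error", {
  v <- variant_table(character(), integer(), character(), character())
  g <- data.frame(key = character(), sample_id = character(),
                  state = character(), depth = integer(),
                  alt_depth = integer(), gq = numeric())
  ann <- data.frame(key = character(), transcript_status = character(),
                    region = character(), consequence = character(),
                    alt_pop_freq = numeric())
  filt <- run_filter_cascade(v, g, ann)
  expect_equal(filt$trace$remaining, rep(0L, 8))
})

test_that("low-GQ genotypes are masked before any other stage", {
  v <- variant_table("1", 1:2, c("A", "C"), c("G", "T"))
  g <- data.frame(
    key = rep(v$key, each = 2),
    sample_id = rep(c("S1", "S2"), 2),
    state = c("het", "hom_ref", "het", "het"),
    depth = 50L, alt_depth = 40L,
    gq = c(10, 99, 99, 99))
  ann <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    gene = c("G1", "G2"), transcript_status = "confirmed",
                    region = "coding", consequence = "nonsynonymous SNV",
                    gmaf = 0.1, alt_pop_freq = 0.1, key = v$key)
  filt <- run_filter_cascade(v, g, ann)
  # variant 1's only carrier fails Q20, so it falls out at the quality stage
  expect_equal(filt$trace$remaining[2], 1L)
  expect_equal(filt$surviving, v$key[2])
  expect_equal(filt$genotypes$state[1], "missing")
})

test_that("stage-count reconciliation reproduces printed ledgers", {
  fx <- paper_fixtures()
  rec <- reconcile_filter_counts(fx$filter_stage_counts)
  expect_true(all(rec$consistent))
  expect_equal(rec$remaining[rec$stage == "functionally_annotated"], 41877L)
  expect_equal(rec$remaining, cummin(rec$remaining))
})

test_that("percent rendering follows the declared conventions", {
  expect_equal(fmt_pct(20748, 41877, 1), "49.5")
  expect_equal(fmt_pct(21129, 41877, 1), "50.5")
  expect_equal(fmt_pct(6, 9, 1), "66.7")
  expect_equal(round_half_up(28.571), 29)
  expect_equal(round_half_up(42.857), 43)
  expect_equal(round_half_up(0.5), 1)      # half always rounds up
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(49.5449, 1), 49.5)
})
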