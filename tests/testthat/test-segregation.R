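test_that("family satisfaction encodes shared homozygosity and shared variants", {
  ped <- toy_pedigree()
  # homozygous-alternate affected member: both models hold
  st <- setNames(rep("hom_ref", 9), ped$individual_id)
  st["A1"] <- "hom_alt"
  expect_true(family_satisfies(st, ped, "F1", "affected", "recessive"))
  expect_true(family_satisfies(st, ped, "F1", "affected", "dominant"))
  # heterozygous member: dominant only
  st["A1"] <- "het"
  expect_false(family_satisfies(st, ped, "F1", "affected", "recessive"))
  expect_true(family_satisfies(st, ped, "F1", "affected", "dominant"))
  # all wild-type: neither model
  st["A1"] <- "hom_ref"
  expect_false(family_satisfies(st, ped, "F1", "affected", "dominant"))
  expect_error(family_satisfies(st, ped, "F9", "affected", "dominant"),
               "not in pedigree")
})

test_that("multi-sibling families require all group members by default", {
  ped <- toy_pedigree()  # F1 has two non-affected siblings U1, U2
  st <- setNames(rep("hom_ref", 9), ped$individual_id)
  st["U1"] <- "hom_alt"
  expect_false(family_satisfies(st, ped, "F1", "non_affected", "dominant"))
  expect_true(family_satisfies(st, ped, "F1", "non_affected", "dominant",
                               member_rule = "any"))
  st["U2"] <- "het"
  expect_true(family_satisfies(st, ped, "F1", "non_affected", "dominant"))
  expect_false(family_satisfies(st, ped, "F1", "non_affected", "recessive"))
  # a missing genotype is conservative: the family fails
  st["U2"] <- "missing"
  expect_false(family_satisfies(st, ped, "F1", "non_affected", "dominant"))
})

test_that("k-of-N confirmation emits calls with the confirming families", {
  ped <- toy_pedigree()
  st <- setNames(rep("hom_ref", 9), ped$individual_id)
  st[c("U1", "U2", "U3", "U4")] <- "hom_alt"  # families F1-F3 non-affected hom
  conf <- confirm_across_families(st, ped, "non_affected", "recessive")
  expect_equal(sort(conf$families), c("F1", "F2", "F3"))
  st["U3"] <- "hom_ref"  # only 2 families left
  expect_null(confirm_across_families(st, ped, "non_affected", "recessive"))
})

test_that("model assignment gives recessive precedence and never both", {
  expect_equal(assign_model(3, 4), "recessive")
  expect_equal(assign_model(1, 3), "dominant")
  expect_equal(assign_model(0, 3), "dominant")
  expect_true(is.na(assign_model(2, 2)))
  expect_equal(assign_model(c(3, 0), c(4, 4)), c("recessive", "dominant"))
})

test_that("segregate matches brute-force enumeration on random matrices", {
  ped <- toy_pedigree()
  for (seed in 1:12) {
    st <- random_states(30, ped, seed = seed)
    got <- segregate(st, ped, seg_config())
    want <- brute_force_calls(st, ped, k = 3)
    expect_equal(sort_calls(got), sort_calls(want), label = paste("seed", seed))
    # any_model exclusivity agrees with brute force too
    got2 <- segregate(st, ped, seg_config(exclusivity = "any_model"))
    want2 <- brute_force_calls(st, ped, k = 3, exclusivity = "any_model")
    expect_equal(sort_calls(got2), sort_calls(want2))
  }
})

test_that("recessive satisfaction implies dominant satisfaction", {
  ped <- toy_pedigree()
  for (seed in 13:18) {
    st <- random_states(40, ped, seed = seed)
    for (g in c("affected", "non_affected")) {
      for (f in unique(ped$family_id)) {
        for (i in seq_len(nrow(st))) {
          if (family_satisfies(st[i, ], ped, f, g, "recessive")) {
            expect_true(family_satisfies(st[i, ], ped, f, g, "dominant"))
          }
        }
      }
    }
  }
})

test_that("call sets shrink monotonically in k", {
  ped <- toy_pedigree()
  for (seed in 19:24) {
    st <- random_states(40, ped, seed = seed)
    prev <- NULL
    for (k in 1:4) {
      calls <- segregate(st, ped, seg_config(k = k))
      ids <- paste(calls$key, calls$group)
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("recessive and dominant blocks never share a (variant, group)", {
  ped <- toy_pedigree()
  for (seed in 25:28) {
    st <- random_states(50, ped, seed = seed)
    calls <- segregate(st, ped, seg_config())
    expect_false(any(duplicated(paste(calls$key, calls$group))))
  }
})

test_that("summaries count distinct genes, variants and curated membership", {
  calls <- data.frame(
    key = c("v1", "v2", "v3"), gene = c("G1", "G1", "G2"),
    group = "affected", model = "dominant",
    stringsAsFactors = FALSE)
  s <- summarize_calls(calls, curated_genes = "G2")
  expect_equal(s$n_genes, 2L)
  expect_equal(s$n_variants, 3L)
  expect_equal(s$n_curated, 1L)
  expect_equal(s$pct_curated, 50)
  expect_equal(nrow(summarize_calls(calls[0, ], "G2")), 0L)
})

test_that("table mode reproduces the printed block partition row by row", {
  fx <- paper_fixtures()
  a <- segregate_table(fx$affected, group = "affected", k = 3)
  expect_equal(a$model, fx$affected$block[a$row_id])
  n <- suppressWarnings(segregate_table(fx$nonaffected,
                                        group = "non_affected", k = 3))
  expect_equal(n$model, fx$nonaffected$block[n$row_id])
  # the under-confirmed two-cell row is included only by gene-level rescue
  hjurp <- a[a$snp_id == "rs3806589", ]
  expect_true(hjurp$rescued)
  expect_equal(hjurp$n_hom_families, 2)
  strict <- segregate_table(fx$affected, group = "affected", k = 3,
                            rescue = FALSE)
  expect_false("rs3806589" %in% strict$snp_id)
  expect_equal(nrow(strict), nrow(a) - 1L)
})

test_that("table-mode calls for known example rows", {
  fx <- paper_fixtures()
  a <- segregate_table(fx$affected, group = "affected", k = 3)
  expect_equal(a$model[a$gene == "AKNA"], "recessive")
  expect_equal(a$model[a$gene == "PRDM16"], "dominant")
  n <- suppressWarnings(segregate_table(fx$nonaffected,
                                        group = "non_affected", k = 3))
  cd5 <- n[n$snp_id == "rs2229177", ]
  expect_equal(cd5$model, "recessive")
  expect_equal(cd5$n_hom_families, 3)
  # the variant printed in both blocks with different evidence
  hlac <- n[n$snp_id == "rs79636386", ]
  expect_setequal(hlac$model, c("recessive", "dominant"))
})

test_that("planted exclusive variants are exclusive under every mode", {
  ped <- toy_pedigree()
  st <- matrix("hom_ref", 1, 9, dimnames = list("v1", ped$individual_id))
  st[1, ped$individual_id[ped$phenotype == "affected"]] <- "hom_alt"
  for (mode in c("none", "same_model", "any_model")) {
    calls <- segregate(st, ped, seg_config(exclusivity = mode))
    expect_true(all(calls$exclusive[calls$group == "affected"]))
  }
  # dominant-confirmed in both groups: not exclusive under same_model
  st2 <- matrix("het", 1, 9, dimnames = list("v1", ped$individual_id))
  calls2 <- segregate(st2, ped, seg_config(exclusivity = "same_model"))
  expect_false(any(calls2$exclusive))
})
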