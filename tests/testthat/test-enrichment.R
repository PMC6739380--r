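test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_upper(5, 5, 5, 20), 1 / choose(20, 5))
  set.seed(41)
  for (rep in 1:20) {
    N <- sample(5:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper(k, K, n, N),
                 enumerate_hypergeom_upper(k, K, n, N),
                 tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  expect_error(hypergeom_upper(6, 5, 5, 20), "inconsistent")
  expect_error(hypergeom_upper(2, 25, 5, 20), "inconsistent")
})

test_that("hypergeometric tail agrees with the library distribution", {
  set.seed(42)
  for (rep in 1:50) {
    N <- sample(10:100, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("BH step-up matches hand computation and library oracle", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(43)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q <= 1) && all(q > 0))
    # permutation invariance and monotonicity along sorted p
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("ORA ranks a fully recovered planted set first", {
  universe <- paste0("G", 1:50)
  sets <- list(PLANTED = paste0("G", 1:8),
               DECOY1 = paste0("G", 20:30),
               DECOY2 = paste0("G", 31:40))
  query <- paste0("G", 1:8)
  res <- run_ora(query, sets, universe)
  expect_equal(res$set_id[1], "PLANTED")
  expect_equal(res$k[1], 8L)
  expect_lt(res$q[1], 0.05)
  # disjoint query: every p is 1
  res2 <- run_ora(paste0("G", 41:45), sets, universe)
  expect_true(all(res2$p == 1))
  # query genes outside the universe are dropped with a warning
  expect_warning(run_ora(c("G1", "NOT_THERE"), sets, universe), "outside")
  w <- capture_warnings(res3 <- run_ora("NOT_THERE", sets, universe))
  expect_match(w, "outside", all = FALSE)
  expect_match(w, "empty query", all = FALSE)
  expect_equal(nrow(res3), 0L)
})

test_that("set-size window is applied after universe intersection", {
  universe <- paste0("G", 1:30)
  sets <- list(TINY = c("G1", "G2"),
               OK = paste0("G", 1:10),
               HUGE = paste0("G", 1:25))
  res <- run_ora(paste0("G", 1:5), sets, universe, min_size = 3, max_size = 20)
  expect_equal(res$set_id, "OK")
  expect_setequal(attr(res, "skipped_sets"), c("TINY", "HUGE"))
})

test_that("enrichment-map edges equal brute-force all-pairs overlap", {
  sets <- list(A = c("x", "y", "z"), B = c("x", "y", "z"),
               C = c("p", "q", "r"))
  res <- data.frame(set_id = c("A", "B", "C"), description = "",
                    k = 3L, K = 3L, n = 3L, N = 10L,
                    p = c(0.001, 0.001, 0.001), q = c(0.01, 0.01, 0.01),
                    stringsAsFactors = FALSE)
  map <- build_enrichment_map(res, sets)
  expect_equal(nrow(map$nodes), 3L)
  expect_equal(nrow(map$edges), 1L)          # identical sets only
  expect_equal(map$edges$similarity, 1.0)

  set.seed(44)
  genes <- paste0("g", 1:40)
  rsets <- lapply(1:8, function(i) sample(genes, sample(3:12, 1)))
  names(rsets) <- paste0("S", 1:8)
  rres <- data.frame(set_id = names(rsets), description = "",
                     k = 1L, K = lengths(rsets), n = 5L, N = 40L,
                     p = 0.001, q = runif(8, 0, 0.04),
                     stringsAsFactors = FALSE)
  for (cutoff in c(0, 0.25, 0.375, 0.8)) {
    map2 <- build_enrichment_map(rres, rsets, similarity_cutoff = cutoff)
    # brute force over all unordered pairs
    want <- 0L
    for (i in 1:7) for (j in (i + 1):8) {
      a <- rsets[[i]]; b <- rsets[[j]]
      sim <- length(intersect(a, b)) / min(length(a), length(b))
      if (sim >= cutoff) {
        want <- want + 1L
        row <- map2$edges[map2$edges$set_a == names(rsets)[i] &
                            map2$edges$set_b == names(rsets)[j], ]
        expect_equal(row$similarity, sim)
      }
    }
    expect_equal(nrow(map2$edges), want)
  }
  # jaccard variant
  mj <- build_enrichment_map(res, sets, metric = "jaccard",
                             similarity_cutoff = 0.9)
  expect_equal(mj$edges$similarity, 1.0)
})

test_that("node set shrinks monotonically as the q cutoff tightens", {
  set.seed(45)
  sets <- lapply(1:10, function(i) paste0("g", sample(1:50, 8)))
  names(sets) <- paste0("S", 1:10)
  res <- data.frame(set_id = names(sets), description = "", k = 1L, K = 8L,
                    n = 5L, N = 50L, p = 0.01, q = runif(10),
                    stringsAsFactors = FALSE)
  prev <- NULL
  for (qc in c(0.8, 0.4, 0.1, 0.01)) {
    m <- build_enrichment_map(res, sets, q_cutoff = qc)
    if (!is.null(prev)) expect_true(all(m$nodes$set_id %in% prev))
    prev <- m$nodes$set_id
  }
})

test_that("SIF export covers all significant nodes", {
  sets <- list(A = c("x", "y"), B = c("x", "y"), C = c("p", "q"))
  res <- data.frame(set_id = c("A", "B", "C"), description = "", k = 2L,
                    K = 2L, n = 2L, N = 10L, p = 0.001, q = 0.01,
                    stringsAsFactors = FALSE)
  map <- build_enrichment_map(res, sets)
  sif <- tempfile(fileext = ".sif")
  write_sif(map, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), 2L)  # one edge line, one isolated node
  expect_true(any(grepl("^A\tgeneset_overlap\tB$", lines)))
  expect_true("C" %in% lines)
  expect_true(file.exists(sub("\\.sif$", ".edges.tsv", sif)))
})
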