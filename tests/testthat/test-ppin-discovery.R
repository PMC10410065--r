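mk_grn <- function(snp, gene) {
  structure(data.frame(snp_id = snp, gene_id = gene, beta = 0.1, se = 0.05,
                       p_nominal = 1e-8, p_adjusted = 1e-6,
                       interaction_class = "cis", gene_tpm = 1,
                       stringsAsFactors = FALSE),
            class = c("grn", "data.frame"))
}

test_that("level 0 is the query-hit subnetwork of the GRN", {
  grn <- mk_grn(c("s1", "s2"), c("gA", "gB"))
  l0 <- build_level0("s1", grn)
  expect_equal(l0$genes, "gA")
  expect_equal(nrow(l0$records), 1)
  expect_warning(l0e <- build_level0("sX", grn), "empty")
  expect_length(l0e$genes, 0)
})

test_that("network expansion assigns breadth-first levels above the score cutoff", {
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                      score = 0.8, stringsAsFactors = FALSE)
  map <- data.frame(gene_id = c("gA", "gB", "gC"),
                    protein_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  pp <- ppin_graph(edges, map, min_score = 0.7)
  lv <- expand_ppin("gA", pp, max_level = 4)
  expect_equal(lv$proteins[[1]], "A")
  expect_equal(lv$proteins[[2]], "B")
  expect_equal(lv$proteins[[3]], "C")
  expect_equal(lv$genes[[2]], "gB")

  # an edge scoring 0.69 is not traversed at the 0.7 cutoff
  edges$score <- c(0.69, 0.8)
  pp2 <- ppin_graph(edges, map, min_score = 0.7)
  lv2 <- expand_ppin("gA", pp2)
  expect_length(lv2$proteins[[2]], 0)
  # a score of exactly 0.7 is retained (inclusive cutoff)
  edges$score <- c(0.7, 0.8)
  lv3 <- expand_ppin("gA", ppin_graph(edges, map, min_score = 0.7))
  expect_equal(lv3$proteins[[2]], "B")

  # unmapped level-0 genes are recorded and skipped
  lv4 <- expand_ppin(c("gA", "gZ"), pp)
  expect_equal(lv4$unmapped_level0_genes, "gZ")
})

test_that("level assignment equals a brute-force BFS oracle on random graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    prot <- sprintf("p%02d", 1:n)
    cmb <- combn(prot, 2)
    pick <- runif(ncol(cmb)) < 0.25
    if (!any(pick)) next
    edges <- data.frame(protein_a = cmb[1, pick], protein_b = cmb[2, pick],
                        score = 0.9, stringsAsFactors = FALSE)
    map <- data.frame(gene_id = paste0("g_", prot), protein_id = prot,
                      stringsAsFactors = FALSE)
    seeds <- paste0("g_", sample(prot, sample(1:2, 1)))
    lv <- expand_ppin(seeds, ppin_graph(edges, map), max_level = 4)
    oracle <- bfs_levels_oracle(edges, sub("^g_", "", seeds), 4)
    for (L in 0:4) {
      expect_setequal(lv$proteins[[L + 1]],
                      names(oracle)[oracle == L])
    }
    # levels are disjoint
    all_prot <- unlist(lv$proteins)
    expect_equal(anyDuplicated(all_prot), 0)
  }
})

test_that("per-level eQTL re-query collects the level genes' GRN records", {
  grn <- mk_grn(c("s1", "s2", "s3", "s4"), c("gA", "gA", "gA", "gB"))
  edges <- data.frame(protein_a = "A", protein_b = "B", score = 0.9)
  map <- data.frame(gene_id = c("gA", "gB"), protein_id = c("A", "B"))
  lv <- expand_ppin("gA", ppin_graph(edges, map), max_level = 2)
  eq <- requery_eqtls(lv, grn)
  expect_equal(eq$level0$snps, c("s1", "s2", "s3")) # 3 eQTLs attached
  expect_equal(eq$level1$snps, "s4")
  expect_length(eq$level2$snps, 0) # gene absent from GRN contributes nothing
})

test_that("hypergeometric enrichment matches the closed form", {
  # N=10, K=5, n=4, k=4 -> p = C(5,4) C(5,0) / C(10,4) = 5/210
  universe <- sprintf("u%02d", 1:10)
  catalog <- data.frame(trait = rep(c("T", "pad"), c(5, 5)),
                        snp = universe, stringsAsFactors = FALSE)
  lv <- list(list(snps = universe[1:4]))
  enr <- enrich_traits(lv, catalog, keep_all = TRUE)
  row <- enr[enr$trait == "T", ]
  expect_equal(row$k, 4)
  expect_equal(row$p_hyper, 5 / 210, tolerance = 1e-12)
  # k = 0 -> upper tail includes X = 0 -> p = 1
  lv0 <- list(list(snps = universe[6:9]))
  enr0 <- enrich_traits(lv0, catalog, keep_all = TRUE)
  expect_equal(enr0$p_hyper[enr0$trait == "T"],
               hyper_tail_oracle(10, 5, 4, 0))
  expect_equal(hyper_tail_oracle(10, 5, 4, 0), 1)
  # a level with no eQTLs in the universe is skipped with a warning
  expect_warning(enrich_traits(list(list(snps = character(0))), catalog),
                 "skipped")
})

test_that("enrichment equals the enumeration oracle on random small worlds", {
  set.seed(123)
  for (rep in 1:60) {
    N <- sample(3:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k_max <- min(K, n)
    k_min <- max(0, n - (N - K))
    k <- sample(k_min:k_max, 1)
    universe <- sprintf("s%02d", 1:N)
    trait_snps <- universe[1:K]
    lvl <- c(universe[seq_len(k)],
             if (n - k > 0) universe[K + seq_len(n - k)])
    catalog <- rbind(
      data.frame(trait = "T", snp = trait_snps, stringsAsFactors = FALSE),
      data.frame(trait = "pad", snp = universe, stringsAsFactors = FALSE))
    enr <- enrich_traits(list(list(snps = lvl)), catalog, keep_all = TRUE)
    expect_equal(enr$p_hyper[enr$trait == "T"],
                 hyper_tail_oracle(N, K, n, k), tolerance = 1e-12,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("bootstrap p-values implement the counting formula exactly", {
  expect_equal(bootstrap_pvalue(5, rep(0, 1000)), 0)
  expect_equal(bootstrap_pvalue(5, c(rep(10, 10), rep(0, 990))), 0.010)
  expect_equal(bootstrap_pvalue(0, rep(0, 1000)), 1) # every overlap >= 0
  expect_equal(bootstrap_pvalue(3, c(3, 2, 5, 1), conservative = TRUE), 3 / 5)
  # always a multiple of 1/n_iter, in [0, 1]
  set.seed(4)
  for (rep in 1:20) {
    ks <- rpois(200, 2)
    p <- bootstrap_pvalue(sample(0:5, 1), ks)
    expect_true(p >= 0 && p <= 1)
    expect_equal(p * 200, round(p * 200))
  }
  # monotone: larger observed overlap never increases p on fixed draws
  ks <- rpois(500, 3)
  ps <- vapply(0:10, function(k) bootstrap_pvalue(k, ks), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("bootstrap null is seeded, reproducible, and flags planted traits", {
  w <- default_world()
  tab <- gen_eqtl_table(w, seed = 12)
  grn <- build_grn(w, tab)
  catalog <- gen_gwas_catalog(w, n_traits = 20, pleiotropy_frac = 0.8,
                              trait_size = 20, seed = 13)
  pp <- ppin_graph(w$ppin, w$gene_protein_map)
  cfg <- bootstrap_config(n_iter = 100, seed = 14, threshold = 0.05)
  d1 <- suppressWarnings(discover_traits(w$truth$query_snps, grn, pp,
                                         catalog, bootstrap_cfg = cfg))
  d2 <- suppressWarnings(discover_traits(w$truth$query_snps, grn, pp,
                                         catalog, bootstrap_cfg = cfg))
  expect_identical(d1$table, d2$table)
  planted <- d1$enrichment[d1$enrichment$trait == "planted_trait_01" &
                             d1$enrichment$level == 0, ]
  expect_equal(nrow(planted), 1)
  expect_lt(planted$p_hyper, 0.05)
  expect_lt(planted$p_bootstrap, 0.05)
  expect_true(planted$significant)
  # resample size larger than the universe is a configuration error
  expect_error(
    bootstrap_null(d1$enrichment, catalog, grn, pp,
                   bootstrap_config(n_iter = 2, resample_size = 10000)),
    class = "pleionet_config_error")
})

test_that("discovery summary is deterministically ordered", {
  df <- data.frame(trait = c("b", "a", "c"), level = c(1, 0, 0),
                   k = 1, K = 2, n = 3, N = 10,
                   p_hyper = c(0.01, 0.5, 0.2), overlap_snps = "",
                   stringsAsFactors = FALSE)
  s <- summarize_discovery(NULL, df)
  expect_equal(s$trait, c("c", "a", "b")) # level, then p, then name
  empty <- df[0, ]
  expect_equal(nrow(summarize_discovery(NULL, empty)), 0)
})
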