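test_that("fragments tile each chromosome exactly and SNPs map uniquely", {
  w <- default_world()
  # 2 chromosomes of 1 Mb at 4 kb fragments -> 250 + 250 fragments
  expect_equal(nrow(w$fragments), 500)
  for (ch in w$genome$chrom) {
    f <- w$fragments[w$fragments$chrom == ch, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], 0)
    expect_equal(f$end[nrow(f)], w$genome$length[w$genome$chrom == ch])
    expect_true(all(f$start[-1] == f$end[-nrow(f)])) # disjoint, gap-free
  }
  sf <- assign_fragments(w$snps, w$fragments)
  expect_length(sf, nrow(w$snps))
  expect_false(anyNA(sf))
})

test_that("world generation is a pure function of (config, seed)", {
  w1 <- gen_world(sim_config(n_snps = 50, n_genes = 10, n_true_eqtls = 5,
                             causal_gene_instruments = 2), seed = 42)
  w2 <- gen_world(sim_config(n_snps = 50, n_genes = 10, n_true_eqtls = 5,
                             causal_gene_instruments = 2), seed = 42)
  expect_identical(w1, w2)
  w3 <- gen_world(sim_config(n_snps = 50, n_genes = 10, n_true_eqtls = 5,
                             causal_gene_instruments = 2), seed = 43)
  expect_false(identical(w1$snps, w3$snps))
  # generators leave the global RNG stream untouched
  set.seed(7)
  before <- .Random.seed
  invisible(gen_world(sim_config(), seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_snps = 0), class = "pleionet_config_error")
  expect_error(sim_config(n_chromosomes = 0), class = "pleionet_config_error")
  expect_error(sim_config(gene_length_range = c(2e6, 3e6)),
               class = "pleionet_config_error")
  expect_error(sim_config(n_true_eqtls = 2, causal_gene_instruments = 5),
               class = "pleionet_config_error")
})

test_that("world invariants hold: r2 in [0,1], SNP inside one fragment, planted contacts exist", {
  w <- default_world()
  expect_true(all(w$ld$r2 >= 0 & w$ld$r2 <= 1))
  ld <- ld_resource(w$ld, w$snps[c("snp_id", "chrom", "pos")])
  expect_equal(ld_r2(ld, "rs00001", "rs00001"), 1)
  # planted-pair spatial witness: SNP fragment contacts a gene fragment
  sf <- assign_fragments(w$snps, w$fragments)
  ckey <- pleionet:::pair_key(w$contacts$fragment_a, w$contacts$fragment_b)
  truth <- w$truth$true_spatial_eqtls
  for (i in seq_len(nrow(truth))) {
    g <- w$genes[w$genes$gene_id == truth$gene_id[i], ]
    gf <- w$fragments$fragment_id[w$fragments$chrom == g$chrom &
                                    w$fragments$start < g$end &
                                    w$fragments$end > g$start]
    s <- unname(sf[truth$snp_id[i]])
    witness <- s %in% gf ||
      any(pleionet:::pair_key(rep(s, length(gf)), gf) %in% ckey)
    expect_true(witness, info = paste("pair", i))
  }
  # planted identifiers all exist in the world
  expect_true(all(truth$snp_id %in% w$snps$snp_id))
  expect_true(all(truth$gene_id %in% w$genes$gene_id))
  expect_true(all(names(w$truth$causal_genes) %in% w$genes$gene_id))
})

test_that("planted pairs get concentrated low p, null pairs uniform p", {
  # >= 1000 planted draws across seeds: all below 1e-6
  planted_p <- unlist(lapply(1:50, function(s) {
    w <- default_world()
    tab <- gen_eqtl_table(w, seed = s)
    key <- paste(tab$snp_id, tab$gene_id)
    tkey <- paste(w$truth$true_spatial_eqtls$snp_id,
                  w$truth$true_spatial_eqtls$gene_id)
    tab$p[key %in% tkey]
  }))
  expect_gte(length(planted_p), 1000)
  expect_true(all(planted_p <= 1e-6))

  # null p-values pass a KS uniformity check at alpha = 0.01, >= 10k draws
  null_p <- unlist(lapply(1:60, function(s) {
    w <- default_world()
    tab <- gen_eqtl_table(w, seed = 1000 + s)
    key <- paste(tab$snp_id, tab$gene_id)
    tkey <- paste(w$truth$true_spatial_eqtls$snp_id,
                  w$truth$true_spatial_eqtls$gene_id)
    tab$p[!(key %in% tkey)]
  }))
  expect_gte(length(null_p), 10000)
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif"))$p.value, 0.01)
})

test_that("a world without planted structure yields an all-null table", {
  cfg <- sim_config(n_true_eqtls = 0, causal_gene_instruments = 0)
  w0 <- gen_world(cfg, seed = 5)
  expect_equal(nrow(w0$truth$true_spatial_eqtls), 0)
  tab <- gen_eqtl_table(w0, null_p_uniform = FALSE, seed = 6)
  expect_true(all(tab$p == 1))
})

test_that("catalog plants the requested pleiotropic sharing", {
  w <- default_world()
  cat1 <- gen_gwas_catalog(w, n_traits = 5, pleiotropy_frac = 1,
                           trait_size = 10, seed = 3)
  planted <- cat1$snp[cat1$trait == "planted_trait_01"]
  expect_length(planted, 10)
  expect_true(all(planted %in% w$truth$query_snps))
  # containment by construction
  expect_true(all(cat1$snp %in% w$snps$snp_id))

  # pleiotropy_frac = 0: overlap matches the uniform-draw expectation
  cat0 <- gen_gwas_catalog(w, n_traits = 200, pleiotropy_frac = 0,
                           trait_size = 20, seed = 4)
  per_trait <- vapply(split(cat0$snp, cat0$trait), function(s) {
    length(intersect(s, w$truth$query_snps))
  }, numeric(1))
  m <- 20 * length(unique(w$truth$query_snps)) / nrow(w$snps)
  v <- m * (nrow(w$snps) - 20) / nrow(w$snps) *
    (nrow(w$snps) - length(unique(w$truth$query_snps))) / (nrow(w$snps) - 1)
  expect_lt(abs(mean(per_trait) - m), 3 * sqrt(v / 200))
})

test_that("MR summary generator honours theta, intercept and allele swaps", {
  w <- default_world()
  g <- names(w$truth$causal_genes)
  # theta = 0: mean ratio over 1000 instruments within 3 MC SE of 0
  s0 <- gen_mr_summary(w, g, n_instruments = 1000, theta = 0, seed = 8)
  ratio <- s0$outcome$beta / s0$exposure$beta
  expect_lt(abs(mean(ratio)), 3 * stats::sd(ratio) / sqrt(1000))
  # swap_frac = 0.5 on 50 instruments: exactly 25 rows need flipping
  s1 <- gen_mr_summary(w, g, n_instruments = 50, theta = 0.3, seed = 9,
                       swap_frac = 0.5)
  flipped <- s1$outcome$effect_allele == s1$exposure$other_allele &
    s1$outcome$other_allele == s1$exposure$effect_allele
  expect_equal(sum(flipped), 25)
  expect_error(gen_mr_summary(w, g, n_instruments = 0, theta = 0),
               class = "pleionet_config_error")
})

test_that("admission generator plants the requested odds ratios", {
  # OR = 1: sample OR within 2 SE of 1 at n = 50,000
  adm <- gen_admissions(50000, index_prevalence = 0.05,
                        or_map = c(J450 = 1), base_rates = c(J450 = 0.1),
                        seed = 21)
  tab <- build_contingency(adm, "F840", "J450")
  f <- fisher_or(tab["a"], tab["b"], tab["c"], tab["d"])
  se_log <- sqrt(sum(1 / pmax(tab, 0.5)))
  expect_lt(abs(log(f$odds_ratio)), 2 * se_log)
  # cell probabilities reproduce the planted OR exactly
  cells <- pleionet:::solve_joint_prob(0.01, 0.05, 4)
  expect_equal((cells["p11"] * cells["p00"]) /
                 (cells["p10"] * cells["p01"]), c(p11 = 4))
  # degenerate inputs rejected
  expect_error(gen_admissions(100, 0, c(A10 = 2), c(A10 = 0.1)),
               class = "pleionet_config_error")
  expect_error(gen_admissions(100, 0.1, c(A10 = -1), c(A10 = 0.1)),
               class = "pleionet_config_error")
  expect_error(gen_admissions(100, 0.1, c(A10 = 2), c(A10 = 1)),
               class = "pleionet_config_error")
})

test_that("world writers round-trip through plain-text formats", {
  w <- gen_world(sim_config(n_snps = 40, n_genes = 8, n_true_eqtls = 4,
                            causal_gene_instruments = 2), seed = 30)
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  genes_back <- read_genes_gff3(paths[["genes"]])
  expect_equal(genes_back[c("gene_id", "chrom", "start", "end", "strand")],
               w$genes[c("gene_id", "chrom", "start", "end", "strand")])
  expect_equal(genes_back$tpm, w$genes$tpm)
  snps_back <- pleionet:::read_tsv(paths[["snps"]])
  expect_equal(snps_back$snp_id, w$snps$snp_id)
  expect_equal(snps_back$pos, w$snps$pos)
})
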