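test_that("Wald ratio arithmetic and delta-method SE", {
  w <- wald_ratio(0.1, 0.2, 0.05)
  expect_equal(w$estimate, 2)
  expect_equal(w$se, 0.5)
  expect_equal(wald_ratio(0.1, 0, 0.05)$estimate, 0)
  expect_error(wald_ratio(0, 0.2, 0.05), class = "pleionet_input_error")
})

test_that("IVW matches the closed-form sums and reduces to Wald", {
  # hand-computed 3-instrument fixture
  bx <- c(0.2, 0.25, 0.18)
  by <- c(0.07, 0.06, 0.05)
  sy <- c(0.04, 0.05, 0.03)
  v <- ivw(bx, by, sy)
  w <- 1 / sy^2
  expect_equal(v$estimate, sum(w * bx * by) / sum(w * bx^2), tolerance = 1e-15)
  expect_equal(v$se, 1 / sqrt(sum(w * bx^2)), tolerance = 1e-15)

  # two identical instruments equal the single-instrument Wald ratio
  v2 <- ivw(c(0.2, 0.2), c(0.06, 0.06), c(0.05, 0.05))
  expect_equal(v2$estimate, wald_ratio(0.2, 0.06, 0.05)$estimate)

  # a single instrument split into two half-weight copies reproduces the
  # Wald ratio estimate and SE to machine precision
  wd <- wald_ratio(0.21, 0.065, 0.04)
  v1 <- ivw(c(0.21, 0.21), c(0.065, 0.065), c(0.04, 0.04) * sqrt(2))
  expect_equal(v1$estimate, wd$estimate, tolerance = 1e-15)
  expect_equal(v1$se, wd$se, tolerance = 1e-15)

  expect_error(ivw(0.2, 0.06, 0.05), class = "pleionet_input_error")
})

test_that("IVW recovers a planted causal effect", {
  w <- default_world()
  g <- names(w$truth$causal_genes)
  s <- gen_mr_summary(w, g, n_instruments = 50, theta = 0.3, seed = 17)
  inst <- harmonise(s$exposure, s$outcome)
  v <- ivw(inst$beta_exposure, inst$beta_outcome, inst$se_outcome)
  expect_lt(abs(v$estimate - 0.3), 2 * v$se)
})

test_that("Egger regression recovers slope and directional pleiotropy", {
  # exact linear data: slope recovered exactly, intercept 0
  bx <- seq(0.1, 0.3, length.out = 5)
  e <- egger(bx, 0.3 * bx, rep(0.05, 5))
  expect_equal(e$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)

  # planted intercept c = 0.05 over 100 instruments within 2 SE
  w <- default_world()
  g <- names(w$truth$causal_genes)
  s <- gen_mr_summary(w, g, n_instruments = 100, theta = 0.3,
                      intercept_c = 0.05, seed = 18)
  e2 <- egger(s$exposure$beta, s$outcome$beta, s$outcome$se)
  expect_lt(abs(e2$intercept - 0.05), 2 * e2$intercept_se)
  expect_lt(abs(e2$estimate - 0.3), 3 * e2$se)

  expect_error(egger(c(0.1, 0.2), c(0.03, 0.06), c(0.05, 0.05)),
               class = "pleionet_input_error")
})

test_that("Egger slope equals IVW when the intercept is constrained to zero", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    bx <- abs(rnorm(n, 0.2, 0.05))
    by <- 0.4 * bx + rnorm(n, 0, 0.05)
    sy <- runif(n, 0.03, 0.08)
    v <- ivw(bx, by, sy)
    constrained <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
    expect_equal(v$estimate, unname(coef(constrained)["bx"]),
                 tolerance = 1e-10)
  }
})

test_that("harmonisation flips swapped alleles and drops the unresolvable", {
  ex <- data.frame(snp_id = c("r1", "r2", "r3", "r4"), gene_id = "g",
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "G"),
                   beta = 0.2, se = 0.02, p = 1e-8,
                   stringsAsFactors = FALSE)
  ou <- data.frame(snp_id = c("r1", "r2", "r3", "r4"),
                   effect_allele = c("G", "A", "A", "C"),
                   other_allele = c("A", "G", "T", "T"),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = 0.05, p = 0.01,
                   stringsAsFactors = FALSE)
  h <- suppressMessages(harmonise(ex, ou))
  # r1 swapped -> sign flip; r2 straight; r3 palindromic A/T dropped;
  # r4 allele mismatch dropped
  expect_setequal(h$snp_id, c("r1", "r2"))
  expect_equal(h$beta_outcome[h$snp_id == "r1"], -0.1)
  expect_equal(h$beta_outcome[h$snp_id == "r2"], 0.1)

  # involution: applying the allele flip twice restores the original row
  flip <- function(row) {
    tmp <- row$effect_allele
    row$effect_allele <- row$other_allele
    row$other_allele <- tmp
    row$beta <- -row$beta
    row
  }
  expect_identical(flip(flip(ou[2, ])), ou[2, ])
  # ... and harmonising a once-flipped straight row undoes the flip
  h2 <- harmonise(ex[2, ], flip(ou[2, ]))
  expect_equal(h2$beta_outcome, ou$beta[2])
})

test_that("harmonising a swap-emitted table recovers the unswapped effects", {
  w <- default_world()
  g <- names(w$truth$causal_genes)
  s_plain <- gen_mr_summary(w, g, n_instruments = 40, theta = 0.3, seed = 20,
                            swap_frac = 0)
  s_swap <- gen_mr_summary(w, g, n_instruments = 40, theta = 0.3, seed = 20,
                           swap_frac = 0.5)
  h <- harmonise(s_swap$exposure, s_swap$outcome)
  expect_equal(h$beta_outcome[match(s_plain$outcome$snp_id, h$snp_id)],
               s_plain$outcome$beta)
})

test_that("instrument preparation filters by exposure p and clumps", {
  pos <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(1000, 2000, 50000), stringsAsFactors = FALSE)
  ld <- ld_resource(data.frame(snp_a = "a", snp_b = "b", r2 = 0.9), pos)
  ex <- data.frame(snp_id = c("a", "b", "c"), gene_id = "g",
                   effect_allele = "A", other_allele = "G",
                   beta = 0.2, se = 0.02,
                   p = c(1e-8, 1e-6, 2e-5), stringsAsFactors = FALSE)
  kept <- prepare_exposures(ex, p_max = 1e-5, ld = ld, clump_r2 = 0.1,
                            clump_window_bp = 1e6)
  # c removed by the p filter (2e-5 > 1e-5), b clumped away against a
  expect_equal(kept$snp_id, "a")
  # independent instruments at p <= 1e-5 are all retained
  ld0 <- ld_resource(data.frame(snp_a = character(0), snp_b = character(0),
                                r2 = numeric(0)), pos)
  kept2 <- prepare_exposures(ex[1:2, ], p_max = 1e-5, ld = ld0)
  expect_setequal(kept2$snp_id, c("a", "b"))
})

test_that("2SMR routes by instrument count and applies Bonferroni", {
  w <- default_world()
  genes <- sprintf("g%02d", 1:10)
  sims <- lapply(seq_along(genes), function(i) {
    gen_mr_summary(w, genes[i], n_instruments = if (i == 1) 1 else 5,
                   theta = if (i <= 2) 0.5 else 0, seed = 100 + i)
  })
  exposure <- do.call(rbind, lapply(sims, `[[`, "exposure"))
  outcome <- do.call(rbind, lapply(sims, `[[`, "outcome"))
  res <- run_2smr(exposure, outcome, alpha = 0.05)
  expect_equal(attr(res, "p_threshold"), 0.05 / 10)
  r1 <- res[res$gene_id == "g01", ]
  expect_equal(r1$method, "wald_ratio")
  expect_equal(r1$n_instruments, 1L)
  r2 <- res[res$gene_id == "g02", ]
  expect_setequal(r2$method, c("ivw", "egger"))
  expect_true(r2$primary[r2$method == "ivw"])
  expect_false(r2$primary[r2$method == "egger"])
  # the planted causal multi-instrument gene is flagged significant
  expect_true(r2$significant[r2$method == "ivw"])
  # null genes: family-wise behaviour sane under the threshold
  nulls <- res[res$primary & !(res$gene_id %in% c("g01", "g02")), ]
  expect_true(all(nulls$significant == (nulls$p < 0.005)))
})

test_that("under a global null the family-wise error stays near alpha", {
  w <- default_world()
  n_sig <- 0L
  n_rep <- 120
  for (rep in seq_len(n_rep)) {
    sims <- lapply(1:8, function(i) {
      gen_mr_summary(w, sprintf("h%02d", i), n_instruments = 4, theta = 0,
                     seed = 5000 + rep * 10 + i)
    })
    exposure <- do.call(rbind, lapply(sims, `[[`, "exposure"))
    outcome <- do.call(rbind, lapply(sims, `[[`, "outcome"))
    res <- run_2smr(exposure, outcome, alpha = 0.05)
    if (any(res$significant)) n_sig <- n_sig + 1L
  }
  # FWER <= alpha up to 3 Monte-Carlo SE
  expect_lte(n_sig / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
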