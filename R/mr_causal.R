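#' Filter and clump exposure instruments per gene
#'
#' Keeps exposure rows with p-value at or below `p_max` (instruments with
#' weaker evidence are removed), then clumps each gene's surviving SNPs to
#' independence with [clump()]. Genes left with no instruments are dropped
#' with a message.
#'
#' @param exposure data.frame (snp_id, gene_id, effect_allele,
#'   other_allele, beta, se, p)
#' @param p_max exposure p-value ceiling (default 1e-5)
#' @param ld an [ld_resource()] for clumping, or NULL to skip clumping
#' @param clump_r2 clumping r2 threshold (default 0.001)
#' @param clump_window_bp clumping window (default 10 Mb)
#' @return the filtered exposure data.frame, split-ready by gene_id
#' @export
prepare_exposures <- function(exposure, p_max = 1e-5, ld = NULL,
                              clump_r2 = 0.001, clump_window_bp = 1e7) {
  assert_columns(exposure, c("snp_id", "gene_id", "beta", "se", "p"),
                 "exposure table")
  if (any(exposure$se <= 0)) stop_input("exposure se must be > 0")
  kept <- exposure[exposure$p <= p_max, , drop = FALSE]
  if (!is.null(ld) && nrow(kept)) {
    keep_rows <- unlist(lapply(split(seq_len(nrow(kept)), kept$gene_id),
                               function(ii) {
      idx <- clump(kept$snp_id[ii], kept$p[ii], ld,
                   r2_max = clump_r2, window_bp = clump_window_bp)
      ii[kept$snp_id[ii] %in% idx]
    }), use.names = FALSE)
    kept <- kept[sort(keep_rows), , drop = FALSE]
  }
  dropped <- setdiff(unique(exposure$gene_id), unique(kept$gene_id))
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped with no surviving instruments")
  }
  rownames(kept) <- NULL
  kept
}

.palindromic <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Retains SNPs present in both tables. When the outcome's effect/other
#' alleles are swapped relative to the exposure, the outcome effect sign
#' is flipped and the alleles re-oriented. Palindromic SNPs (A/T or C/G)
#' are dropped outright, as are rows whose alleles cannot be reconciled.
#'
#' @param exposure data.frame (snp_id, gene_id, effect_allele,
#'   other_allele, beta, se, p)
#' @param outcome data.frame (snp_id, effect_allele, other_allele, beta,
#'   se, p)
#' @return instrument data.frame: snp_id, gene_id, effect_allele,
#'   other_allele, beta_exposure, se_exposure, p_exposure, beta_outcome,
#'   se_outcome, p_outcome
#' @export
harmonise <- function(exposure, outcome) {
  assert_columns(exposure, c("snp_id", "effect_allele", "other_allele",
                             "beta", "se", "p"), "exposure table")
  assert_columns(outcome, c("snp_id", "effect_allele", "other_allele",
                            "beta", "se", "p"), "outcome table")
  oi <- match(exposure$snp_id, outcome$snp_id)
  keep <- !is.na(oi)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[oi[keep], , drop = FALSE]
  straight <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  palin <- .palindromic(ex$effect_allele, ex$other_allele)
  usable <- (straight | swapped) & !palin
  n_drop <- sum(!usable)
  if (n_drop) {
    message(n_drop, " SNP(s) dropped during harmonisation (",
            sum(palin & (straight | swapped)), " palindromic, ",
            sum(!(straight | swapped)), " allele mismatch)")
  }
  ex <- ex[usable, , drop = FALSE]
  ou <- ou[usable, , drop = FALSE]
  sw <- swapped[usable]
  beta_out <- ifelse(sw, -ou$beta, ou$beta)
  data.frame(
    snp_id = ex$snp_id,
    gene_id = if ("gene_id" %in% names(ex)) ex$gene_id else NA_character_,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, p_exposure = ex$p,
    beta_outcome = beta_out, se_outcome = ou$se, p_outcome = ou$p,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' Estimate `beta_Y / beta_X` with first-order delta-method standard error
#' `se_Y / |beta_X|`; p-value from the normal approximation.
#'
#' @param beta_exposure,beta_outcome,se_outcome instrument statistics
#' @return list(estimate, se, p)
#' @export
wald_ratio <- function(beta_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) {
    stop_input("Wald ratio undefined: exposure effect is 0")
  }
  est <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' Fixed-effects inverse-variance weighted causal estimate
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights `1/se_Y^2`:
#' estimate `sum(w bX bY) / sum(w bX^2)`, standard error
#' `1 / sqrt(sum(w bX^2))` (fixed effects, no overdispersion scaling).
#'
#' @param beta_exposure,beta_outcome,se_outcome aligned instrument vectors
#'   (>= 2 instruments)
#' @return list(estimate, se, p)
#' @export
ivw <- function(beta_exposure, beta_outcome, se_outcome) {
  if (length(beta_exposure) < 2) {
    stop_input("IVW needs >= 2 instruments; use wald_ratio()")
  }
  w <- 1 / se_outcome^2
  est <- sum(w * beta_exposure * beta_outcome) / sum(w * beta_exposure^2)
  se <- 1 / sqrt(sum(w * beta_exposure^2))
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_Y^2`. Instruments are first oriented so
#' that all exposure effects are non-negative (the conventional sign
#' rule); the fitted intercept captures directional pleiotropy.
#'
#' @param beta_exposure,beta_outcome,se_outcome aligned instrument vectors
#'   (>= 3 instruments; slope plus intercept need residual d.f.)
#' @return list(estimate, se, p, intercept, intercept_se, intercept_p)
#' @export
egger <- function(beta_exposure, beta_outcome, se_outcome) {
  if (length(beta_exposure) < 3) {
    stop_input("MR-Egger needs >= 3 instruments")
  }
  flip <- sign(beta_exposure)
  flip[flip == 0] <- 1
  bx <- beta_exposure * flip
  by <- beta_outcome * flip
  fit <- stats::lm(by ~ bx, weights = 1 / se_outcome^2)
  cf <- summary(fit)$coefficients
  list(estimate = cf["bx", "Estimate"], se = cf["bx", "Std. Error"],
       p = cf["bx", "Pr(>|t|)"],
       intercept = cf["(Intercept)", "Estimate"],
       intercept_se = cf["(Intercept)", "Std. Error"],
       intercept_p = cf["(Intercept)", "Pr(>|t|)"])
}

#' Two-sample Mendelian randomisation over all genes
#'
#' Prepares instruments ([prepare_exposures()]), harmonises them against
#' the outcome statistics ([harmonise()]), then routes each gene by its
#' instrument count: one instrument uses the Wald ratio; two or more use
#' the fixed-effects IVW estimate (the primary result), with MR-Egger
#' reported as a sensitivity analysis when at least three instruments are
#' available. Significance is Bonferroni-controlled: the threshold is
#' `alpha` divided by the number of genes actually tested, applied to each
#' gene's primary p-value.
#'
#' @param exposure exposure data.frame (snp_id, gene_id, effect_allele,
#'   other_allele, beta, se, p)
#' @param outcome outcome data.frame (snp_id, effect_allele, other_allele,
#'   beta, se, p)
#' @param ld optional [ld_resource()] for clumping
#' @param p_max exposure p-value ceiling
#' @param alpha family-wise error target for the Bonferroni threshold
#' @param clump_r2,clump_window_bp clumping parameters
#' @return data.frame, one row per gene x method, with `primary` flagging
#'   the row driving the significance call; attribute `p_threshold`
#' @export
run_2smr <- function(exposure, outcome, ld = NULL, p_max = 1e-5,
                     alpha = 0.05, clump_r2 = 0.001,
                     clump_window_bp = 1e7) {
  kept <- prepare_exposures(exposure, p_max = p_max, ld = ld,
                            clump_r2 = clump_r2,
                            clump_window_bp = clump_window_bp)
  inst <- harmonise(kept, outcome)
  genes <- sort(unique(inst$gene_id))
  if (!length(genes)) {
    warning("no genes with usable instruments")
    res <- data.frame(gene_id = character(0), method = character(0),
                      n_instruments = integer(0), estimate = numeric(0),
                      se = numeric(0), p = numeric(0),
                      egger_intercept = numeric(0),
                      egger_intercept_se = numeric(0),
                      primary = logical(0), significant = logical(0))
    attr(res, "p_threshold") <- NA_real_
    return(res)
  }
  thr <- alpha / length(genes)
  rows <- list()
  for (g in genes) {
    d <- inst[inst$gene_id == g, , drop = FALSE]
    m <- nrow(d)
    if (m == 1) {
      w <- wald_ratio(d$beta_exposure, d$beta_outcome, d$se_outcome)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, method = "wald_ratio", n_instruments = 1L,
        estimate = w$estimate, se = w$se, p = w$p,
        egger_intercept = NA_real_, egger_intercept_se = NA_real_,
        primary = TRUE, stringsAsFactors = FALSE)
    } else {
      v <- ivw(d$beta_exposure, d$beta_outcome, d$se_outcome)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, method = "ivw", n_instruments = m,
        estimate = v$estimate, se = v$se, p = v$p,
        egger_intercept = NA_real_, egger_intercept_se = NA_real_,
        primary = TRUE, stringsAsFactors = FALSE)
      if (m >= 3) {
        e <- egger(d$beta_exposure, d$beta_outcome, d$se_outcome)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, method = "egger", n_instruments = m,
          estimate = e$estimate, se = e$se, p = e$p,
          egger_intercept = e$intercept,
          egger_intercept_se = e$intercept_se,
          primary = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$p_bonferroni_threshold <- thr
  res$significant <- res$primary & res$p < thr
  res <- res[order(res$p, res$gene_id, res$method), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_threshold") <- thr
  res
}

#' Build an exposure table from a GRN and the SNP annotation
#'
#' The significant spatial eQTL-gene pairs of a tissue GRN become the MR
#' exposure instruments: effect allele = ALT, other allele = REF, effect
#' statistics taken from the GRN record.
#'
#' @param grn a `grn`
#' @param snps SNP table (snp_id, ref, alt)
#' @return exposure data.frame for [run_2smr()]
#' @export
grn_exposures <- function(grn, snps) {
  assert_columns(snps, c("snp_id", "ref", "alt"), "SNP table")
  i <- match(grn$snp_id, snps$snp_id)
  if (anyNA(i)) stop_input("GRN SNP(s) missing from the SNP table")
  data.frame(
    snp_id = grn$snp_id, gene_id = grn$gene_id,
    effect_allele = snps$alt[i], other_allele = snps$ref[i],
    beta = grn$beta, se = grn$se, p = grn$p_nominal,
    stringsAsFactors = FALSE
  )
}
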