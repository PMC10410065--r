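#' Generate an eQTL association table over all spatial candidates
#'
#' Every spatial SNP-gene candidate pair in the world (fragment contact or
#' shared fragment) receives an effect size, a standard error and a nominal
#' p-value. Planted true pairs draw their p from a concentrated low-p
#' distribution, `10^(-U)` with `U ~ Uniform(6, 12)`, which keeps them below
#' 1e-6 and guarantees survival of Benjamini-Hochberg correction at desk
#' scale; their effect sizes are `N(mu_pair, effect_sd)` around the planted
#' per-pair mean. Non-planted pairs are null: `p ~ Uniform(0, 1)` (or
#' exactly 1 when `null_p_uniform = FALSE`, a noise-free null table useful
#' for exact assertions) and effects centred on zero.
#'
#' @param world a [gen_world()] result
#' @param effect_sd standard deviation of effect sizes around their mean
#' @param null_p_uniform draw null p-values uniformly (default) or pin them
#'   at 1
#' @param seed integer seed
#' @return data.frame with columns snp_id, gene_id, beta, se, p
#' @export
gen_eqtl_table <- function(world, effect_sd = 0.05, null_p_uniform = TRUE,
                           seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (effect_sd <= 0) stop_config("effect_sd must be > 0")
  snp_frags <- assign_fragments(world$snps, world$fragments)
  pairs <- find_spatial_pairs(snp_frags, world$genes, world$fragments,
                              world$contacts, include_same_fragment = TRUE)
  with_seed(seed, {
    truth <- world$truth$true_spatial_eqtls
    key <- paste(pairs$snp_id, pairs$gene_id)
    tkey <- paste(truth$snp_id, truth$gene_id)
    is_true <- key %in% tkey
    n <- nrow(pairs)
    p <- if (null_p_uniform) stats::runif(n) else rep(1, n)
    beta <- stats::rnorm(n, 0, effect_sd)
    if (any(is_true)) {
      idx <- match(key[is_true], tkey)
      p[is_true] <- 10^(-stats::runif(sum(is_true), 6, 12))
      beta[is_true] <- stats::rnorm(sum(is_true), truth$mu[idx], effect_sd)
    }
    data.frame(
      snp_id = pairs$snp_id, gene_id = pairs$gene_id,
      beta = beta,
      se = stats::runif(n, 0.02, 0.08),
      p = p,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a trait-SNP catalog with planted pleiotropic traits
#'
#' Emulates a GWAS trait catalog: each trait maps to a SNP set drawn from
#' the world's SNP universe. For each of the `n_pleiotropic` planted traits,
#' a fraction `pleiotropy_frac` of its SNPs is drawn from the query trait's
#' eQTL SNP set (the planted true spatial eQTLs), the remainder uniformly
#' from the rest of the universe. The planted sharing is recorded in the
#' `"planted"` attribute (trait name -> shared SNP ids).
#'
#' @param world a [gen_world()] result
#' @param n_traits number of traits (>= 1)
#' @param pleiotropy_frac fraction of a planted trait's SNPs shared with the
#'   query eQTL set, in [0, 1]
#' @param seed integer seed
#' @param n_pleiotropic number of planted pleiotropic traits
#' @param trait_size SNPs per trait
#' @return data.frame (trait, snp) with attribute `planted`
#' @export
gen_gwas_catalog <- function(world, n_traits = 30, pleiotropy_frac = 0.8,
                             seed = 1, n_pleiotropic = 1, trait_size = 20) {
  stopifnot(inherits(world, "synthetic_world"))
  if (n_traits < 1) stop_config("n_traits must be >= 1")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    stop_config("pleiotropy_frac must be in [0, 1]")
  }
  if (n_pleiotropic > n_traits) stop_config("n_pleiotropic > n_traits")
  with_seed(seed, {
    universe <- world$snps$snp_id
    query_set <- unique(world$truth$query_snps)
    n_share <- round(pleiotropy_frac * trait_size)
    if (n_share > length(query_set)) {
      stop_config("trait_size * pleiotropy_frac exceeds the query eQTL set")
    }
    planted <- list()
    rows <- vector("list", n_traits)
    for (i in seq_len(n_traits)) {
      if (i <= n_pleiotropic) {
        trait <- sprintf("planted_trait_%02d", i)
        shared <- sample(query_set, n_share)
        rest <- sample(setdiff(universe, shared), trait_size - n_share)
        planted[[trait]] <- shared
        snp <- c(shared, rest)
      } else {
        trait <- sprintf("trait_%02d", i)
        snp <- sample(universe, trait_size)
      }
      rows[[i]] <- data.frame(trait = trait, snp = snp,
                              stringsAsFactors = FALSE)
    }
    catalog <- do.call(rbind, rows)
    rownames(catalog) <- NULL
    attr(catalog, "planted") <- planted
    catalog
  })
}

#' Generate exposure/outcome GWAS summary statistics for one gene
#'
#' Simulates a two-sample MR input for a single gene: `n_instruments`
#' independent instruments with exposure effects `beta_X ~ N(0.2, 0.05^2)`
#' and fixed exposure SE, and outcome effects
#' `beta_Y = theta * beta_X + intercept_c + eps`, `eps ~ N(0, se_y^2)`.
#' `intercept_c` plants directional pleiotropy that an Egger intercept
#' should recover. A `swap_frac` fraction of outcome rows is emitted with
#' effect/other alleles swapped and the effect sign negated, so that allele
#' harmonisation is exercised (and, done correctly, restores the original
#' effect).
#'
#' @param world a [gen_world()] result (instrument SNP ids are drawn from
#'   the gene's planted eQTLs when available, otherwise synthesised)
#' @param gene gene id the instruments act through
#' @param n_instruments number of instruments (>= 1)
#' @param theta planted causal effect of exposure on outcome
#' @param intercept_c planted directional-pleiotropy intercept
#' @param seed integer seed
#' @param swap_frac fraction of outcome rows emitted allele-swapped
#' @param beta_x_mean,beta_x_sd exposure effect distribution
#' @param se_x,se_y exposure / outcome standard errors
#' @return list with data.frames `exposure` and `outcome`
#' @export
gen_mr_summary <- function(world, gene, n_instruments, theta,
                           intercept_c = 0, seed = 1, swap_frac = 0,
                           beta_x_mean = 0.2, beta_x_sd = 0.05,
                           se_x = 0.02, se_y = 0.05) {
  if (n_instruments < 1) stop_config("n_instruments must be >= 1")
  with_seed(seed, {
    planted <- world$truth$true_spatial_eqtls
    have <- planted$snp_id[planted$gene_id == gene]
    snp_id <- c(have, sprintf("%s_iv%03d",
                              gene, seq_len(max(0, n_instruments - length(have)))))
    snp_id <- snp_id[seq_len(n_instruments)]
    ap <- .allele_pairs[sample.int(nrow(.allele_pairs), n_instruments,
                                   replace = TRUE), , drop = FALSE]
    beta_x <- stats::rnorm(n_instruments, beta_x_mean, beta_x_sd)
    exposure <- data.frame(
      snp_id = snp_id, gene_id = gene,
      effect_allele = ap[, 2], other_allele = ap[, 1],
      beta = beta_x, se = se_x,
      p = 2 * stats::pnorm(-abs(beta_x / se_x)),
      stringsAsFactors = FALSE
    )
    beta_y <- theta * beta_x + intercept_c +
      stats::rnorm(n_instruments, 0, se_y)
    outcome <- data.frame(
      snp_id = snp_id,
      effect_allele = ap[, 2], other_allele = ap[, 1],
      beta = beta_y, se = se_y,
      p = 2 * stats::pnorm(-abs(beta_y / se_y)),
      stringsAsFactors = FALSE
    )
    n_swap <- round(swap_frac * n_instruments)
    if (n_swap > 0) {
      sw <- sample.int(n_instruments, n_swap)
      tmp <- outcome$effect_allele[sw]
      outcome$effect_allele[sw] <- outcome$other_allele[sw]
      outcome$other_allele[sw] <- tmp
      outcome$beta[sw] <- -outcome$beta[sw]
    }
    list(exposure = exposure, outcome = outcome)
  })
}

#' Generate outcome summary statistics for an existing exposure table
#'
#' Used by the pipeline demonstration: for every exposure row, the outcome
#' effect is `theta_gene * beta_X + intercept + eps` where `theta_gene`
#' comes from `theta_map` (0 for genes not named there).
#'
#' @param exposure exposure data.frame (snp_id, gene_id, effect_allele,
#'   other_allele, beta, se, p)
#' @param theta_map named numeric vector, gene id -> causal effect
#' @param intercept directional-pleiotropy constant
#' @param se_y outcome standard error
#' @param seed integer seed
#' @param swap_frac fraction of rows emitted allele-swapped
#' @return outcome data.frame (snp_id, effect_allele, other_allele, beta,
#'   se, p); one row per distinct SNP (the first gene context wins)
#' @export
gen_outcome_stats <- function(exposure, theta_map, intercept = 0,
                              se_y = 0.05, seed = 1, swap_frac = 0) {
  assert_columns(exposure, c("snp_id", "gene_id", "effect_allele",
                             "other_allele", "beta", "se"), "exposure table")
  with_seed(seed, {
    ex <- exposure[!duplicated(exposure$snp_id), , drop = FALSE]
    theta <- ifelse(ex$gene_id %in% names(theta_map),
                    theta_map[ex$gene_id], 0)
    n <- nrow(ex)
    beta_y <- theta * ex$beta + intercept + stats::rnorm(n, 0, se_y)
    out <- data.frame(
      snp_id = ex$snp_id,
      effect_allele = ex$effect_allele, other_allele = ex$other_allele,
      beta = beta_y, se = se_y,
      p = 2 * stats::pnorm(-abs(beta_y / se_y)),
      stringsAsFactors = FALSE
    )
    n_swap <- round(swap_frac * n)
    if (n_swap > 0) {
      sw <- sample.int(n, n_swap)
      tmp <- out$effect_allele[sw]
      out$effect_allele[sw] <- out$other_allele[sw]
      out$other_allele[sw] <- tmp
      out$beta[sw] <- -out$beta[sw]
    }
    out
  })
}

# Solve the index-and-code joint probability from the marginals and the
# odds ratio: with p11 = P(index & code), the 2x2 cell probabilities are
# determined by (prevalence, base rate, OR) through a quadratic in p11.
solve_joint_prob <- function(prevalence, base_rate, or) {
  if (or == 1) {
    p11 <- prevalence * base_rate
  } else {
    a <- or - 1
    b <- -(a * (prevalence + base_rate) + 1)
    cc <- or * prevalence * base_rate
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop_config("infeasible OR/rate combination")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    lo <- max(0, prevalence + base_rate - 1)
    hi <- min(prevalence, base_rate)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop_config("infeasible OR/rate combination")
    p11 <- min(max(roots[ok][1], lo), hi)
  }
  cells <- c(p11 = p11, p10 = prevalence - p11, p01 = base_rate - p11,
             p00 = 1 - prevalence - base_rate + p11)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12)) {
    stop_config("infeasible OR/rate combination: cell probability outside [0,1]")
  }
  pmin(pmax(cells, 0), 1)
}

#' Generate person-level admission records with planted co-occurrence
#'
#' Each individual carries an index-condition flag (prevalence
#' `index_prevalence`, recorded as an admission with `index_code`) and, for
#' every condition code in `or_map`, a presence flag sampled from the exact
#' 2x2 cell probabilities solved from (base rate, prevalence, odds ratio) -
#' so the population odds ratio for code `k` equals `or_map[k]`.
#' Individuals with no sampled condition receive a generic admission code
#' (`"Z000"`, general examination) so that every person appears in the
#' table and the downstream 2x2 denominators are well defined.
#'
#' @param n_individuals cohort size
#' @param index_prevalence P(index condition), in (0, 1)
#' @param or_map named numeric vector, condition code -> planted odds ratio
#'   (> 0)
#' @param base_rates named numeric vector, condition code -> marginal
#'   probability, in (0, 1); names must match `or_map`
#' @param seed integer seed
#' @param index_code ICD-10 code recorded for index individuals
#' @return data.frame (person_id, icd10_code), one row per distinct
#'   person-condition
#' @export
gen_admissions <- function(n_individuals, index_prevalence, or_map,
                           base_rates, seed = 1, index_code = "F840") {
  if (index_prevalence <= 0 || index_prevalence >= 1) {
    stop_config("index_prevalence must be in (0, 1)")
  }
  if (any(or_map <= 0)) stop_config("planted odds ratios must be > 0")
  if (any(base_rates <= 0) || any(base_rates >= 1)) {
    stop_config("base rates must be in (0, 1)")
  }
  if (!setequal(names(or_map), names(base_rates))) {
    stop_config("or_map and base_rates must name the same codes")
  }
  codes <- names(or_map)
  # validate feasibility up front (conditional probabilities in [0, 1])
  probs <- lapply(codes, function(k) {
    cells <- solve_joint_prob(index_prevalence, base_rates[[k]], or_map[[k]])
    c(p_given_index = cells[["p11"]] / index_prevalence,
      p_given_rest = cells[["p01"]] / (1 - index_prevalence))
  })
  names(probs) <- codes
  with_seed(seed, {
    person_id <- sprintf("P%06d", seq_len(n_individuals))
    index <- stats::runif(n_individuals) < index_prevalence
    rows <- list(data.frame(person_id = person_id[index],
                            icd10_code = index_code,
                            stringsAsFactors = FALSE))
    any_code <- index
    for (k in codes) {
      pr <- ifelse(index, probs[[k]][["p_given_index"]],
                   probs[[k]][["p_given_rest"]])
      has <- stats::runif(n_individuals) < pr
      any_code <- any_code | has
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = person_id[has], icd10_code = k, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      person_id = person_id[!any_code], icd10_code = "Z000",
      stringsAsFactors = FALSE)
    adm <- do.call(rbind, rows)
    adm <- adm[order(adm$person_id, adm$icd10_code), , drop = FALSE]
    rownames(adm) <- NULL
    adm
  })
}
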