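#' Construct a thresholded protein-interaction graph
#'
#' Keeps undirected edges with confidence score at or above `min_score`
#' (0.7 is the conventional high-confidence cutoff), drops self-loops, and
#' attaches the gene-protein mapping used to move between GRN gene space
#' and protein space.
#'
#' @param edges data.frame (protein_a, protein_b, score), scores in [0, 1]
#' @param gene_protein_map data.frame (gene_id, protein_id)
#' @param min_score minimum interaction score retained
#' @return a `ppin_graph` (igraph + mapping)
#' @export
ppin_graph <- function(edges, gene_protein_map, min_score = 0.7) {
  assert_columns(edges, c("protein_a", "protein_b", "score"), "PPIN edges")
  assert_columns(gene_protein_map, c("gene_id", "protein_id"),
                 "gene-protein map")
  if (any(edges$score < 0 | edges$score > 1)) {
    stop_input("interaction scores must lie in [0, 1]")
  }
  keep <- edges$score >= min_score & edges$protein_a != edges$protein_b
  kept <- edges[keep, , drop = FALSE]
  verts <- unique(c(edges$protein_a, edges$protein_b,
                    gene_protein_map$protein_id))
  g <- igraph::graph_from_data_frame(
    kept[c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(name = verts))
  structure(list(graph = g, map = gene_protein_map, min_score = min_score),
            class = "ppin_graph")
}

#' Build the level-0 query-specific network
#'
#' Subsets the tissue GRN to records whose eQTL SNP belongs to the
#' (LD-expanded) query SNP set; the distinct target genes of those records
#' form level 0.
#'
#' @param query_snps character vector of query SNP ids
#' @param grn a `grn` from [call_eqtls()]
#' @return list with `records` (the matching GRN rows) and `genes`
#' @export
build_level0 <- function(query_snps, grn) {
  records <- grn[grn$snp_id %in% query_snps, , drop = FALSE]
  if (nrow(records) == 0) {
    warning("query SNPs share no records with the GRN; level 0 is empty")
  }
  list(records = records, genes = sort(unique(records$gene_id)))
}

#' Expand the level-0 gene set through the protein-interaction network
#'
#' Maps level-0 genes to proteins (genes with no mapping are skipped) and
#' assigns every other protein its breadth-first shortest-path distance
#' from the level-0 protein set in the thresholded graph. Level L
#' (1 <= L <= `max_level`) contains exactly the proteins at distance L; a
#' protein reachable at several depths takes its minimum depth only, so
#' levels are disjoint by construction.
#'
#' @param level0_genes character vector of level-0 gene ids
#' @param ppin a [ppin_graph()]
#' @param max_level deepest level to expand to (default 4)
#' @return a `ppin_levels` list: `proteins` and `genes` per level (index 1
#'   = level 0), plus the unmapped level-0 genes
#' @export
expand_ppin <- function(level0_genes, ppin, max_level = 4) {
  stopifnot(inherits(ppin, "ppin_graph"))
  map <- ppin$map
  seed_prot <- map$protein_id[map$gene_id %in% level0_genes]
  unmapped <- setdiff(level0_genes, map$gene_id)
  proteins <- vector("list", max_level + 1)
  proteins[[1]] <- sort(unique(seed_prot))
  if (length(seed_prot)) {
    d <- igraph::distances(ppin$graph, v = proteins[[1]], mode = "all")
    dmin <- apply(d, 2, min)
    for (L in seq_len(max_level)) {
      proteins[[L + 1]] <- sort(names(dmin)[is.finite(dmin) & dmin == L])
    }
  } else {
    for (L in seq_len(max_level)) proteins[[L + 1]] <- character(0)
  }
  genes <- lapply(seq_along(proteins), function(i) {
    if (i == 1) sort(unique(level0_genes))
    else sort(unique(map$gene_id[map$protein_id %in% proteins[[i]]]))
  })
  structure(list(proteins = proteins, genes = genes,
                 unmapped_level0_genes = unmapped,
                 max_level = max_level),
            class = "ppin_levels")
}

#' Re-query the GRN with each level's genes
#'
#' For each network level, collects the GRN records whose target gene sits
#' on that level. SNP sets may overlap across levels (the same eQTL can
#' regulate genes on different levels).
#'
#' @param levels a [expand_ppin()] result
#' @param grn a `grn`
#' @return list per level (named "level0".."levelN") with `records` and
#'   the distinct `snps`
#' @export
requery_eqtls <- function(levels, grn) {
  stopifnot(inherits(levels, "ppin_levels"))
  out <- lapply(seq_along(levels$genes), function(i) {
    rec <- grn[grn$gene_id %in% levels$genes[[i]], , drop = FALSE]
    list(records = rec, snps = sort(unique(rec$snp_id)))
  })
  names(out) <- paste0("level", seq_along(out) - 1)
  out
}

#' Hypergeometric trait enrichment per network level
#'
#' For each (trait, level): with universe size N (all distinct catalog
#' SNPs), trait size K, level eQTL count n (restricted to the universe)
#' and overlap k, the enrichment p-value is the upper hypergeometric tail
#' `P(X >= k)` (the observed count included). Traits with p below `alpha`
#' are retained unless `keep_all` is set.
#'
#' @param level_eqtls a [requery_eqtls()] result (or any list with per-level
#'   `snps`)
#' @param catalog data.frame (trait, snp)
#' @param alpha retention threshold on the hypergeometric p
#' @param keep_all return all (trait, level) rows, not only significant ones
#' @param universe optional explicit SNP universe; defaults to all distinct
#'   catalog SNPs
#' @return data.frame (trait, level, k, K, n, N, p_hyper, overlap_snps)
#' @export
enrich_traits <- function(level_eqtls, catalog, alpha = 0.05,
                          keep_all = FALSE, universe = NULL) {
  assert_columns(catalog, c("trait", "snp"), "trait catalog")
  universe <- unique(universe %||% catalog$snp)
  N <- length(universe)
  trait_snps <- lapply(split(catalog$snp, catalog$trait),
                       function(s) unique(s[s %in% universe]))
  rows <- list()
  for (i in seq_along(level_eqtls)) {
    lvl <- i - 1L
    eq <- unique(level_eqtls[[i]]$snps)
    eq <- eq[eq %in% universe]
    n <- length(eq)
    if (n == 0) {
      warning("level ", lvl, " has no eQTLs in the universe; skipped")
      next
    }
    for (tr in names(trait_snps)) {
      K <- length(trait_snps[[tr]])
      ov <- intersect(trait_snps[[tr]], eq)
      k <- length(ov)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, level = lvl, k = k, K = K, n = n, N = N,
        p_hyper = p,
        overlap_snps = paste(sort(ov), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(0), level = integer(0), k = integer(0),
               K = integer(0), n = integer(0), N = integer(0),
               p_hyper = numeric(0), overlap_snps = character(0))
  if (!keep_all) res <- res[res$p_hyper < alpha, , drop = FALSE]
  res <- res[order(res$level, res$p_hyper, res$trait), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bootstrap configuration
#'
#' @param n_iter bootstrap iterations (the reference analysis used 1,000)
#' @param resample_size SNPs drawn per iteration; defaults at run time to
#'   the size of the expanded query SNP set
#' @param seed integer seed
#' @param threshold significance threshold on the bootstrap p (0.01 by
#'   default; 0.05 is the other conventional choice)
#' @param conservative use the (b + 1) / (n_iter + 1) variant instead of
#'   the plain count / n_iter formula
#' @return a `bootstrap_config`
#' @export
bootstrap_config <- function(n_iter = 1000, resample_size = NULL, seed = 1,
                             threshold = 0.01, conservative = FALSE) {
  if (n_iter < 1) stop_config("n_iter must be >= 1")
  if (!is.null(resample_size) && resample_size < 1) {
    stop_config("resample_size must be >= 1")
  }
  structure(list(n_iter = as.integer(n_iter), resample_size = resample_size,
                 seed = as.integer(seed), threshold = threshold,
                 conservative = conservative),
            class = "bootstrap_config")
}

#' Bootstrap p-value from observed and resampled overlap counts
#'
#' Implements the resampling formula verbatim: the p-value is the number
#' of iterations whose overlap is greater than or equal to the observed
#' overlap, divided by the number of iterations. With `conservative =
#' TRUE` the (b + 1) / (n + 1) variant is used.
#'
#' @param observed_k observed overlap count
#' @param boot_ks integer vector of per-iteration overlap counts
#' @param conservative add-one correction flag
#' @return p-value in [0, 1]
#' @export
bootstrap_pvalue <- function(observed_k, boot_ks, conservative = FALSE) {
  b <- sum(boot_ks >= observed_k)
  n <- length(boot_ks)
  if (conservative) (b + 1) / (n + 1) else b / n
}

#' Bootstrap null for trait enrichment
#'
#' For each iteration, draws `resample_size` distinct SNPs uniformly
#' without replacement from the catalog universe, reruns the discovery
#' chain (level-0 build, protein-network expansion, per-level eQTL
#' re-query) on the random draw, and records the per-(trait, level)
#' overlap with each trait's SNP set. The bootstrap p-value for an
#' observed enrichment is the fraction of iterations whose overlap reached
#' the observed overlap (see [bootstrap_pvalue()]).
#'
#' @param observed an [enrich_traits()] result (rows to score)
#' @param catalog data.frame (trait, snp)
#' @param grn a `grn`
#' @param ppin a [ppin_graph()]
#' @param cfg a [bootstrap_config()]; `resample_size` must be set here or
#'   via `resample_size`
#' @param resample_size overrides `cfg$resample_size`
#' @param max_level network depth, matching the observed run
#' @return `observed` with columns `p_bootstrap` and `significant` added
#' @export
bootstrap_null <- function(observed, catalog, grn, ppin, cfg,
                           resample_size = NULL, max_level = 4) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  universe <- unique(catalog$snp)
  size <- resample_size %||% cfg$resample_size
  if (is.null(size)) stop_config("resample_size is not set")
  if (size > length(universe)) {
    stop_config("resample_size (", size, ") exceeds the catalog universe (",
                length(universe), ")")
  }
  if (nrow(observed) == 0) {
    observed$p_bootstrap <- numeric(0)
    observed$significant <- logical(0)
    return(observed)
  }
  trait_snps <- lapply(split(catalog$snp, catalog$trait), unique)
  counts <- matrix(0L, nrow = nrow(observed), ncol = cfg$n_iter)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iter)) {
      draw <- sample(universe, size)
      lvl0 <- suppressWarnings(build_level0(draw, grn))
      levels <- expand_ppin(lvl0$genes, ppin, max_level = max_level)
      eq <- requery_eqtls(levels, grn)
      lvl_snps <- lapply(eq, `[[`, "snps")
      for (r in seq_len(nrow(observed))) {
        li <- observed$level[r] + 1L
        if (li <= length(lvl_snps)) {
          counts[r, it] <- length(intersect(trait_snps[[observed$trait[r]]],
                                            lvl_snps[[li]]))
        }
      }
    }
  })
  observed$p_bootstrap <- vapply(seq_len(nrow(observed)), function(r) {
    bootstrap_pvalue(observed$k[r], counts[r, ], cfg$conservative)
  }, numeric(1))
  observed$significant <- observed$p_bootstrap < cfg$threshold
  observed
}

#' Summarise a discovery run as one trait table
#'
#' One row per (trait, level) with the enrichment counts, hypergeometric
#' and bootstrap p-values, and the contributing eQTL-gene pairs, in
#' deterministic order (level, then hypergeometric p, then trait name).
#'
#' @param levels a [expand_ppin()] result
#' @param enrichments an [enrich_traits()] result
#' @param bootstrap a [bootstrap_null()] result (may be the same object)
#' @param level_eqtls the [requery_eqtls()] result used for enrichment
#' @return data.frame, the discovery table
#' @export
summarize_discovery <- function(levels, enrichments, bootstrap = NULL,
                                level_eqtls = NULL) {
  res <- enrichments
  if (!is.null(bootstrap) && nrow(res)) {
    key <- paste(res$trait, res$level)
    bkey <- paste(bootstrap$trait, bootstrap$level)
    res$p_bootstrap <- bootstrap$p_bootstrap[match(key, bkey)]
    res$significant <- bootstrap$significant[match(key, bkey)]
  }
  if (!is.null(level_eqtls) && nrow(res)) {
    res$eqtl_gene_pairs <- vapply(seq_len(nrow(res)), function(r) {
      li <- res$level[r] + 1L
      rec <- level_eqtls[[li]]$records
      ov <- strsplit(res$overlap_snps[r], ",", fixed = TRUE)[[1]]
      rec <- rec[rec$snp_id %in% ov, , drop = FALSE]
      paste(sprintf("%s>%s", rec$snp_id, rec$gene_id), collapse = ";")
    }, character(1))
  }
  res <- res[order(res$level, res$p_hyper, res$trait), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full trait-discovery chain
#'
#' Convenience wrapper: level-0 build from the query SNPs, network
#' expansion, per-level eQTL re-query, hypergeometric enrichment, and
#' (optionally) the bootstrap null.
#'
#' @param query_snps character vector of (LD-expanded) query SNP ids
#' @param grn a `grn`
#' @param ppin a [ppin_graph()]
#' @param catalog data.frame (trait, snp)
#' @param alpha hypergeometric retention threshold
#' @param max_level network depth
#' @param bootstrap_cfg a [bootstrap_config()] or NULL to skip the null
#' @return list: `level0`, `levels`, `level_eqtls`, `enrichment`, `table`
#' @export
discover_traits <- function(query_snps, grn, ppin, catalog, alpha = 0.05,
                            max_level = 4, bootstrap_cfg = NULL) {
  lvl0 <- build_level0(query_snps, grn)
  levels <- expand_ppin(lvl0$genes, ppin, max_level = max_level)
  eq <- requery_eqtls(levels, grn)
  enr <- enrich_traits(eq, catalog, alpha = alpha)
  if (!is.null(bootstrap_cfg)) {
    enr <- bootstrap_null(enr, catalog, grn, ppin, bootstrap_cfg,
                          resample_size = bootstrap_cfg$resample_size %||%
                            length(unique(query_snps)),
                          max_level = max_level)
  }
  list(level0 = lvl0, levels = levels, level_eqtls = eq, enrichment = enr,
       table = summarize_discovery(levels, enr, enr, eq))
}
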