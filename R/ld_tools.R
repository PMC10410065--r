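#' Build a pairwise-LD lookup resource
#'
#' Wraps a sparse pairwise r-squared table and a SNP position table.
#' Lookups are symmetric, r2 of a SNP with itself is 1, and a pair absent
#' from the table is treated as unlinked (r2 = 0).
#'
#' @param pairs data.frame (snp_a, snp_b, r2), r2 in [0, 1]
#' @param positions data.frame (snp_id, chrom, pos)
#' @return an `ld_resource`
#' @export
ld_resource <- function(pairs, positions) {
  assert_columns(pairs, c("snp_a", "snp_b", "r2"), "LD pair table")
  assert_columns(positions, c("snp_id", "chrom", "pos"), "SNP position table")
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
    stop_input("r2 values must lie in [0, 1]")
  }
  key <- pair_key(pairs$snp_a, pairs$snp_b)
  # keep the last entry for a duplicated pair
  lut <- stats::setNames(pairs$r2, key)
  lut <- lut[!duplicated(names(lut), fromLast = TRUE)]
  structure(list(lut = lut, pairs = pairs, positions = positions),
            class = "ld_resource")
}

#' Look up pairwise r-squared values
#' @param ld an [ld_resource()]
#' @param a,b SNP id vectors (recycled to common length)
#' @return numeric vector of r2 values
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_resource"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- unname(ld$lut[pair_key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

ld_pos <- function(ld, snp) {
  i <- match(snp, ld$positions$snp_id)
  if (anyNA(i)) {
    stop_input("SNP(s) without a position: ",
               paste(utils::head(snp[is.na(i)], 5), collapse = ", "))
  }
  ld$positions[i, , drop = FALSE]
}

#' Expand a query SNP set through linkage disequilibrium
#'
#' Returns the query SNPs plus every SNP with r2 >= `r2_min` to some query
#' SNP and within `width_bp` of it (the width is applied as +/- `width_bp`
#' around the index SNP). Each added SNP is tagged with its best index SNP:
#' highest r2, ties broken by distance, then lexicographic id.
#'
#' @param query_snps character vector of query SNP ids
#' @param ld an [ld_resource()]
#' @param r2_min LD threshold (default 0.8)
#' @param width_bp window half-width in bp (default 5000)
#' @return data.frame (snp_id, index_snp); query SNPs index themselves
#' @export
expand_ld <- function(query_snps, ld, r2_min = 0.8, width_bp = 5000) {
  stopifnot(inherits(ld, "ld_resource"))
  query_snps <- unique(query_snps)
  qpos <- ld_pos(ld, query_snps)
  # candidate partners come from the sparse pair table
  pr <- ld$pairs
  cand <- rbind(
    data.frame(snp = pr$snp_b, index = pr$snp_a, r2 = pr$r2,
               stringsAsFactors = FALSE),
    data.frame(snp = pr$snp_a, index = pr$snp_b, r2 = pr$r2,
               stringsAsFactors = FALSE)
  )
  cand <- cand[cand$index %in% query_snps & cand$r2 >= r2_min &
                 !(cand$snp %in% query_snps), , drop = FALSE]
  if (nrow(cand)) {
    pi_ <- ld$positions[match(cand$index, ld$positions$snp_id), ]
    ps <- ld$positions[match(cand$snp, ld$positions$snp_id), ]
    ok <- !is.na(ps$pos) & ps$chrom == pi_$chrom &
      abs(ps$pos - pi_$pos) <= width_bp
    cand <- cand[ok, , drop = FALSE]
    cand$dist <- abs(ps$pos[ok] - pi_$pos[ok])
    cand <- cand[order(cand$snp, -cand$r2, cand$dist, cand$index), ,
                 drop = FALSE]
    cand <- cand[!duplicated(cand$snp), , drop = FALSE]
  }
  out <- rbind(
    data.frame(snp_id = query_snps, index_snp = query_snps,
               stringsAsFactors = FALSE),
    if (nrow(cand)) data.frame(snp_id = cand$snp, index_snp = cand$index,
                               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping for instrument independence
#'
#' Sorts SNPs by ascending p-value (ties by id) and accepts a SNP iff its
#' r2 with every previously accepted SNP within `window_bp` is below
#' `r2_max`. Defaults follow the conventional two-sample MR instrument
#' settings (r2 < 0.001 within 10 Mb).
#'
#' @param snps character vector of SNP ids
#' @param pvalues numeric vector aligned with `snps`
#' @param ld an [ld_resource()]
#' @param r2_max exclusion threshold: accepted pairs must have r2 below it
#' @param window_bp window within which the r2 constraint applies
#' @return character vector of accepted (index) SNPs, in acceptance order
#' @export
clump <- function(snps, pvalues, ld, r2_max = 0.001, window_bp = 1e7) {
  stopifnot(inherits(ld, "ld_resource"), length(snps) == length(pvalues))
  if (!length(snps)) return(character(0))
  pos <- ld_pos(ld, snps)
  ord <- order(pvalues, snps)
  accepted <- integer(0)
  for (i in ord) {
    in_window <- accepted[pos$chrom[accepted] == pos$chrom[i] &
                            abs(pos$pos[accepted] - pos$pos[i]) <= window_bp]
    if (!length(in_window) ||
        all(ld_r2(ld, snps[i], snps[in_window]) < r2_max)) {
      accepted <- c(accepted, i)
    }
  }
  snps[accepted]
}

#' Group SNPs into LD loci by single-linkage clustering
#'
#' Connects two SNPs when r2 >= `r2_min` and they lie within `width_bp` of
#' each other on the same chromosome; connected components of the
#' resulting graph become loci. The locus index SNP is the member with the
#' lowest p-value (first id when no p-values are supplied).
#'
#' @inheritParams expand_ld
#' @param snps character vector of SNP ids to group
#' @param pvalues optional numeric vector aligned with `snps`
#' @return data.frame (snp_id, locus_id, index_snp, chrom, span_start,
#'   span_end); loci partition the input
#' @export
group_loci <- function(snps, ld, r2_min = 0.8, width_bp = 5000,
                       pvalues = NULL) {
  stopifnot(inherits(ld, "ld_resource"))
  snps <- unique(snps)
  if (!length(snps)) {
    return(data.frame(snp_id = character(0), locus_id = character(0),
                      index_snp = character(0), chrom = character(0),
                      span_start = integer(0), span_end = integer(0)))
  }
  pos <- ld_pos(ld, snps)
  pr <- ld$pairs[ld$pairs$snp_a %in% snps & ld$pairs$snp_b %in% snps &
                   ld$pairs$r2 >= r2_min, , drop = FALSE]
  if (nrow(pr)) {
    pa <- pos[match(pr$snp_a, snps), ]
    pb <- pos[match(pr$snp_b, snps), ]
    pr <- pr[pa$chrom == pb$chrom & abs(pa$pos - pb$pos) <= width_bp, ,
             drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    pr[c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = snps))
  comp <- igraph::components(g)$membership[snps]
  pv <- if (is.null(pvalues)) rep(NA_real_, length(snps)) else pvalues
  out <- data.frame(snp_id = snps, comp = unname(comp),
                    chrom = pos$chrom, pos = pos$pos, p = pv,
                    stringsAsFactors = FALSE)
  idx_by_comp <- vapply(split(seq_len(nrow(out)), out$comp), function(ii) {
    o <- out[ii, , drop = FALSE]
    if (all(is.na(o$p))) sort(o$snp_id)[1]
    else o$snp_id[order(o$p, o$snp_id)][1]
  }, character(1))
  span <- lapply(split(seq_len(nrow(out)), out$comp), function(ii) {
    c(min(out$pos[ii]), max(out$pos[ii]))
  })
  comp_id <- as.character(out$comp)
  res <- data.frame(
    snp_id = out$snp_id,
    locus_id = sprintf("locus_%03d", out$comp),
    index_snp = unname(idx_by_comp[comp_id]),
    chrom = out$chrom,
    span_start = vapply(comp_id, function(k) span[[k]][1], numeric(1)),
    span_end = vapply(comp_id, function(k) span[[k]][2], numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}
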