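#' Assign each SNP to the restriction fragment containing it
#'
#' Fragments are 0-based half-open intervals tiling each chromosome; a SNP
#' at position `pos` maps to the unique fragment with
#' `start <= pos < end`.
#'
#' @param snps data.frame with columns snp_id, chrom, pos
#' @param fragments data.frame with columns chrom, start, end, fragment_id
#' @return named character vector snp_id -> fragment_id
#' @export
assign_fragments <- function(snps, fragments) {
  assert_columns(snps, c("snp_id", "chrom", "pos"), "SNP table")
  assert_columns(fragments, c("chrom", "start", "end", "fragment_id"),
                 "fragment table")
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start + 1L, fragments$end))
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos + 1L, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, frag_gr))
  idx <- rep(NA_integer_, nrow(snps))
  idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  if (anyNA(idx)) {
    bad <- snps$snp_id[is.na(idx)]
    stop_input("SNP(s) outside all fragments: ",
               paste(utils::head(bad, 5), collapse = ", "),
               if (length(bad) > 5) " ..." else "")
  }
  stats::setNames(fragments$fragment_id[idx], snps$snp_id)
}

#' Find spatial SNP-gene candidate pairs gated by chromatin contacts
#'
#' A pair (SNP s, gene g) is emitted iff some fragment overlapping g forms
#' a contact with s's fragment - or equals it, when same-fragment pairs are
#' enabled (a SNP inside a gene's own fragment is trivially spatially
#' proximal). A gene overlapping several fragments yields at most one pair
#' per SNP. Contacts are unordered; duplicates and orientation are ignored.
#'
#' @param snp_frags named vector snp_id -> fragment_id
#'   (from [assign_fragments()])
#' @param genes gene data.frame (gene_id, chrom, start, end)
#' @param fragments fragment data.frame (chrom, start, end, fragment_id)
#' @param contacts data.frame (fragment_a, fragment_b), unordered pairs
#' @param include_same_fragment also emit pairs where the SNP's fragment
#'   itself overlaps the gene
#' @return data.frame (snp_id, gene_id, snp_fragment, gene_fragment,
#'   same_fragment)
#' @export
find_spatial_pairs <- function(snp_frags, genes, fragments, contacts,
                               include_same_fragment = TRUE) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  assert_columns(contacts, c("fragment_a", "fragment_b"), "contact table")
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, frag_gr))
  gene_frag <- data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    gene_fragment = fragments$fragment_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  snp_df <- data.frame(snp_id = names(snp_frags),
                       snp_fragment = unname(snp_frags),
                       stringsAsFactors = FALSE)
  # contact partners of each SNP fragment, both orientations
  both <- rbind(
    stats::setNames(contacts[c("fragment_a", "fragment_b")], c("f", "partner")),
    stats::setNames(contacts[c("fragment_b", "fragment_a")], c("f", "partner"))
  )
  both <- unique(both)
  sp <- merge(snp_df, both, by.x = "snp_fragment", by.y = "f")
  via_contact <- merge(sp, gene_frag, by.x = "partner", by.y = "gene_fragment")
  out <- data.frame(
    snp_id = via_contact$snp_id, gene_id = via_contact$gene_id,
    snp_fragment = via_contact$snp_fragment,
    gene_fragment = via_contact$partner,
    same_fragment = rep(FALSE, nrow(via_contact)), stringsAsFactors = FALSE
  )
  if (include_same_fragment) {
    same <- merge(snp_df, gene_frag, by.x = "snp_fragment",
                  by.y = "gene_fragment")
    if (nrow(same)) {
      out <- rbind(data.frame(
        snp_id = same$snp_id, gene_id = same$gene_id,
        snp_fragment = same$snp_fragment, gene_fragment = same$snp_fragment,
        same_fragment = TRUE, stringsAsFactors = FALSE
      ), out)
    }
  }
  # one pair per (snp, gene); same-fragment witness wins, then lowest
  # fragment id, for a deterministic representative
  out <- out[order(out$snp_id, out$gene_id, !out$same_fragment,
                   out$gene_fragment), , drop = FALSE]
  out <- out[!duplicated(out[c("snp_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a regulatory interaction as cis or trans
#'
#' Same chromosome and SNP-to-gene distance under 1 Mb is cis; same
#' chromosome at 1 Mb or more is trans-intrachromosomal; different
#' chromosomes is trans-interchromosomal. Distance is measured from the
#' SNP position to the nearest gene boundary and is 0 when the SNP lies
#' inside the gene; exactly 1 Mb classifies as trans.
#'
#' @param snp_chrom,snp_pos SNP coordinates (0-based position)
#' @param gene_chrom,gene_start,gene_end gene interval (0-based half-open)
#' @param cis_max_bp cis/trans distance threshold in bp
#' @return character vector in {"cis", "trans_intrachromosomal",
#'   "trans_interchromosomal"}
#' @export
classify_interaction <- function(snp_chrom, snp_pos, gene_chrom,
                                 gene_start, gene_end, cis_max_bp = 1e6) {
  dist <- pmax(0, gene_start - snp_pos, snp_pos - (gene_end - 1L))
  ifelse(snp_chrom != gene_chrom, "trans_interchromosomal",
         ifelse(dist < cis_max_bp, "cis", "trans_intrachromosomal"))
}

#' Call significant spatially constrained eQTLs
#'
#' Removes rare SNPs (MAF below `maf_min`) before testing, applies
#' Benjamini-Hochberg correction jointly over all remaining spatial
#' candidate pairs, retains records with adjusted p <= `alpha`, and
#' annotates each retained record with its interaction class and the
#' target gene's expression (TPM).
#'
#' @param pairs spatial candidate pairs (from [find_spatial_pairs()])
#' @param assoc association table (snp_id, gene_id, beta, se, p)
#' @param snps SNP table (snp_id, chrom, pos, maf)
#' @param genes gene table (gene_id, chrom, start, end, tpm)
#' @param maf_min minor allele frequency floor (common variants only)
#' @param alpha adjusted-p significance threshold
#' @param tissue provenance label carried on the result
#' @return a `grn` data.frame: snp_id, gene_id, beta, se, p_nominal,
#'   p_adjusted, interaction_class, gene_tpm
#' @export
call_eqtls <- function(pairs, assoc, snps, genes, maf_min = 0.05,
                       alpha = 0.05, tissue = "synthetic") {
  assert_columns(assoc, c("snp_id", "gene_id", "beta", "se", "p"),
                 "association table")
  assert_columns(snps, c("snp_id", "chrom", "pos", "maf"), "SNP table")
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  keep_snps <- snps$snp_id[snps$maf >= maf_min]
  cand <- pairs[pairs$snp_id %in% keep_snps, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_grn(tissue))
  key <- paste(cand$snp_id, cand$gene_id)
  akey <- paste(assoc$snp_id, assoc$gene_id)
  idx <- match(key, akey)
  if (anyNA(idx)) {
    stop_input(sum(is.na(idx)),
               " spatial pair(s) missing from the association table")
  }
  p_nominal <- assoc$p[idx]
  p_adjusted <- stats::p.adjust(p_nominal, method = "BH")
  sel <- p_adjusted <= alpha
  res <- data.frame(
    snp_id = cand$snp_id[sel], gene_id = cand$gene_id[sel],
    beta = assoc$beta[idx][sel], se = assoc$se[idx][sel],
    p_nominal = p_nominal[sel], p_adjusted = p_adjusted[sel],
    stringsAsFactors = FALSE
  )
  si <- match(res$snp_id, snps$snp_id)
  gi <- match(res$gene_id, genes$gene_id)
  res$interaction_class <- classify_interaction(
    snps$chrom[si], snps$pos[si],
    genes$chrom[gi], genes$start[gi], genes$end[gi])
  res$gene_tpm <- if ("tpm" %in% names(genes)) genes$tpm[gi] else NA_real_
  res <- res[order(res$p_adjusted, res$snp_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("grn", "data.frame"),
            tissue = tissue,
            params = list(maf_min = maf_min, alpha = alpha),
            n_tested = nrow(cand))
}

empty_grn <- function(tissue = "synthetic") {
  structure(
    data.frame(snp_id = character(0), gene_id = character(0),
               beta = numeric(0), se = numeric(0), p_nominal = numeric(0),
               p_adjusted = numeric(0), interaction_class = character(0),
               gene_tpm = numeric(0), stringsAsFactors = FALSE),
    class = c("grn", "data.frame"), tissue = tissue,
    params = list(), n_tested = 0L)
}

#' Build a tissue GRN from a synthetic world in one call
#'
#' Convenience wrapper chaining [assign_fragments()],
#' [find_spatial_pairs()] and [call_eqtls()].
#'
#' @inheritParams call_eqtls
#' @param world a [gen_world()] result
#' @param assoc association table (e.g. from [gen_eqtl_table()])
#' @param include_same_fragment passed to [find_spatial_pairs()]
#' @return a `grn` (see [call_eqtls()])
#' @export
build_grn <- function(world, assoc, maf_min = 0.05, alpha = 0.05,
                      include_same_fragment = TRUE, tissue = "synthetic") {
  snp_frags <- assign_fragments(world$snps, world$fragments)
  pairs <- find_spatial_pairs(snp_frags, world$genes, world$fragments,
                              world$contacts, include_same_fragment)
  call_eqtls(pairs, assoc, world$snps, world$genes, maf_min, alpha, tissue)
}
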