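#' Simulation configuration for a synthetic genome world
#'
#' Defines the scale and planted structure of a [gen_world()] simulation:
#' a fragment-partitioned genome with gene annotation, SNPs with
#' block-structured LD and minor allele frequencies, fragment-fragment
#' chromatin contacts, a weighted protein-interaction network, and planted
#' true spatial eQTLs including one causal gene with multiple independent
#' instruments.
#'
#' Defaults describe a desk-scale world: two 1 Mb chromosomes cut into 4 kb
#' restriction fragments, 40 genes, 300 common-to-rare SNPs in tight LD
#' blocks, and 20 planted true SNP-gene regulatory pairs of which 5 target a
#' single causal gene.
#'
#' @param n_chromosomes number of chromosomes (>= 1)
#' @param chromosome_length chromosome length in bp (scalar, recycled)
#' @param fragment_bp restriction-fragment length in bp (> 0)
#' @param n_genes number of genes (>= 1)
#' @param gene_length_range min/max gene length in bp
#' @param n_snps number of SNPs (>= 1)
#' @param maf_range min/max minor allele frequency
#' @param ld_block_size number of SNPs per LD block
#' @param ld_jitter_bp half-width of the positional spread of a block's SNPs
#'   around its centre; keeps within-block SNPs inside typical LD windows
#' @param ld_r2_range range of within-block pairwise r-squared values
#' @param n_contacts number of random fragment-fragment contacts (planted
#'   pairs always receive a supporting contact in addition)
#' @param n_true_eqtls number of planted true spatial eQTL pairs
#' @param causal_gene_instruments how many of the planted pairs converge on
#'   the single planted causal gene (its MR instruments)
#' @param causal_theta planted causal effect of that gene on the outcome
#' @param n_extra_proteins proteins in the interaction network beyond those
#'   encoded by genes
#' @param n_ppin_edges random protein-interaction edges
#' @param ppin_score_range range of interaction confidence scores
#' @param unmapped_gene_frac fraction of genes with no protein mapping
#'   (exercises the unmapped-gene skip path during network expansion)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2,
                       chromosome_length = 1e6,
                       fragment_bp = 4000,
                       n_genes = 40,
                       gene_length_range = c(2000, 20000),
                       n_snps = 300,
                       maf_range = c(0.01, 0.5),
                       ld_block_size = 4,
                       ld_jitter_bp = 2000,
                       ld_r2_range = c(0.5, 1),
                       n_contacts = 400,
                       n_true_eqtls = 20,
                       causal_gene_instruments = 5,
                       causal_theta = 0.5,
                       n_extra_proteins = 40,
                       n_ppin_edges = 160,
                       ppin_score_range = c(0.3, 1),
                       unmapped_gene_frac = 0.05) {
  cfg <- list(
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    fragment_bp = fragment_bp, n_genes = n_genes,
    gene_length_range = gene_length_range, n_snps = n_snps,
    maf_range = maf_range, ld_block_size = ld_block_size,
    ld_jitter_bp = ld_jitter_bp, ld_r2_range = ld_r2_range,
    n_contacts = n_contacts, n_true_eqtls = n_true_eqtls,
    causal_gene_instruments = causal_gene_instruments,
    causal_theta = causal_theta, n_extra_proteins = n_extra_proteins,
    n_ppin_edges = n_ppin_edges, ppin_score_range = ppin_score_range,
    unmapped_gene_frac = unmapped_gene_frac
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1) stop_config("n_chromosomes must be >= 1")
  if (any(cfg$chromosome_length <= 0)) stop_config("chromosome_length must be > 0")
  if (cfg$fragment_bp <= 0) stop_config("fragment_bp must be > 0")
  if (cfg$n_genes < 1) stop_config("n_genes must be >= 1")
  if (cfg$n_snps < 1) stop_config("n_snps must be >= 1")
  if (max(cfg$gene_length_range) >= min(cfg$chromosome_length)) {
    stop_config("genes cannot be longer than the shortest chromosome")
  }
  if (cfg$maf_range[1] < 0 || cfg$maf_range[2] > 0.5) {
    stop_config("maf_range must lie within [0, 0.5]")
  }
  if (cfg$n_true_eqtls < cfg$causal_gene_instruments) {
    stop_config("n_true_eqtls must be >= causal_gene_instruments")
  }
  if (cfg$n_true_eqtls > cfg$n_snps) stop_config("more planted pairs than SNPs")
  invisible(cfg)
}

# non-palindromic allele pairs only, so harmonisation never has to guess
.allele_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

#' Generate a synthetic world with planted ground truth
#'
#' Builds the complete input universe that the downstream stages consume:
#' genome, restriction-fragment tiling (0-based half-open, BED convention),
#' genes with TPM expression, SNPs with MAF and block LD, chromatin
#' contacts, a protein-interaction network with a gene-protein map, and a
#' `truth` record naming every planted signal (true spatial eQTL pairs, the
#' query SNP set, the causal gene and its effect).
#'
#' Every planted SNP-gene pair is guaranteed a supporting contact between
#' the SNP's fragment and a fragment overlapping the gene, and planted SNPs
#' have MAF >= 0.05 so they survive the common-variant filter.
#'
#' @param config a [sim_config()]
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed)
#' @return a list of class `synthetic_world` with elements `genome`,
#'   `fragments`, `genes`, `snps`, `ld`, `contacts`, `ppin`,
#'   `gene_protein_map`, `truth`
#' @export
gen_world <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    lens <- rep_len(config$chromosome_length, config$n_chromosomes)
    genome <- data.frame(chrom = chroms, length = lens,
                         stringsAsFactors = FALSE)

    # fragments tile each chromosome exactly: union = [0, length), disjoint
    fragments <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      starts <- seq(0, lens[i] - 1, by = config$fragment_bp)
      data.frame(
        chrom = chroms[i],
        start = starts,
        end = pmin(starts + config$fragment_bp, lens[i]),
        fragment_id = sprintf("frag_%s_%05d", chroms[i], seq_along(starts)),
        stringsAsFactors = FALSE
      )
    }))
    rownames(fragments) <- NULL

    glen <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                               config$gene_length_range[2]))
    gchrom_i <- sample.int(config$n_chromosomes, config$n_genes, replace = TRUE)
    gstart <- floor(stats::runif(config$n_genes) * (lens[gchrom_i] - glen))
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
      chrom = chroms[gchrom_i],
      start = gstart,
      end = gstart + glen,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      tpm = round(stats::rlnorm(config$n_genes, log(5), 1), 2),
      stringsAsFactors = FALSE
    )

    # SNPs in tight positional LD blocks
    n_blocks <- ceiling(config$n_snps / config$ld_block_size)
    block_chrom_i <- sample.int(config$n_chromosomes, n_blocks, replace = TRUE)
    block_center <- floor(stats::runif(n_blocks) *
                            (lens[block_chrom_i] - 2 * config$ld_jitter_bp)) +
      config$ld_jitter_bp
    block_of <- rep(seq_len(n_blocks), each = config$ld_block_size)[
      seq_len(config$n_snps)]
    pos <- block_center[block_of] +
      round(stats::runif(config$n_snps, -config$ld_jitter_bp,
                         config$ld_jitter_bp))
    pos <- pmax(0, pmin(pos, lens[block_chrom_i][block_of] - 1))
    ap <- .allele_pairs[sample.int(nrow(.allele_pairs), config$n_snps,
                                   replace = TRUE), , drop = FALSE]
    snps <- data.frame(
      snp_id = sprintf("rs%05d", seq_len(config$n_snps)),
      chrom = chroms[block_chrom_i][block_of],
      pos = pos,
      ref = ap[, 1], alt = ap[, 2],
      maf = stats::runif(config$n_snps, config$maf_range[1],
                         config$maf_range[2]),
      ld_block = block_of,
      stringsAsFactors = FALSE
    )
    # de-duplicate positions within a chromosome (SNPs are point variants)
    dup <- duplicated(snps[c("chrom", "pos")])
    while (any(dup)) {
      snps$pos[dup] <- pmax(0, snps$pos[dup] + sample(c(-1L, 1L), sum(dup),
                                                      replace = TRUE))
      dup <- duplicated(snps[c("chrom", "pos")])
    }

    ld <- do.call(rbind, lapply(split(snps$snp_id, snps$ld_block), function(ids) {
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(sort(ids), 2)
      data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                 r2 = stats::runif(ncol(cmb), config$ld_r2_range[1],
                                   config$ld_r2_range[2]),
                 stringsAsFactors = FALSE)
    }))
    rownames(ld) <- NULL

    # random contacts (unordered, deduplicated)
    fa <- sample(fragments$fragment_id, config$n_contacts, replace = TRUE)
    fb <- sample(fragments$fragment_id, config$n_contacts, replace = TRUE)
    keep <- fa != fb
    contacts <- unique(data.frame(
      fragment_a = pmin(fa[keep], fb[keep]),
      fragment_b = pmax(fa[keep], fb[keep]),
      stringsAsFactors = FALSE
    ))
    rownames(contacts) <- NULL

    # ---- planted truth -------------------------------------------------
    common <- snps$snp_id[snps$maf >= 0.05]
    if (length(common) < config$n_true_eqtls) {
      stop_config("not enough common SNPs to plant ", config$n_true_eqtls,
                  " true pairs; increase n_snps or maf_range")
    }
    # causal-gene instruments come from distinct LD blocks so they remain
    # independent after clumping
    blocks_of_common <- snps$ld_block[match(common, snps$snp_id)]
    ord <- sample(seq_along(common))
    first_in_block <- ord[!duplicated(blocks_of_common[ord])]
    if (length(first_in_block) < config$causal_gene_instruments) {
      stop_config("not enough LD blocks for independent causal instruments")
    }
    causal_snps <- common[first_in_block[seq_len(config$causal_gene_instruments)]]
    remaining <- setdiff(common, causal_snps)
    other_snps <- sample(remaining,
                         config$n_true_eqtls - config$causal_gene_instruments)
    causal_gene <- sample(genes$gene_id, 1)
    other_genes <- sample(setdiff(genes$gene_id, causal_gene),
                          length(other_snps), replace = TRUE)
    true_pairs <- data.frame(
      snp_id = c(causal_snps, other_snps),
      gene_id = c(rep(causal_gene, length(causal_snps)), other_genes),
      mu = sample(c(-1, 1), config$n_true_eqtls, replace = TRUE) *
        stats::runif(config$n_true_eqtls, 0.15, 0.4),
      stringsAsFactors = FALSE
    )

    # guarantee a supporting contact for every planted pair
    snp_frag <- assign_fragments(snps, fragments)
    gene_first_frag <- vapply(seq_len(nrow(genes)), function(i) {
      hit <- fragments$chrom == genes$chrom[i] &
        fragments$start <= genes$start[i] & fragments$end > genes$start[i]
      fragments$fragment_id[hit][1]
    }, character(1))
    names(gene_first_frag) <- genes$gene_id
    sf <- unname(snp_frag[true_pairs$snp_id])
    gf <- unname(gene_first_frag[true_pairs$gene_id])
    extra <- data.frame(fragment_a = pmin(sf, gf), fragment_b = pmax(sf, gf),
                        stringsAsFactors = FALSE)
    extra <- extra[extra$fragment_a != extra$fragment_b, , drop = FALSE]
    contacts <- unique(rbind(contacts, extra))
    rownames(contacts) <- NULL

    # ---- protein-interaction network -----------------------------------
    mapped <- stats::runif(config$n_genes) >= config$unmapped_gene_frac
    mapped[genes$gene_id == causal_gene] <- TRUE
    gene_protein_map <- data.frame(
      gene_id = genes$gene_id[mapped],
      protein_id = paste0("P_", genes$gene_id[mapped]),
      stringsAsFactors = FALSE
    )
    proteins <- c(gene_protein_map$protein_id,
                  sprintf("prot%03d", seq_len(config$n_extra_proteins)))
    pa <- sample(proteins, config$n_ppin_edges, replace = TRUE)
    pb <- sample(proteins, config$n_ppin_edges, replace = TRUE)
    keep <- pa != pb
    ppin <- data.frame(
      protein_a = pmin(pa[keep], pb[keep]),
      protein_b = pmax(pa[keep], pb[keep]),
      score = round(stats::runif(sum(keep), config$ppin_score_range[1],
                                 config$ppin_score_range[2]), 3),
      stringsAsFactors = FALSE
    )
    ppin <- ppin[!duplicated(ppin[c("protein_a", "protein_b")]), , drop = FALSE]
    rownames(ppin) <- NULL

    truth <- list(
      true_spatial_eqtls = true_pairs,
      query_snps = true_pairs$snp_id,
      causal_genes = stats::setNames(config$causal_theta, causal_gene),
      pleiotropic_loci = list(),
      pleiotropy_intercept = 0,
      comorbid_or = numeric(0)
    )

    world <- list(genome = genome, fragments = fragments, genes = genes,
                  snps = snps, ld = ld, contacts = contacts, ppin = ppin,
                  gene_protein_map = gene_protein_map, truth = truth,
                  config = config, seed = as.integer(seed))
    class(world) <- "synthetic_world"
    world
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:",
      nrow(x$genome), "chromosomes,",
      nrow(x$fragments), "fragments,",
      nrow(x$genes), "genes,",
      nrow(x$snps), "SNPs,",
      nrow(x$contacts), "contacts,",
      nrow(x$ppin), "PPIN edges\n")
  cat("planted:", nrow(x$truth$true_spatial_eqtls), "true spatial eQTLs;",
      "causal gene", names(x$truth$causal_genes), "(theta =",
      unname(x$truth$causal_genes), ")\n")
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Fragments as 4-column BED, genes as GFF3, and SNPs, LD pairs, contacts
#' and protein interactions as headered TSV; the planted truth as JSON.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if absent)
#' @return invisibly, the named vector of file paths written
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fragments = file.path(dir, "fragments.bed"),
    genes = file.path(dir, "genes.gff3"),
    snps = file.path(dir, "snps.tsv"),
    ld = file.path(dir, "ld_pairs.tsv"),
    contacts = file.path(dir, "contacts.tsv"),
    ppin = file.path(dir, "ppin_edges.tsv"),
    gene_protein_map = file.path(dir, "gene_protein_map.tsv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.table(world$fragments[c("chrom", "start", "end", "fragment_id")],
                     paths["fragments"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- world$genes
  gff <- data.frame(
    seqid = g$chrom, source = "pleionet", type = "gene",
    start = g$start + 1L, end = g$end, score = ".", strand = g$strand,
    phase = ".",
    attributes = sprintf("ID=%s;tpm=%s", g$gene_id, g$tpm),
    stringsAsFactors = FALSE
  )
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), paths["genes"])
  write_tsv(world$snps, paths["snps"])
  write_tsv(world$ld, paths["ld"])
  write_tsv(world$contacts, paths["contacts"])
  write_tsv(world$ppin, paths["ppin"])
  write_tsv(world$gene_protein_map, paths["gene_protein_map"])
  truth <- world$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a GFF3 gene file written by [write_world()]
#' @param path GFF3 file path
#' @return a gene data.frame (0-based half-open coordinates)
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) != 9L
  if (any(bad)) stop_input("malformed GFF3 line(s) in ", path)
  m <- do.call(rbind, f)
  attrs <- m[, 9]
  get_attr <- function(key) {
    sub(sprintf(".*%s=([^;]+).*", key), "\\1", attrs)
  }
  data.frame(
    gene_id = get_attr("ID"),
    chrom = m[, 1],
    start = as.integer(m[, 4]) - 1L,
    end = as.integer(m[, 5]),
    strand = m[, 7],
    tpm = as.numeric(get_attr("tpm")),
    stringsAsFactors = FALSE
  )
}
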