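# Small hand-built fixtures shared across test files.

# Two fragments on one chromosome, one gene, one SNP; contact F1-F7 style.
tiny_fragments <- function() {
  data.frame(
    chrom = "chr1",
    start = seq(0, 36000, by = 4000),
    end = seq(4000, 40000, by = 4000),
    fragment_id = sprintf("F%d", 1:10),
    stringsAsFactors = FALSE
  )
}

tiny_genes <- function() {
  # gene overlapping F7 ([24000, 28000)) and part of F8
  data.frame(gene_id = "gA", chrom = "chr1", start = 25000, end = 30000,
             strand = "+", tpm = 7.5, stringsAsFactors = FALSE)
}

tiny_snps <- function() {
  data.frame(snp_id = "s1", chrom = "chr1", pos = 1000, ref = "A",
             alt = "G", maf = 0.3, stringsAsFactors = FALSE)
}

# An LD fixture with explicit positions and sparse pairwise r2.
tiny_ld <- function(pairs, positions) {
  ld_resource(pairs, positions)
}

default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_world(sim_config(), seed = 11)
    cache
  }
})
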