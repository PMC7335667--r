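# Small fixtures shared across tests, built in code.

# A tiny deterministic random genome as a named character vector.
random_genome <- function(lengths, seed = 1) {
  set.seed(seed)
  setNames(vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), names(lengths))
}

# Minimal two-gene annotation (one protein-coding + strand, one lncRNA
# - strand) on a single contig.
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("G0001", "G0002"),
    gene_name = c("G0001", "G0002"),
    biotype = c("protein_coding", "lncRNA"),
    contig = "chr1",
    strand = c("+", "-"),
    tss = c(1000L, 20399L))
  exons <- data.frame(
    gene_id = c("G0001", "G0001", "G0002", "G0002"),
    contig = "chr1",
    start = c(1000L, 2000L, 19100L, 20000L),
    end = c(1500L, 2600L, 19500L, 20400L))
  list(genes = genes, exons = exons)
}

# A directly constructed tag table.
tag_df <- function(contig, pos, strand) {
  data.frame(contig = contig, pos = as.integer(pos), strand = strand)
}
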