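# Synthetic-data generators. Everything downstream of alignment is testable
# against planted truth: a random genome, a Gencode-style annotation, true
# binding sites with per-condition (A / M / G1) occupancy, single-position
# phantom read stacks, stranded 5'-start tags, and a DE table with known
# effects. All generators are deterministic under a fixed seed.

#' Simulation parameters
#'
#' Defaults describe the study conditions used throughout the package's
#' tests and analyses: a 2 x 300 kb genome carrying 50 genes (25% lncRNA),
#' 40 true binding sites of which half are bookmarked (occupied in both M
#' and G1), 10 phantom single-position read stacks, a mean of 300 reads per
#' occupied site and replicate, 180 bp fragments sequenced as single-end
#' 85 bp reads, and a background of 5e-4 tags per base per strand.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_genes Total number of genes.
#' @param lncRNA_fraction Fraction of genes with biotype `lncRNA`; the
#'   count is `round(lncRNA_fraction * n_genes)` (ties to even).
#' @param n_true_sites Number of planted true binding sites (each at a
#'   distinct gene's TSS, within 5 kb).
#' @param bookmark_fraction Fraction of true sites occupied in both M and
#'   G1 (the bookmarked subset).
#' @param n_artifacts Number of phantom single-position, single-strand read
#'   stacks, placed at least 10 kb from any TSS.
#' @param reads_per_site Mean (Poisson) read count per occupied site per
#'   replicate.
#' @param fragment_size Mean ChIP fragment size in bases.
#' @param read_length Sequenced read length in bases.
#' @param background_rate Background tags per base per strand.
#' @param jitter_sd Standard deviation (bases) of fragment centers around
#'   the site center.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_contigs = 2, contig_length = 300000, n_genes = 50,
                       lncRNA_fraction = 0.25, n_true_sites = 40,
                       bookmark_fraction = 0.5, n_artifacts = 10,
                       reads_per_site = 300, fragment_size = 180,
                       read_length = 85, background_rate = 5e-4,
                       jitter_sd = 20, seed = 1) {
  p <- list(n_contigs = n_contigs, contig_length = contig_length,
            n_genes = n_genes, lncRNA_fraction = lncRNA_fraction,
            n_true_sites = n_true_sites,
            bookmark_fraction = bookmark_fraction,
            n_artifacts = n_artifacts, reads_per_site = reads_per_site,
            fragment_size = fragment_size, read_length = read_length,
            background_rate = background_rate, jitter_sd = jitter_sd,
            seed = as.integer(seed))
  stopifnot(p$fragment_size > p$read_length, p$read_length > 0,
            p$n_contigs >= 1, p$contig_length >= 1,
            p$lncRNA_fraction >= 0, p$lncRNA_fraction <= 1,
            p$bookmark_fraction >= 0, p$bookmark_fraction <= 1,
            p$n_true_sites <= p$n_genes,
            p$n_genes >= 0, p$n_artifacts >= 0, p$background_rate >= 0)
  class(p) <- "sim_params"
  p
}

# Derive an independent, reproducible stream seed (< 2^31) from the global
# seed and a stage label.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Generate a random genome
#'
#' Contigs `chr1..chrN` of i.i.d. uniform A/C/G/T bases.
#'
#' @param params A [sim_params()] object.
#' @return Named character vector of sequences.
#' @export
make_genome <- function(params) {
  stopifnot(params$contig_length >= 1, params$n_contigs >= 1)
  set.seed(derive_seed(params$seed, "genome"))
  seqs <- vapply(seq_len(params$n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), params$contig_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  setNames(seqs, paste0("chr", seq_len(params$n_contigs)))
}

#' Generate gene models on a genome
#'
#' TSSs are laid out on a jittered grid inside the first 60% of each
#' contig, leaving the tail of every contig gene-free (where phantom
#' artifacts can sit at least 10 kb from any TSS). Each gene has 1-3
#' basic-tag exons and a random strand; on `-` the TSS is the last
#' (highest-coordinate) base of the gene. Exactly
#' `round(lncRNA_fraction * n_genes)` genes are lncRNA.
#'
#' @param genome Named character vector of sequences.
#' @param params A [sim_params()] object.
#' @return A gene-model list (`genes`, `exons`) as from [read_gtf()].
#' @export
make_genes <- function(genome, params) {
  set.seed(derive_seed(params$seed, "genes"))
  lens <- contig_lengths(genome)
  n_contig <- length(lens)
  per_contig <- diff(round(seq(0, params$n_genes, length.out = n_contig + 1)))
  zone_lo <- 5000
  gene_rows <- list(); exon_rows <- list(); gi <- 0
  for (ci in seq_len(n_contig)) {
    n_here <- per_contig[ci]
    if (n_here == 0) next
    zone_hi <- floor(0.6 * lens[ci])
    spacing <- (zone_hi - zone_lo) / n_here
    if (spacing < 4500) {
      stop("genome too small for requested gene count (TSS spacing ",
           round(spacing), " bp)")
    }
    grid <- round(zone_lo + spacing * (seq_len(n_here) - 0.5))
    tss <- grid + sample(-400:400, n_here, replace = TRUE)
    strand <- sample(c("+", "-"), n_here, replace = TRUE)
    for (j in seq_len(n_here)) {
      gi <- gi + 1
      gene_id <- sprintf("G%04d", gi)
      n_ex <- sample(1:3, 1)
      ex_len <- sample(150:500, n_ex, replace = TRUE)
      intron <- if (n_ex > 1) sample(200:1000, n_ex - 1, replace = TRUE)
                else integer(0)
      if (strand[j] == "+") {
        starts <- tss[j] + cumsum(c(0, ex_len[-n_ex] + intron))
        ends <- starts + ex_len
      } else {
        ends <- tss[j] + 1 - cumsum(c(0, ex_len[-n_ex] + intron))
        starts <- ends - ex_len
        o <- order(starts); starts <- starts[o]; ends <- ends[o]
      }
      gene_rows[[gi]] <- data.frame(
        gene_id = gene_id, gene_name = gene_id, biotype = "protein_coding",
        contig = names(lens)[ci], strand = strand[j],
        tss = as.integer(tss[j]))
      exon_rows[[gi]] <- data.frame(
        gene_id = gene_id, contig = names(lens)[ci],
        start = as.integer(starts), end = as.integer(ends))
    }
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, exon_rows)
  n_lnc <- round(params$lncRNA_fraction * params$n_genes)
  if (n_lnc > 0) {
    lnc <- sample(genes$gene_id, n_lnc)
    genes$biotype[genes$gene_id %in% lnc] <- "lncRNA"
  }
  rownames(genes) <- NULL; rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Plant true binding sites and phantom artifacts
#'
#' Each true site is placed within 800 bp of a distinct gene's TSS (well
#' inside the 5 kb annotation cutoff). `round(bookmark_fraction *
#' n_true_sites)` sites are bookmarked (occupancy `A,M,G1`); the remaining
#' true sites are split cyclically over A-only, M-only and G1-only.
#' Phantom artifacts are single-position single-strand read stacks present
#' in all conditions, placed at least 10 kb from every TSS, and bound to no
#' gene.
#'
#' @param genes A gene-model list from [make_genes()].
#' @param params A [sim_params()] object.
#' @return data.frame with `site_id`, `contig`, `center`, `kind`
#'   (`true_site`/`phantom_artifact`), `occupancy` (comma-separated subset
#'   of `A,M,G1`), `bound_gene_id` (NA for phantoms), `strand` (phantom
#'   stack strand, NA for true sites).
#' @export
plant_sites <- function(genes, params) {
  stopifnot(params$n_true_sites <= nrow(genes$genes))
  set.seed(derive_seed(params$seed, "sites"))
  g <- genes$genes
  pick <- g[sample(nrow(g), params$n_true_sites), , drop = FALSE]
  offset <- sample(-800:800, params$n_true_sites, replace = TRUE)
  n_bm <- round(params$bookmark_fraction * params$n_true_sites)
  occ <- rep(c("A-only", "M-only", "G1-only"),
             length.out = max(params$n_true_sites - n_bm, 0))
  occ_str <- c(rep("A,M,G1", n_bm),
               c("A-only" = "A", "M-only" = "M", "G1-only" = "G1")[occ])
  occ_str <- occ_str[sample(length(occ_str))]
  sites <- data.frame(
    site_id = sprintf("site%03d", seq_len(params$n_true_sites)),
    contig = pick$contig,
    center = as.integer(pick$tss + offset),
    kind = "true_site",
    occupancy = unname(occ_str),
    bound_gene_id = pick$gene_id,
    strand = NA_character_)
  if (params$n_artifacts > 0) {
    tss_by_contig <- split(g$tss, g$contig)
    contigs <- unique(g$contig)
    art <- data.frame(site_id = character(), contig = character(),
                      center = integer())
    tries <- 0
    while (nrow(art) < params$n_artifacts) {
      tries <- tries + 1
      if (tries > 200 * params$n_artifacts) {
        stop("could not place phantom artifacts >= 10 kb from all TSSs")
      }
      cm <- sample(contigs, 1)
      pos <- sample.int(params$contig_length - 1000, 1)
      tss <- tss_by_contig[[cm]]
      if (length(tss) == 0 || min(abs(tss - pos)) >= 10000) {
        art <- rbind(art, data.frame(
          site_id = sprintf("phantom%03d", nrow(art) + 1),
          contig = cm, center = pos))
      }
    }
    art$kind <- "phantom_artifact"
    art$occupancy <- "A,M,G1"
    art$bound_gene_id <- NA_character_
    art$strand <- sample(c("+", "-"), nrow(art), replace = TRUE)
    sites <- rbind(sites, art)
  }
  rownames(sites) <- NULL
  sites
}

occupied_in <- function(occupancy, condition) {
  vapply(strsplit(occupancy, ","),
         function(x) condition %in% x, logical(1))
}

#' Simulate stranded ChIP tags for one condition and replicate
#'
#' For each true site occupied in `condition`, `Poisson(reads_per_site)`
#' fragments are drawn with centers `Normal(site center, jitter_sd)`; each
#' fragment yields one single-end read on a random strand, with the 5'
#' start at `center - fragment_size/2` (`+`) or `center + fragment_size/2`
#' (`-`, the fragment's right end). Phantom artifacts emit
#' `Poisson(reads_per_site)` tags at one position on one strand.
#' Background tags are `Poisson(background_rate * length)` per strand,
#' uniformly placed.
#'
#' @param truth Site table from [plant_sites()].
#' @param params A [sim_params()] object.
#' @param condition One of `"A"`, `"M"`, `"G1"`.
#' @param replicate Replicate index (>= 1); each replicate gets an
#'   independent stream.
#' @return Tag data.frame (`contig`, `pos`, `strand`), sorted.
#' @export
simulate_tags <- function(truth, params, condition, replicate = 1) {
  stopifnot(condition %in% c("A", "M", "G1"), replicate >= 1)
  set.seed(derive_seed(params$seed,
                       paste0("tags:", condition, ":", replicate)))
  lens <- setNames(rep(params$contig_length, params$n_contigs),
                   paste0("chr", seq_len(params$n_contigs)))
  half <- round(params$fragment_size / 2)
  rows <- list()
  active <- truth[occupied_in(truth$occupancy, condition), , drop = FALSE]
  for (i in seq_len(nrow(active))) {
    s <- active[i, ]
    n <- rpois(1, params$reads_per_site)
    if (n == 0) next
    if (s$kind == "phantom_artifact") {
      rows[[length(rows) + 1]] <- data.frame(
        contig = s$contig, pos = rep(s$center, n), strand = s$strand)
    } else {
      centers <- round(rnorm(n, s$center, params$jitter_sd))
      plus <- runif(n) < 0.5
      pos <- ifelse(plus, centers - half, centers + half)
      rows[[length(rows) + 1]] <- data.frame(
        contig = s$contig,
        pos = pmin(pmax(pos, 0), lens[[s$contig]] - 1L),
        strand = ifelse(plus, "+", "-"))
    }
  }
  for (nm in names(lens)) {
    for (st in c("+", "-")) {
      n_bg <- rpois(1, params$background_rate * lens[[nm]])
      if (n_bg > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          contig = nm, pos = sample.int(lens[[nm]], n_bg) - 1L, strand = st)
      }
    }
  }
  if (length(rows) == 0) {
    tags <- data.frame(contig = character(), pos = integer(),
                       strand = character())
  } else {
    tags <- do.call(rbind, rows)
  }
  tags$pos <- as.integer(tags$pos)
  tags <- tags[order(tags$contig, tags$pos), , drop = FALSE]
  rownames(tags) <- NULL
  tags
}

#' Simulate a differential-expression results table
#'
#' 35% of site-bound genes and 5% of unbound genes are flagged truly DE.
#' Truly-DE rows draw `base_mean ~ LogNormal(3, 1)`,
#' `|log2fc| ~ 1 + Exp(1)` with random sign, `pvalue ~ Uniform(0, 0.01)`;
#' null rows draw `base_mean` from the same LogNormal,
#' `log2fc ~ Normal(0, 0.2)` and `pvalue ~ Uniform(0, 1)`.
#'
#' @param genes A gene-model list from [make_genes()].
#' @param truth Site table from [plant_sites()] (defines bound genes), or
#'   NULL for an all-null table.
#' @param params A [sim_params()] object.
#' @return data.frame with `gene_id`, `base_mean`, `log2fc`, `pvalue`,
#'   `truly_de`.
#' @export
simulate_de <- function(genes, truth, params) {
  set.seed(derive_seed(params$seed, "de"))
  ids <- genes$genes$gene_id
  bound <- if (is.null(truth)) character(0) else
    truth$bound_gene_id[!is.na(truth$bound_gene_id)]
  is_bound <- ids %in% bound
  de <- logical(length(ids))
  de[is_bound] <- runif(sum(is_bound)) < 0.35
  de[!is_bound] <- runif(sum(!is_bound)) < 0.05
  n <- length(ids)
  base_mean <- rlnorm(n, meanlog = 3, sdlog = 1)
  log2fc <- rnorm(n, 0, 0.2)
  pvalue <- runif(n)
  nd <- sum(de)
  if (nd > 0) {
    log2fc[de] <- sample(c(-1, 1), nd, replace = TRUE) * (1 + rexp(nd, 1))
    pvalue[de] <- runif(nd, 0, 0.01)
  }
  data.frame(gene_id = ids, base_mean = base_mean, log2fc = log2fc,
             pvalue = pvalue, truly_de = de)
}

#' Write a full synthetic dataset to a directory
#'
#' Convenience wrapper producing the on-disk layout the pipeline consumes:
#' genome FASTA, contig sizes, GTF, truth TSV, per-condition/replicate tag
#' TSVs and a DE table.
#'
#' @param params A [sim_params()] object.
#' @param outdir Output directory (created if absent).
#' @param n_replicates Tag replicates per condition.
#' @return Invisibly, a list of generated objects and file paths.
#' @export
simulate_dataset <- function(params, outdir, n_replicates = 2) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(params)
  genes <- make_genes(genome, params)
  truth <- plant_sites(genes, params)
  de <- simulate_de(genes, truth, params)
  write_fasta(genome, file.path(outdir, "genome.fa"))
  write_genome_sizes(contig_lengths(genome),
                     file.path(outdir, "genome.sizes"))
  write_gtf(genes, file.path(outdir, "genes.gtf"))
  write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(de, file.path(outdir, "de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tag_paths <- list()
  for (cond in c("A", "M", "G1")) {
    tag_paths[[cond]] <- vapply(seq_len(n_replicates), function(r) {
      p <- file.path(outdir, sprintf("tags_%s_rep%d.tsv", cond, r))
      write_tags(simulate_tags(truth, params, cond, r), p)
      p
    }, character(1))
  }
  invisible(list(genome = genome, genes = genes, truth = truth, de = de,
                 tag_paths = tag_paths, outdir = outdir))
}
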