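small_params <- function(seed = 1, ...) {
  sim_params(n_contigs = 2, contig_length = 100000, n_genes = 16,
             lncRNA_fraction = 0.25, n_true_sites = 12,
             bookmark_fraction = 0.5, n_artifacts = 4, seed = seed, ...)
}

test_that("genome generation is deterministic and base-balanced", {
  p <- small_params(seed = 1)
  g <- make_genome(p)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(unname(nchar(g)), c(100000L, 100000L))
  expect_identical(make_genome(p), g)
  expect_false(identical(make_genome(small_params(seed = 2)), g))
  gc <- sum(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("gene models respect biotype quota, spacing and TSS convention", {
  p <- small_params(seed = 7)
  g <- make_genome(p)
  genes <- make_genes(g, p)
  expect_identical(nrow(genes$genes), 16L)
  expect_identical(sum(genes$genes$biotype == "lncRNA"), 4L)
  # TSS = 5'-most exon boundary respecting strand
  for (i in seq_len(nrow(genes$genes))) {
    gi <- genes$genes[i, ]
    ex <- genes$exons[genes$exons$gene_id == gi$gene_id, ]
    if (gi$strand == "+") {
      expect_identical(gi$tss, min(ex$start))
    } else {
      expect_identical(gi$tss, max(ex$end) - 1L)
    }
  }
  # GTF round-trip preserves the TSS set
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, gtf)
  back <- read_gtf(gtf)
  expect_identical(sort(back$genes$tss), sort(genes$genes$tss))
  expect_identical(back$genes$biotype[order(back$genes$gene_id)],
                   genes$genes$biotype[order(genes$genes$gene_id)])
  # genome too small for the gene count
  expect_error(make_genes(random_genome(c(chr1 = 20000), 1),
                          sim_params(n_contigs = 1, contig_length = 20000,
                                     n_genes = 40, n_true_sites = 1)),
               "too small")
})

test_that("planted sites satisfy the occupancy and placement contracts", {
  p <- small_params(seed = 3)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  ts <- truth[truth$kind == "true_site", ]
  art <- truth[truth$kind == "phantom_artifact", ]
  expect_identical(nrow(ts), 12L)
  expect_identical(nrow(art), 4L)
  # bookmarked quota
  expect_identical(sum(ts$occupancy == "A,M,G1"), 6L)
  expect_true(all(nzchar(ts$occupancy)))
  # each true site within 5 kb of its own distinct gene's TSS
  expect_false(anyDuplicated(ts$bound_gene_id) > 0)
  tss_of <- setNames(genes$genes$tss, genes$genes$gene_id)
  expect_true(all(abs(ts$center - tss_of[ts$bound_gene_id]) <= 5000))
  # artifacts unbound and >= 10 kb from every TSS
  expect_true(all(is.na(art$bound_gene_id)))
  for (i in seq_len(nrow(art))) {
    tss <- genes$genes$tss[genes$genes$contig == art$contig[i]]
    expect_gte(min(abs(tss - art$center[i])), 10000)
  }
})

test_that("simulated tags have the bidirectional geometry of real ChIP", {
  p <- small_params(seed = 5, background_rate = 0, reads_per_site = 200)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  one <- truth[truth$kind == "true_site" & truth$occupancy == "A,M,G1", ][1, ]
  truth1 <- truth[truth$site_id == one$site_id, ]
  devs_p <- c(); devs_m <- c()
  for (r in 1:5) {
    tags <- simulate_tags(truth1, p, "M", r)
    devs_p <- c(devs_p, mean(tags$pos[tags$strand == "+"]) - one$center)
    devs_m <- c(devs_m, mean(tags$pos[tags$strand == "-"]) - one$center)
  }
  expect_lt(abs(mean(devs_p) + 90), 3)
  expect_lt(abs(mean(devs_m) - 90), 3)
})

test_that("phantom stacks are single-position and occupancy is honored", {
  p <- small_params(seed = 6, background_rate = 0)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  art <- truth[truth$kind == "phantom_artifact", ][1, ]
  tags <- simulate_tags(truth[truth$site_id == art$site_id, ], p, "A")
  expect_identical(length(unique(tags$pos)), 1L)
  expect_identical(unique(tags$strand), art$strand)
  expect_identical(unique(tags$pos), art$center)
  # a site occupied only in M emits nothing in G1
  m_only <- truth[truth$occupancy == "M", ][1, ]
  g1_tags <- simulate_tags(truth[truth$site_id == m_only$site_id, ], p, "G1")
  expect_identical(nrow(g1_tags), 0L)
  # determinism per (condition, replicate)
  expect_identical(simulate_tags(truth, p, "M", 2),
                   simulate_tags(truth, p, "M", 2))
  expect_false(identical(simulate_tags(truth, p, "M", 1),
                         simulate_tags(truth, p, "M", 2)))
})

test_that("tag counts match planted expectation within Poisson bounds", {
  p <- small_params(seed = 8, background_rate = 1e-4)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  tags <- simulate_tags(truth, p, "G1", 1)
  n_active <- sum(vapply(strsplit(truth$occupancy, ","),
                         function(x) "G1" %in% x, logical(1)))
  expected <- n_active * p$reads_per_site +
    2 * p$background_rate * p$n_contigs * p$contig_length
  expect_lt(abs(nrow(tags) - expected), 3 * sqrt(expected))
})

test_that("DE simulation is deterministic with calibrated null behavior", {
  p <- small_params(seed = 9)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  de <- simulate_de(genes, truth, p)
  expect_identical(de, simulate_de(genes, truth, p))
  expect_identical(nrow(de), nrow(genes$genes))
  # a strong truly-DE row survives the significance filter
  expect_identical(
    filter_de(data.frame(gene_id = "g", base_mean = 20.1, log2fc = 2.3,
                         pvalue = 0.004)), "g")
  # Monte-Carlo: all-null pass rate = P(baseMean>5) P(|lfc|>1) P(p<0.05)
  n <- 1e5
  set.seed(17)
  null_tab <- data.frame(gene_id = sprintf("g%d", 1:n),
                         base_mean = rlnorm(n, 3, 1),
                         log2fc = rnorm(n, 0, 0.2),
                         pvalue = runif(n))
  rate <- (1 - plnorm(5, 3, 1)) * 2 * pnorm(-1, 0, 0.2) * 0.05
  got <- length(filter_de(null_tab))
  expect_lt(abs(got - n * rate), 3 * sqrt(n * rate * (1 - rate)) + 1)
})
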