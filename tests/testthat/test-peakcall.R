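test_that("pileup extends tags by fragment size, clipped at edges", {
  lens <- c(chr1 = 1000L)
  cov <- pileup(tag_df("chr1", 100, "+"), 180, lens)$chr1
  expect_identical(which(cov == 1L), 101:280)      # 0-based [100, 280)
  cov <- pileup(tag_df("chr1", 279, "-"), 180, lens)$chr1
  expect_identical(which(cov == 1L), 101:280)      # mirror of the + case
  # clipping at the left edge
  cov <- pileup(tag_df("chr1", 10, "-"), 180, lens)$chr1
  expect_identical(which(cov == 1L), 1:11)
  # mass conservation without clipping
  set.seed(1)
  tags <- tag_df("chr1", sample(200:700, 50, replace = TRUE),
                 sample(c("+", "-"), 50, replace = TRUE))
  expect_identical(sum(pileup(tags, 180, lens)$chr1), 50L * 180L)
  expect_error(pileup(tag_df("chrX", 1, "+"), 180, lens), "unknown contig")
})

test_that("poisson_sf is the exact upper-tail Poisson probability", {
  expect_identical(poisson_sf(0, 0), 1)
  expect_identical(poisson_sf(0, 7.3), 1)
  # closed form: P(X >= 5 | lam = 1) = 1 - sum_{k<5} e^-1 / k!
  closed <- 1 - exp(-1) * sum(1 / factorial(0:4))
  expect_equal(poisson_sf(5, 1), closed, tolerance = 1e-10)
  expect_lt(abs(poisson_sf(5, 1) - 3.6598e-3), 1e-7)
  # monotone non-increasing in count
  expect_true(all(diff(poisson_sf(0:30, 4)) <= 0))
  expect_error(poisson_sf(-1, 1), ">= 0")
})

test_that("lambda track is constant without a control and local with one", {
  lens <- c(chr1 = 50000L)
  params <- peak_call_params()
  set.seed(3)
  unif <- tag_df("chr1", sample(0:49999, 2000, replace = TRUE),
                 sample(c("+", "-"), 2000, replace = TRUE))
  lam <- lambda_track(unif, params, lens, local = FALSE)$chr1
  expect_identical(length(unique(lam)), 1L)
  # uniform control: local lambda stays near the genome-wide rate
  lam_loc <- lambda_track(unif, params, lens, local = TRUE)$chr1
  mid <- lam_loc[5000:45000]
  expect_lt(mean(abs(mid - lam[1])) / lam[1], 0.10)
  expect_lt(max(abs(mid - lam[1])) / lam[1], 0.50)
  # a dense control cluster elevates lambda only within its largest window
  clust <- rbind(unif, tag_df("chr1", rep(25000, 400), "+"))
  lam_c <- lambda_track(clust, params, lens, local = TRUE)$chr1
  expect_gt(lam_c[25001], 5 * lam[1])
  expect_lt(max(lam_c[1:15000]) / max(lam_c), 0.2)
  expect_error(lambda_track(unif[0, ], params, lens), "empty")
})

test_that("call_peaks recovers a planted site and is quiet on background", {
  p <- sim_params(n_contigs = 1, contig_length = 100000, n_genes = 4,
                  n_true_sites = 1, n_artifacts = 0, reads_per_site = 200,
                  background_rate = 5e-4, seed = 31)
  genes <- make_genes(make_genome(p), p)
  truth <- plant_sites(genes, p)
  truth$occupancy <- "M"
  tags <- simulate_tags(truth, p, "M")
  lens <- c(chr1 = 100000L)
  res <- call_peaks(tags, lens)
  expect_identical(nrow(res$peaks), 1L)
  expect_true(res$peaks$start <= truth$center[1] &
                truth$center[1] < res$peaks$end)
  expect_lte(res$peaks$min_pvalue, 1e-5)
  expect_true(res$peaks$start <= res$peaks$summit &
                res$peaks$summit < res$peaks$end)
  # pure background on 1 Mb: no peaks survive the min-length filter in
  # most seeds
  lens1m <- c(chr1 = 1000000L)
  n_peaks <- vapply(1:8, function(s) {
    set.seed(s)
    bg <- tag_df("chr1", sample(0:999999, 1000, replace = TRUE),
                 sample(c("+", "-"), 1000, replace = TRUE))
    nrow(call_peaks(bg, lens1m)$peaks)
  }, numeric(1))
  expect_gte(mean(n_peaks == 0), 0.95)
  expect_error(call_peaks(tags[0, ], lens), "empty")
})

test_that("candidate bases equal brute-force per-base Poisson evaluation", {
  lens <- c(toy = 2000L)
  set.seed(41)
  tags <- rbind(
    tag_df("toy", sample(0:1999, 120, replace = TRUE),
           sample(c("+", "-"), 120, replace = TRUE)),
    tag_df("toy", round(rnorm(60, 910, 15)), "+"),
    tag_df("toy", round(rnorm(60, 1090, 15)), "-"))
  tags$pos <- pmin(pmax(tags$pos, 0L), 1999L)
  params <- peak_call_params(min_peak_length = 1, merge_gap = 0)
  res <- call_peaks(tags, lens, params)
  # brute force: per-base tail probability from first principles
  cov <- pileup(tags, params$fragment_size, lens)$toy
  lam <- sum(cov) / 2000
  brute <- which(vapply(cov, function(k) {
    if (k == 0) 1 else 1 - sum(exp(-lam) * lam^(0:(k - 1)) /
                                 factorial(0:(k - 1)))
  }, numeric(1)) <= params$p_threshold) - 1L
  called <- unlist(lapply(seq_len(nrow(res$peaks)), function(i)
    seq(res$peaks$start[i], res$peaks$end[i] - 1L)))
  expect_identical(sort(called), sort(brute))
})

test_that("peak calling invariants hold", {
  p <- sim_params(seed = 19)
  truth <- plant_sites(make_genes(make_genome(p), p), p)
  tags <- simulate_tags(truth, p, "A")
  lens <- setNames(rep(300000L, 2), c("chr1", "chr2"))
  res <- call_peaks(tags, lens)
  pk <- res$peaks
  # disjoint, sorted, in bounds
  for (nm in unique(pk$contig)) {
    s <- pk[pk$contig == nm, ]
    expect_true(all(diff(s$start) > 0))
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    expect_true(all(s$start >= 0 & s$end <= lens[[nm]]))
  }
  # FE equals 1 where pileup equals lambda
  cov <- pileup(tags, 180, lens)$chr1
  lamv <- sum(sapply(pileup(tags, 180, lens), sum)) / sum(lens)
  eq <- which(abs(cov - lamv) < 1e-9)
  if (length(eq) > 0) {
    expect_true(all(abs(res$fe_track$chr1[eq] - 1) < 1e-12))
  }
  # raising the threshold never removes candidate bases
  loose <- call_peaks(tags, lens, peak_call_params(p_threshold = 1e-3,
                                                   min_peak_length = 1,
                                                   merge_gap = 0))
  strict <- call_peaks(tags, lens, peak_call_params(p_threshold = 1e-7,
                                                    min_peak_length = 1,
                                                    merge_gap = 0))
  bases <- function(res, nm) unlist(lapply(
    which(res$peaks$contig == nm), function(i)
      seq(res$peaks$start[i], res$peaks$end[i] - 1)))
  for (nm in c("chr1", "chr2")) {
    expect_true(all(bases(strict, nm) %in% bases(loose, nm)))
  }
})
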