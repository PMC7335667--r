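# Brute-force oracle: every exact occurrence of each read or its reverse
# complement, found by scanning all substrings of both strands.
brute_matches <- function(reads, genome) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  w <- nchar(reads[1])
  rows <- list()
  for (nm in names(genome)) {
    L <- nchar(genome[[nm]])
    if (L < w) next
    subs <- substring(genome[[nm]], 1:(L - w + 1), w:L)
    for (r in unique(reads)) {
      hits <- which(subs == r | subs == rc(r))
      for (h in hits) {
        rows[[length(rows) + 1]] <- data.frame(
          contig = nm, start = h - 1L, end = h - 1L + w)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer())
  unique(out[order(out$contig, out$start), ])
}

test_that("tile_reads yields the expected window count and content", {
  unit <- random_genome(c(u = 60), seed = 2)[["u"]]
  expect_length(tile_reads(unit, 50, 1), 11)
  expect_identical(tile_reads(substr(unit, 1, 50), 50, 1),
                   substr(unit, 1, 50))
  u1k <- random_genome(c(u = 1000), seed = 4)[["u"]]
  reads <- tile_reads(u1k, 50, 1)
  expect_length(reads, 951)
  expect_true(all(nchar(reads) == 50))
  expect_identical(reads[10], substr(u1k, 10, 59))
  expect_error(tile_reads("ACGT", 50), "shorter")
})

test_that("locate_matches agrees with a brute-force two-strand scan", {
  g <- random_genome(c(c1 = 200, c2 = 120), seed = 7)
  # forward read present verbatim
  r_fwd <- substr(g[["c1"]], 31, 50)
  got <- locate_matches(r_fwd, g)
  expect_true(any(got$contig == "c1" & got$start == 30 & got$end == 50))
  # a read whose reverse complement occurs at a known position
  target <- substr(g[["c2"]], 61, 80)
  r_rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(target, "")[[1]]), collapse = ""))
  got <- locate_matches(r_rc, g)
  expect_true(any(got$contig == "c2" & got$start == 60 & got$end == 80))
  # absent read
  expect_identical(nrow(locate_matches(strrep("A", 20), g)), 0L)
  # full agreement with the oracle for a batch of tiled reads
  reads <- tile_reads(substr(g[["c1"]], 11, 70), 20, 5)
  got <- unique(locate_matches(reads, g))
  got <- got[order(got$contig, got$start), ]
  expect_equal(got, brute_matches(reads, g), ignore_attr = "row.names")
})

test_that("merge_intervals sorts, merges overlaps and touching runs", {
  m <- function(s, e) data.frame(contig = "c", start = s, end = e)
  expect_equal(merge_intervals(m(c(0, 1), c(50, 51))), m(0, 51),
               ignore_attr = "row.names")
  expect_equal(merge_intervals(m(c(0, 10), c(10, 20))), m(0, 20),
               ignore_attr = "row.names")
  expect_equal(merge_intervals(m(c(20, 0), c(30, 10))),
               m(c(0, 20), c(10, 30)), ignore_attr = "row.names")
  # base-set preservation on random interval soups
  set.seed(5)
  for (i in 1:5) {
    s <- sample(0:80, 12, replace = TRUE)
    iv <- data.frame(contig = sample(c("a", "b"), 12, replace = TRUE),
                     start = s, end = s + sample(1:15, 12, replace = TRUE))
    mg <- merge_intervals(iv)
    cover <- function(x) sort(unique(unlist(
      lapply(seq_len(nrow(x)), function(i)
        paste(x$contig[i], seq(x$start[i], x$end[i] - 1))))))
    expect_identical(cover(mg), cover(iv))
    expect_true(all(mg$start[-1] > mg$end[-nrow(mg)] |
                      mg$contig[-1] != mg$contig[-nrow(mg)]))
  }
})

test_that("hard_mask replaces exactly the requested bases with N", {
  g <- c(c1 = "ACGTACGTAC")
  masked <- hard_mask(g, data.frame(contig = "c1", start = 2L, end = 5L))
  expect_identical(masked[["c1"]], "ACNNNCGTAC")
  expect_identical(hard_mask(g, data.frame(contig = character(),
                                           start = integer(),
                                           end = integer())), g)
  expect_error(hard_mask(g, data.frame(contig = "c1", start = 5L,
                                       end = 11L)), "bounds")
})

test_that("build_rdna_reference masks all unit copies and appends the unit", {
  set.seed(9)
  unit <- random_genome(c(u = 300), seed = 10)[["u"]]
  flank <- function(n, s) random_genome(c(x = n), seed = s)[["x"]]
  g <- c(chrA = paste0(flank(500, 11), unit, flank(400, 12), unit,
                       flank(300, 13)),
         chrB = flank(600, 14))
  res <- build_rdna_reference(g, unit, read_length = 50)
  # exactly the two embedded copies are masked
  expect_identical(sum(res$mask_intervals$end - res$mask_intervals$start),
                   2L * 300L)
  expect_length(res$masked_genome, 3)
  expect_identical(res$masked_genome[["chrU13369.1"]], unit)
  # contig lengths unchanged
  expect_identical(nchar(res$masked_genome[["chrA"]]), nchar(g[["chrA"]]))
  # completeness: no tiled read matches the masked original contigs...
  reads <- tile_reads(unit, 50)
  left <- locate_matches(reads, res$masked_genome[c("chrA", "chrB")])
  expect_identical(nrow(left), 0L)
  # ...and every tiled read maps into the appended contig
  inunit <- locate_matches(reads, res$masked_genome["chrU13369.1"])
  expect_identical(sort(unique(inunit$start)), 0:250)
  # bases outside the mask are untouched
  expect_identical(substr(res$masked_genome[["chrA"]], 1, 500),
                   substr(g[["chrA"]], 1, 500))
})

test_that("masking is idempotent and respects name collisions", {
  unit <- random_genome(c(u = 200), seed = 21)[["u"]]
  g <- c(chr1 = paste0(random_genome(c(x = 300), seed = 22)[["x"]], unit))
  res1 <- build_rdna_reference(g, unit, read_length = 40)
  again <- res1$masked_genome[setdiff(names(res1$masked_genome),
                                      "chrU13369.1")]
  res2 <- build_rdna_reference(again, unit, read_length = 40)
  expect_identical(nrow(res2$mask_intervals), 0L)
  expect_error(build_rdna_reference(res1$masked_genome, unit),
               "already present")
  # zero embedded copies: empty mask, contig count + 1
  g0 <- random_genome(c(chr1 = 400), seed = 23)
  res0 <- build_rdna_reference(g0, unit, read_length = 40)
  expect_identical(nrow(res0$mask_intervals), 0L)
  expect_length(res0$masked_genome, 2)
})
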