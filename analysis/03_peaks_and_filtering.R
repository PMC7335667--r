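#!/usr/bin/env Rscript
# Call peaks per condition on the pooled simulated tags (Poisson
# significance at p <= 1e-5, fragment extension 180 bp), then apply the
# per-peak strand cross-correlation filter (shift 95 bp = 180 - 85;
# pass iff shifted >= 0.7 and shifted - unshifted >= 0.1), and score the
# calls against the planted truth.

library(mitobook)

lens <- read_genome_sizes("results/sim/genome.sizes")
truth <- read.table("results/sim/truth.tsv", header = TRUE, sep = "\t")
dir.create("results/peaks", recursive = TRUE, showWarnings = FALSE)

covers <- function(pk, kind, cond) {
  active <- truth$kind == kind & grepl(cond, truth$occupancy)
  vapply(seq_len(nrow(pk)), function(i) {
    any(active & truth$contig == pk$contig[i] &
          truth$center >= pk$start[i] & truth$center < pk$end[i])
  }, logical(1))
}

for (cond in c("A", "M", "G1")) {
  pooled <- do.call(rbind, lapply(1:2, function(r)
    read_tags(sprintf("results/sim/tags_%s_rep%d.tsv", cond, r))))
  called <- call_peaks(pooled, lens)
  flt <- filter_peaks(called$peaks, pooled, lens)
  write_narrowpeak(called$peaks,
                   sprintf("results/peaks/%s_pooled.narrowPeak", cond))
  write_narrowpeak(flt$kept,
                   sprintf("results/peaks/%s_kept.narrowPeak", cond))
  write_bedgraph(called$fe_track, sprintf("results/peaks/fe_%s.bedGraph", cond))
  write.table(flt$report, sprintf("results/peaks/xcor_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%-3s %3d peaks called; %2d kept after xcor filter (true-site peaks kept %d/%d, phantom peaks kept %d/%d)\n",
    cond, nrow(called$peaks), nrow(flt$kept),
    sum(covers(flt$kept, "true_site", cond)),
    sum(covers(called$peaks, "true_site", cond)),
    sum(covers(flt$kept, "phantom_artifact", cond)),
    sum(covers(called$peaks, "phantom_artifact", cond))))
}
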