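#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 2 x 300 kb genome, 50 genes
# (25% lncRNA), 40 planted binding sites (half bookmarked through M and
# G1), 10 phantom read stacks, stranded tags for A / M / G1 in duplicate,
# and a DE table with planted effects. Everything downstream (02-04)
# consumes these files.

library(mitobook)

params <- sim_params(seed = 20260921)
ds <- simulate_dataset(params, "results/sim")

truth <- ds$truth
cat("Simulated dataset written to results/sim\n")
cat(sprintf("  contigs: %d x %d bp; genes: %d (%d lncRNA)\n",
            params$n_contigs, params$contig_length,
            nrow(ds$genes$genes),
            sum(ds$genes$genes$biotype == "lncRNA")))
cat("  site occupancy classes:\n")
print(table(truth$kind, truth$occupancy))
cat(sprintf("  truly-DE genes planted: %d of %d\n",
            sum(ds$de$truly_de), nrow(ds$de)))
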