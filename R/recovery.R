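# Multi-seed simulation studies: the quantitative properties the synthetic
# truth makes measurable - discrimination of the cross-correlation filter,
# and end-to-end recovery of the planted bookmarked gene set.

#' Cross-correlation filter discrimination study
#'
#' For each seed, simulates one condition's tags from planted true sites
#' and phantom stacks, calls peaks, applies the strand cross-correlation
#' filter, and scores how many true-site peaks were retained and how many
#' phantom-covering peaks were rejected.
#'
#' @param n_seeds Number of independent simulations.
#' @param base_seed Seed from which per-simulation seeds are derived.
#' @param n_true_sites,n_artifacts,reads_per_site,background_rate
#'   Simulation settings for the study (defaults are the package's study
#'   conditions: 20 true sites, 10 phantom stacks, 300 reads per site,
#'   5e-4 background tags/bp/strand).
#' @return data.frame with one row per seed: `true_total`, `true_kept`,
#'   `phantom_total`, `phantom_rejected`.
#' @export
xcor_discrimination_study <- function(n_seeds = 20, base_seed = 1,
                                      n_true_sites = 20, n_artifacts = 10,
                                      reads_per_site = 300,
                                      background_rate = 5e-4) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    p <- sim_params(n_true_sites = n_true_sites, n_artifacts = n_artifacts,
                    reads_per_site = reads_per_site,
                    background_rate = background_rate,
                    seed = derive_seed(base_seed, paste0("xcor", i)))
    truth <- plant_sites(make_genes(make_genome(p), p), p)
    truth$occupancy <- "M"
    tags <- simulate_tags(truth, p, "M")
    lens <- setNames(rep(p$contig_length, p$n_contigs),
                     paste0("chr", seq_len(p$n_contigs)))
    peaks <- call_peaks(tags, lens)$peaks
    kept <- filter_peaks(peaks, tags, lens)$kept
    covers <- function(pk, kind) {
      if (nrow(pk) == 0) return(logical(0))
      vapply(seq_len(nrow(pk)), function(j) {
        any(truth$kind == kind & truth$contig == pk$contig[j] &
              truth$center >= pk$start[j] & truth$center < pk$end[j])
      }, logical(1))
    }
    data.frame(true_total = sum(covers(peaks, "true_site")),
               true_kept = sum(covers(kept, "true_site")),
               phantom_total = sum(covers(peaks, "phantom_artifact")),
               phantom_rejected = sum(covers(peaks, "phantom_artifact")) -
                 sum(covers(kept, "phantom_artifact")))
  })
  do.call(rbind, rows)
}

#' End-to-end bookmarked-gene recovery study
#'
#' For each seed, simulates a full dataset (all three conditions with
#' replicates), runs the analysis chain in memory (pooled peak calling,
#' replicate reproducibility, cross-correlation filtering, TSS annotation,
#' occupancy classification), and compares the recovered shared (M and G1)
#' gene set against the planted bookmarked genes.
#'
#' @param n_seeds Number of independent simulations.
#' @param base_seed Seed from which per-simulation seeds are derived.
#' @param params A [sim_params()] object used as the template (its `seed`
#'   is replaced per simulation).
#' @param n_replicates Tag replicates per condition.
#' @return data.frame with one row per seed: `planted_bookmarked`,
#'   `shared_count`, `precision`, `recall`.
#' @export
bookmark_recovery_study <- function(n_seeds = 20, base_seed = 1,
                                    params = sim_params(),
                                    n_replicates = 2) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    p <- params
    p$seed <- derive_seed(base_seed, paste0("recovery", i))
    genome <- make_genome(p)
    genes <- make_genes(genome, p)
    truth <- plant_sites(genes, p)
    lens <- contig_lengths(genome)
    ann <- list()
    for (cond in c("A", "M", "G1")) {
      reps <- lapply(seq_len(n_replicates), function(r)
        simulate_tags(truth, p, cond, r))
      pooled <- do.call(rbind, reps)
      peaks <- call_peaks(pooled, lens)$peaks
      rep_sets <- lapply(reps, function(t) call_peaks(t, lens)$peaks)
      peaks <- reproducible_peaks(peaks, rep_sets)
      kept <- filter_peaks(peaks, pooled, lens)$kept
      ann[[cond]] <- annotate_tss(kept, genes)
    }
    sets <- bound_gene_sets(ann)
    cls <- classify_genes(sets$A$all, sets$M$all, sets$G1$all)
    shared <- cls$report$gene_id[cls$report$category == "shared_M_G1"]
    planted <- truth$bound_gene_id[truth$kind == "true_site" &
                                     truth$occupancy == "A,M,G1"]
    data.frame(
      planted_bookmarked = length(planted),
      shared_count = length(shared),
      precision = if (length(shared) == 0) NA_real_ else
        mean(shared %in% planted),
      recall = if (length(planted) == 0) NA_real_ else
        mean(planted %in% shared))
  })
  do.call(rbind, rows)
}
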