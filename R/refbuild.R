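# rDNA-aware reference construction: tile short in-silico reads across the
# ribosomal repeat unit, hard-mask every exact occurrence (either strand) in
# the assembly, then append the complete unit as its own contig, so that
# repeat-derived reads align to one canonical place.

#' Tile fixed-length in-silico reads across a sequence
#'
#' @param unit_seq A single sequence string.
#' @param read_length Read length in bases (default 50).
#' @param step Step between consecutive read starts (default 1).
#' @return Character vector of `floor((L - read_length)/step) + 1` windows,
#'   in order, each exactly `read_length` bases.
#' @export
tile_reads <- function(unit_seq, read_length = 50, step = 1) {
  stopifnot(length(unit_seq) == 1, read_length >= 1, step >= 1)
  L <- nchar(unit_seq)
  if (L < read_length) {
    stop("sequence (", L, " bp) shorter than read_length (", read_length, ")")
  }
  starts <- seq(1L, L - read_length + 1L, by = step)
  substring(unit_seq, starts, starts + read_length - 1L)
}

#' Locate exact occurrences of reads in a genome, on either strand
#'
#' Reports one 0-based half-open interval per exact occurrence of each read
#' or its reverse complement, always on the forward coordinate system.
#' Duplicate and overlapping intervals are allowed (merge separately).
#'
#' @param reads Character vector of equal-length read sequences.
#' @param genome Named character vector of contig sequences.
#' @return data.frame with `contig`, `start`, `end`.
#' @export
locate_matches <- function(reads, genome) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer())
  if (length(reads) == 0) return(empty)
  if (length(unique(nchar(reads))) != 1) stop("reads must all be same length")
  w <- nchar(reads[1])
  queries <- unique(c(reads,
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAStringSet(reads)))))
  # PDict requires an N-free dictionary; N-containing queries cannot match
  # an A/C/G/T subject exactly anyway, and masked subject Ns never match.
  queries <- queries[!grepl("N", queries, fixed = TRUE)]
  if (length(queries) == 0) return(empty)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
  hits <- lapply(names(genome), function(nm) {
    subject <- Biostrings::DNAString(genome[[nm]])
    m <- Biostrings::matchPDict(pdict, subject)
    starts <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
    if (length(starts) == 0) return(NULL)
    data.frame(contig = nm, start = starts - 1L, end = starts - 1L + w)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) empty else out
}

#' Merge intervals into a sorted, disjoint set
#'
#' Overlapping and touching intervals merge; the union of covered bases is
#' preserved.
#'
#' @param intervals data.frame with `contig`, `start`, `end`.
#' @return data.frame of merged intervals, sorted by (contig, start).
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  }
  x <- intervals[order(intervals$contig, intervals$start, intervals$end), ,
                 drop = FALSE]
  out <- lapply(split(x, x$contig), function(g) {
    s <- g$start; e <- g$end
    keep_s <- s[1]; keep_e <- e[1]
    res_s <- integer(); res_e <- integer()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= keep_e) {           # overlap or touch
        keep_e <- max(keep_e, e[i])
      } else {
        res_s <- c(res_s, keep_s); res_e <- c(res_e, keep_e)
        keep_s <- s[i]; keep_e <- e[i]
      }
    }
    data.frame(contig = g$contig[1], start = c(res_s, keep_s),
               end = c(res_e, keep_e))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hard-mask genomic intervals with N
#'
#' @param genome Named character vector of contig sequences.
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open, within contig bounds).
#' @return The genome with masked bases replaced by `N`; lengths unchanged.
#' @export
hard_mask <- function(genome, intervals) {
  validate_genome(genome)
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(genome)
  if (!all(intervals$contig %in% names(genome))) {
    stop("interval on unknown contig: ",
         setdiff(intervals$contig, names(genome))[1])
  }
  lens <- contig_lengths(genome)
  if (any(intervals$end > lens[intervals$contig])) {
    stop("interval exceeds contig bounds")
  }
  for (i in seq_len(nrow(intervals))) {
    nm <- intervals$contig[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) {
      substr(genome[[nm]], s + 1L, e) <- strrep("N", e - s)
    }
  }
  genome
}

#' Build an rDNA-aware reference
#'
#' Tiles `read_length`-bp reads across the repeat unit, hard-masks every
#' exact occurrence of a tiled read (either strand) in the genome, and
#' appends the complete unit as a distinct contig.
#'
#' @param genome Named character vector of contig sequences.
#' @param unit_seq The repeat unit sequence (single string).
#' @param read_length,step Tiling parameters, see [tile_reads()].
#' @param contig_name Name for the appended unit contig.
#' @return A list with `masked_genome` (input contigs masked plus the
#'   appended unit), `mask_intervals` (merged, sorted), and
#'   `appended_contig_name`.
#' @export
build_rdna_reference <- function(genome, unit_seq, read_length = 50,
                                 step = 1, contig_name = "chrU13369.1") {
  validate_genome(genome)
  if (contig_name %in% names(genome)) {
    stop("contig '", contig_name, "' already present in genome")
  }
  reads <- tile_reads(unit_seq, read_length = read_length, step = step)
  mask <- merge_intervals(locate_matches(reads, genome))
  masked <- hard_mask(genome, mask)
  masked[[contig_name]] <- toupper(unit_seq)
  list(masked_genome = masked, mask_intervals = mask,
       appended_contig_name = contig_name)
}
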