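# Minimal single-sample peak caller: fragment-extension pileup, a local
# Poisson background lambda, per-base Poisson tail significance at a fixed
# p-value threshold, and a fold-enrichment track.

#' Peak-calling parameters
#'
#' @param p_threshold Per-base Poisson tail p-value threshold.
#' @param fragment_size Fragment-extension length in bases.
#' @param read_length Read length, used as the default candidate merge gap.
#' @param local_windows Window sizes (bases) for the local background
#'   lambda (used when a control tag set is supplied).
#' @param min_peak_length Minimum peak width; defaults to `fragment_size`.
#' @param merge_gap Maximum gap between significant bases merged into one
#'   peak; defaults to `read_length`.
#' @param fe_pseudocount Pseudocount added to both numerator and
#'   denominator of the fold-enrichment ratio.
#' @return A list of class `peak_call_params`.
#' @export
peak_call_params <- function(p_threshold = 1e-5, fragment_size = 180,
                             read_length = 85,
                             local_windows = c(1000, 5000, 10000),
                             min_peak_length = fragment_size,
                             merge_gap = read_length,
                             fe_pseudocount = 1.0) {
  stopifnot(p_threshold > 0, p_threshold < 1, fragment_size >= 1,
            all(local_windows > 0), min_peak_length >= 1, merge_gap >= 0)
  structure(list(p_threshold = p_threshold, fragment_size = fragment_size,
                 read_length = read_length, local_windows = local_windows,
                 min_peak_length = min_peak_length, merge_gap = merge_gap,
                 fe_pseudocount = fe_pseudocount),
            class = "peak_call_params")
}

#' Fragment-extension pileup
#'
#' A `+` tag at `p` covers `[p, p + fragment_size)`; a `-` tag at `p`
#' (5'-most base, i.e. the fragment's right end) covers
#' `[p - fragment_size + 1, p + 1)`. Coverage is clipped at contig edges.
#'
#' @param tags Tag data.frame (`contig`, `pos`, `strand`).
#' @param fragment_size Extension length in bases.
#' @param lengths Named integer vector of contig lengths.
#' @return Named list of per-contig integer coverage vectors (value at
#'   0-based position `i` is element `i + 1`).
#' @export
pileup <- function(tags, fragment_size, lengths) {
  validate_tags(tags)
  if (nrow(tags) > 0 && !all(tags$contig %in% names(lengths))) {
    stop("tag on unknown contig: ",
         setdiff(tags$contig, names(lengths))[1])
  }
  out <- lapply(names(lengths), function(nm) {
    L <- lengths[[nm]]
    t <- tags[tags$contig == nm, , drop = FALSE]
    if (nrow(t) == 0) return(integer(L))
    plus <- t$strand == "+"
    s <- ifelse(plus, t$pos, t$pos - fragment_size + 1L)
    e <- ifelse(plus, t$pos + fragment_size, t$pos + 1L)
    s <- pmax(s, 0L); e <- pmin(e, L)
    # difference array: +1 at each start, -1 past each end, then cumsum
    te <- tabulate(e, nbins = L)
    d <- tabulate(s + 1L, nbins = L) - c(0L, te[-L])
    cumsum(d)
  })
  setNames(out, names(lengths))
}

#' Local Poisson background track
#'
#' The expected coverage at each base is
#' `max(lambda_genome, lambda_w(x))` over the configured window sizes,
#' where `lambda_w` is the window-averaged pileup of the background source
#' centred at `x` and `lambda_genome` is total pileup mass over total
#' genome length. Without a control the background source is the treatment
#' itself and only the genome-wide rate is used, so the track is constant.
#'
#' @param tags Background-source tags (control if available, else the
#'   treatment tags).
#' @param params A [peak_call_params()] object.
#' @param lengths Named integer vector of contig lengths.
#' @param local Use the windowed local lambdas (TRUE for a genuine
#'   control, FALSE when the source is the treatment itself).
#' @return Named list of per-contig numeric lambda vectors.
#' @export
lambda_track <- function(tags, params, lengths, local = TRUE) {
  if (nrow(tags) == 0) stop("empty tag set: background rate is degenerate")
  cov <- pileup(tags, params$fragment_size, lengths)
  lambda_genome <- sum(vapply(cov, sum, numeric(1))) / sum(lengths)
  out <- lapply(names(lengths), function(nm) {
    v <- as.numeric(cov[[nm]])
    lam <- rep(lambda_genome, length(v))
    if (local) {
      cs <- cumsum(c(0, v))
      pos <- seq_along(v)
      for (w in params$local_windows) {
        lo <- pmax(pos - floor(w / 2), 1L)
        hi <- pmin(pos + ceiling(w / 2) - 1L, length(v))
        lam_w <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
        lam <- pmax(lam, lam_w)
      }
    }
    lam
  })
  setNames(out, names(lengths))
}

#' Upper-tail Poisson probability
#'
#' `P(X >= count)` for `X ~ Poisson(lam)`; exactly 1 for `count = 0`.
#'
#' @param count Non-negative integer observed count (vectorised).
#' @param lam Non-negative Poisson mean (vectorised).
#' @return Probability in `[0, 1]`.
#' @export
poisson_sf <- function(count, lam) {
  if (any(count < 0) || any(lam < 0)) stop("count and lam must be >= 0")
  ppois(count - 1, lam, lower.tail = FALSE)
}

#' Call peaks from stranded tags
#'
#' Bases whose pileup has Poisson tail probability `<= p_threshold` under
#' the local lambda are candidates; candidate runs separated by gaps
#' `<= merge_gap` merge into peaks; peaks shorter than `min_peak_length`
#' are dropped. The summit is the leftmost position of maximal pileup
#' within the peak; fold enrichment at the summit (and along the returned
#' track) is `(pileup + fe_pseudocount) / (lambda + fe_pseudocount)`.
#'
#' @param tags Treatment tag data.frame.
#' @param lengths Named integer vector of contig lengths.
#' @param params A [peak_call_params()] object.
#' @param control Optional control tag data.frame; when supplied the
#'   background lambda uses the windowed local model on the control.
#' @return A list with `peaks` (data.frame: `contig`, `start`, `end`,
#'   `name`, `summit`, `max_pileup`, `min_pvalue`, `fold_enrichment`) and
#'   `fe_track` (named list of per-contig per-base fold-enrichment
#'   vectors).
#' @export
call_peaks <- function(tags, lengths, params = peak_call_params(),
                       control = NULL) {
  if (nrow(tags) == 0) stop("cannot call peaks on an empty tag set")
  cov <- pileup(tags, params$fragment_size, lengths)
  lam <- if (is.null(control)) {
    # background source = treatment, genome-wide rate only
    lg <- sum(vapply(cov, sum, numeric(1))) / sum(lengths)
    setNames(lapply(lengths, function(L) rep(lg, L)), names(lengths))
  } else {
    lambda_track(control, params, lengths, local = TRUE)
  }
  fe_track <- setNames(lapply(names(lengths), function(nm) {
    (cov[[nm]] + params$fe_pseudocount) / (lam[[nm]] + params$fe_pseudocount)
  }), names(lengths))
  peak_rows <- list()
  for (nm in names(lengths)) {
    # a base can only be significant where coverage exceeds lambda
    # (p_threshold < 1); evaluate the Poisson tail just there
    pv <- rep(1, length(cov[[nm]]))
    idx <- which(cov[[nm]] > lam[[nm]])
    pv[idx] <- poisson_sf(cov[[nm]][idx], lam[[nm]][idx])
    cand <- which(pv <= params$p_threshold)   # 1-based indices
    if (length(cand) == 0) next
    grp <- cumsum(c(1, diff(cand) > params$merge_gap + 1))
    for (g in split(cand, grp)) {
      start0 <- g[1] - 1L
      end0 <- g[length(g)]          # half-open end = last candidate + 1
      if (end0 - start0 < params$min_peak_length) next
      seg <- cov[[nm]][(start0 + 1L):end0]
      summit0 <- start0 + which.max(seg) - 1L
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        contig = nm, start = start0, end = end0,
        summit = summit0,
        max_pileup = max(seg),
        min_pvalue = min(pv[(start0 + 1L):end0]),
        fold_enrichment = fe_track[[nm]][summit0 + 1L])
    }
  }
  peaks <- if (length(peak_rows) == 0) {
    data.frame(contig = character(), start = integer(), end = integer(),
               summit = integer(), max_pileup = integer(),
               min_pvalue = numeric(), fold_enrichment = numeric())
  } else {
    do.call(rbind, peak_rows)
  }
  if (nrow(peaks) > 0) {
    peaks <- peaks[order(peaks$contig, peaks$start), , drop = FALSE]
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    peaks <- peaks[, c("contig", "start", "end", "name", "summit",
                       "max_pileup", "min_pvalue", "fold_enrichment")]
  } else {
    peaks$name <- character(0)
  }
  list(peaks = peaks, fe_track = fe_track)
}
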