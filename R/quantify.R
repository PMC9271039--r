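#' Count breakends overlapping predicted sites
#'
#' A breakend counts toward a site when its position lies inside the site
#' interval and, if `strand_match`, the strands agree (required for the
#' AsiSI 1-bp reductions, where each strand has its own predicted
#' position). A breakend overlapping several sites counts toward each of
#' them; when this happens the double-counted breakend total is reported so
#' it can be audited.
#'
#' @param bk Breakend `GRanges`.
#' @param sites `GRanges` of site intervals (full motif intervals, 1-bp
#'   reductions, or 2-bp cut windows).
#' @param strand_match Require matching strand (default `FALSE`).
#' @return `sites` with an integer metadata column `n_breaks`.
#' @export
count_breaks_at_sites <- function(bk, sites, strand_match = FALSE) {
  stopifnot(methods::is(bk, "GRanges"), methods::is(sites, "GRanges"))
  n <- GenomicRanges::countOverlaps(sites, bk,
                                    ignore.strand = !strand_match)
  per_bk <- GenomicRanges::countOverlaps(bk, sites,
                                         ignore.strand = !strand_match)
  if (any(per_bk > 1L))
    message("count_breaks_at_sites: ", sum(per_bk > 1L),
            " breakend(s) overlap >1 site and count toward each")
  out <- sites
  S4Vectors::mcols(out)$n_breaks <- n
  out
}

#' Rank sites by break count and compute the cumulative break frequency
#'
#' Sites are ordered by `n_breaks` descending (ties broken by chromosome
#' then start, so output is deterministic); the cumulative percentage is
#' the running break total over the grand total, computed on exact
#' integers. The resulting curve is monotone and ends at 100% whenever any
#' break was observed; its shape summarises how unevenly cutting efficiency
#' is distributed across sites.
#'
#' @param counted `GRanges` with an `n_breaks` column (from
#'   [count_breaks_at_sites()]), or an integer vector of counts.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (when site coordinates are available), `n_breaks`, `rank`, `cum_pct`.
#'   Zero total breaks gives an empty curve with a warning.
#' @examples
#' rank_and_cumulate(c(10L, 30L, 60L))
#' @export
rank_and_cumulate <- function(counted) {
  if (methods::is(counted, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(counted)),
      start = GenomicRanges::start(counted),
      end = GenomicRanges::end(counted),
      strand = as.character(GenomicRanges::strand(counted)),
      n_breaks = as.integer(counted$n_breaks))
  } else {
    df <- data.frame(chrom = NA_character_, start = seq_along(counted),
                     end = seq_along(counted), strand = "*",
                     n_breaks = as.integer(counted))
  }
  total <- sum(df$n_breaks)
  if (total == 0L) {
    warning("no breaks at any site; empty cumulative curve")
    return(cbind(df[0L, ], rank = integer(0L), cum_pct = numeric(0L)))
  }
  o <- order(-df$n_breaks, df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$cum_pct <- cumsum(as.numeric(df$n_breaks)) / total * 100
  rownames(df) <- NULL
  df
}

#' Keep sites with at least a minimum number of breaks
#'
#' The detection threshold used to call a site "cut": e.g. >= 5 breaks per
#' site when benchmarking restriction digestion.
#'
#' @param counted `GRanges` with an `n_breaks` column.
#' @param min_breaks Minimum count (default 5).
#' @return The subset of sites meeting the threshold.
#' @export
define_break_sites <- function(counted, min_breaks = 5L) {
  stopifnot(methods::is(counted, "GRanges"), !is.null(counted$n_breaks))
  counted[counted$n_breaks >= min_breaks]
}

#' Average breaks per cell
#'
#' With a digital readout, total reads equal total labelled break ends, so
#' total breaks divided by the number of cells assayed is the mean break
#' burden per cell.
#'
#' @param total_breaks Total break count (>= 0).
#' @param n_cells Number of cells (> 0).
#' @return `total_breaks / n_cells`.
#' @examples
#' breaks_per_cell(200000, 100000)
#' @export
breaks_per_cell <- function(total_breaks, n_cells) {
  stopifnot(total_breaks >= 0)
  if (n_cells <= 0) stop("n_cells must be > 0")
  total_breaks / n_cells
}

#' Nuclease-induced breaks per million sequenced reads
#'
#' Sequencing-depth normalisation for comparing samples: breaks detected at
#' target sites per million total reads.
#'
#' @param n_breaks_at_sites Breaks overlapping target sites (>= 0).
#' @param total_reads Total reads in the sample (> 0).
#' @return `n_breaks_at_sites / total_reads * 1e6`.
#' @export
breaks_per_million <- function(n_breaks_at_sites, total_reads) {
  stopifnot(n_breaks_at_sites >= 0)
  if (total_reads <= 0) stop("total_reads must be > 0")
  n_breaks_at_sites / total_reads * 1e6
}

#' Subsample breakends in silico
#'
#' Keeps each breakend independently with probability `fraction`
#' (Bernoulli thinning, mirroring an in-silico subset of the sequencing
#' run), or exactly `round(fraction * n)` of them without replacement when
#' `exact = TRUE`. Deterministic given `seed`. Because each read is one
#' break, per-site counts after thinning are proportional to `fraction` up
#' to binomial noise.
#'
#' @param bk Breakend `GRanges`.
#' @param fraction Retention fraction in (0, 1].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param exact Draw an exact-count subsample instead of Bernoulli
#'   thinning.
#' @return The subsampled breakends (original order preserved).
#' @export
subsample_breakends <- function(bk, fraction, seed = NULL, exact = FALSE) {
  stopifnot(methods::is(bk, "GRanges"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(bk)
  if (!is.null(seed)) set.seed(seed)
  n <- length(bk)
  keep <- if (exact) {
    sort(sample.int(n, round(fraction * n)))
  } else {
    which(stats::runif(n) < fraction)
  }
  bk[keep]
}

#' Table of recurrent breaks in treated vs control samples
#'
#' Collapses breakends by genomic position (and strand, unless
#' `strand_aware = FALSE`), ranks positions by their treated-sample count,
#' and flags positions that also carry at least one break in the control —
#' the signature of an endogenous fragile site rather than a
#' nuclease-induced cut.
#'
#' @param treated,control Breakend `GRanges` for the two groups.
#' @param strand_aware Collapse per strand (default `TRUE`).
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `strand`,
#'   `n_treated`, `n_control`, `shared_with_control`, ordered by
#'   `n_treated` descending (ties by chrom, pos); only positions with at
#'   least one treated break are listed.
#' @export
recurrent_break_table <- function(treated, control,
                                  strand_aware = TRUE) {
  stopifnot(methods::is(treated, "GRanges"), methods::is(control, "GRanges"))
  keyify <- function(x) {
    s <- if (strand_aware) as.character(GenomicRanges::strand(x)) else "*"
    paste(as.character(GenomicRanges::seqnames(x)),
          GenomicRanges::start(x), s, sep = "\r")
  }
  tt <- table(keyify(treated))
  ct <- table(keyify(control))
  keys <- names(tt)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(
    chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
    strand = parts[, 3L],
    n_treated = as.integer(tt),
    n_control = as.integer(ct[keys]))
  df$n_control[is.na(df$n_control)] <- 0L
  df$shared_with_control <- df$n_control >= 1L
  df <- df[order(-df$n_treated, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Overlap structure of site lists from different methods
#'
#' Given two or more named interval collections (e.g. off-target sites
#' reported by different detection methods), computes (i) the pairwise
#' matrix whose (i, j) entry is the number of sites in list i overlapping
#' any site in list j by >= 1 bp, and (ii) upset-style counts: merged loci
#' (the reduced union of all lists) classified by which methods detect
#' them.
#'
#' @param site_lists Named list (length >= 2) of `GRanges`.
#' @return A list with elements `pairwise` (integer matrix) and
#'   `combinations` (`data.frame` with one logical column per method plus
#'   `n_loci`).
#' @export
site_set_overlap <- function(site_lists) {
  stopifnot(is.list(site_lists), length(site_lists) >= 2L,
            !is.null(names(site_lists)))
  nm <- names(site_lists)
  k <- length(site_lists)
  pairwise <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- sum(IRanges::overlapsAny(
      site_lists[[i]], site_lists[[j]], ignore.strand = TRUE))
  pooled <- GenomicRanges::reduce(
    do.call(c, unname(lapply(site_lists, function(g) {
      g2 <- GenomicRanges::granges(g)
      GenomicRanges::strand(g2) <- "*"
      g2
    }))), ignore.strand = TRUE)
  member <- vapply(site_lists, function(g)
    IRanges::overlapsAny(pooled, g, ignore.strand = TRUE),
    logical(length(pooled)))
  member <- matrix(member, nrow = length(pooled), dimnames = list(NULL, nm))
  pat <- apply(member, 1L, paste, collapse = "\r")
  combos <- unique(member)
  n_loci <- as.integer(table(pat)[apply(combos, 1L, paste, collapse = "\r")])
  out <- as.data.frame(combos)
  out$n_loci <- n_loci
  rownames(out) <- NULL
  list(pairwise = pairwise, combinations = out)
}
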