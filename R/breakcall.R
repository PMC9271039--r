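#' Breakend-calling configuration
#'
#' Bundles the filtering parameters of the breakend-calling pipeline:
#' minimum mapping quality (alignments with MAPQ below it are ambiguous and
#' removed), whether to drop soft-clipped reads (clipped ends make the 5'
#' terminus unreliable, so single-nucleotide break assignment would be
#' wrong), the optical-duplicate pixel radius, and a blacklist of regions
#' (poor mappability, chromosome ends, incomplete contigs) to exclude.
#'
#' @param min_mapq Minimum MAPQ to retain an alignment (default 30).
#' @param drop_softclipped Drop reads with any `S` CIGAR operation
#'   (default `TRUE`).
#' @param optical_dup_max_dist Pixel radius for optical-duplicate clustering
#'   within a lane/tile (default 100).
#' @param blacklist A `GRanges` of regions whose breakends are discarded,
#'   or `NULL`.
#' @param convention Breakend coordinate convention; see
#'   [assign_breakends()].
#' @return An object of class `call_config`.
#' @export
call_config <- function(min_mapq = 30L, drop_softclipped = TRUE,
                        optical_dup_max_dist = 100,
                        blacklist = NULL,
                        convention = c("terminal_base", "preceding_base")) {
  stopifnot(min_mapq >= 0L, optical_dup_max_dist >= 0,
            is.logical(drop_softclipped))
  if (!is.null(blacklist)) stopifnot(methods::is(blacklist, "GRanges"))
  structure(list(min_mapq = as.integer(min_mapq),
                 drop_softclipped = drop_softclipped,
                 optical_dup_max_dist = optical_dup_max_dist,
                 blacklist = blacklist,
                 convention = match.arg(convention)),
            class = "call_config")
}

#' Filter alignments on mapping quality and soft-clipping
#'
#' Removes alignments with `mapq < min_mapq` and (optionally) any read whose
#' CIGAR contains a soft-clip. A MAPQ of NA (SAM's "unavailable", 255) is
#' treated as failing the threshold. Counts removed per reason are reported
#' as a message and attached as `attr(, "removed")`.
#'
#' @param reads Alignment `GRanges` from [read_alignments()].
#' @param config A [call_config()].
#' @return The retained alignments.
#' @export
filter_alignments <- function(reads, config = call_config()) {
  stopifnot(methods::is(reads, "GRanges"))
  low <- is.na(reads$mapq) | reads$mapq < config$min_mapq
  soft <- if (config$drop_softclipped) reads$has_softclip else
    rep(FALSE, length(reads))
  removed <- c(low_mapq = sum(low), softclip = sum(soft & !low))
  message("filter_alignments: removed ", removed[["low_mapq"]],
          " low-MAPQ and ", removed[["softclip"]], " soft-clipped read(s); ",
          sum(!(low | soft)), " retained")
  out <- reads[!(low | soft)]
  attr(out, "removed") <- removed
  out
}

#' Assign single-nucleotide breakends to filtered reads
#'
#' Each retained read marks one break end: its 5'-terminal aligned base.
#' For a plus-strand read this is the leftmost aligned position; for a
#' minus-strand read, the rightmost. The breakend keeps the read's strand,
#' so the two reads flanking a blunt cut between positions k and k+1 yield
#' a plus breakend at k+1 and a minus breakend at k.
#'
#' The alternative reading of "first 5' nucleotide upstream of the read" —
#' the base immediately *preceding* the read — is available as
#' `convention = "preceding_base"`; only the terminal-base convention
#' reproduces the AsiSI site reduction (in-site positions 6/+ and 3/-)
#' implied by AsiSI's 2-nt 3'-overhang chemistry, so it is the default.
#'
#' @param reads Filtered alignment `GRanges`.
#' @param sample_id Sample label attached to every breakend.
#' @param convention `"terminal_base"` (default) or `"preceding_base"`.
#' @return A breakend `GRanges` (see [breakends()]). Reads whose names do
#'   not carry Illumina flow-cell fields get `NA` coordinates and are later
#'   exempt from optical deduplication (their count is reported).
#' @export
assign_breakends <- function(reads, sample_id = "sample1",
                             convention = c("terminal_base",
                                            "preceding_base")) {
  stopifnot(methods::is(reads, "GRanges"))
  convention <- match.arg(convention)
  str <- as.character(GenomicRanges::strand(reads))
  if (any(str == "*")) stop("reads must be stranded")
  pos <- ifelse(str == "+", GenomicRanges::start(reads),
                GenomicRanges::end(reads))
  if (convention == "preceding_base")
    pos <- ifelse(str == "+", pos - 1L, pos + 1L)
  bk <- breakends(chrom = as.character(GenomicRanges::seqnames(reads)),
                  pos = pos, strand = str, sample_id = sample_id,
                  read_id = reads$read_id)
  n_nofc <- sum(is.na(bk$lane))
  if (n_nofc > 0L)
    message("assign_breakends: ", n_nofc, " read(s) without parseable ",
            "flow-cell coordinates (kept; exempt from optical dedup)")
  bk
}

#' Remove breakends falling in blacklisted regions
#'
#' Strand-blind containment test against half-open intervals: a breakend at
#' position p is removed when p lies inside any blacklist region.
#'
#' @param bk Breakend `GRanges`.
#' @param blacklist `GRanges` of regions; `NULL` or empty is the identity.
#' @return The retained breakends; removed count reported as a message.
#' @export
apply_blacklist <- function(bk, blacklist = NULL) {
  stopifnot(methods::is(bk, "GRanges"))
  if (is.null(blacklist) || length(blacklist) == 0L) return(bk)
  hit <- IRanges::overlapsAny(bk, blacklist, ignore.strand = TRUE)
  message("apply_blacklist: removed ", sum(hit), " breakend(s)")
  bk[!hit]
}

# single-linkage clusters of 2-d points with pairwise threshold `h`
.xy_clusters <- function(x, y, h) {
  n <- length(x)
  if (n == 1L) return(1L)
  if (n == 2L) {
    d <- sqrt((x[1L] - x[2L])^2 + (y[1L] - y[2L])^2)
    return(if (d <= h) c(1L, 1L) else c(1L, 2L))
  }
  hc <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
  stats::cutree(hc, h = h)
}

#' Remove optical duplicates while retaining recurrent breaks
#'
#' Reads from neighbouring flow-cell clusters are spurious copies of one
#' break, not independent events. Among breakends that agree on
#' (sample, chrom, pos, strand, lane, tile), single-linkage clusters under
#' Euclidean pixel distance <= `max_dist` are collapsed to one
#' representative: the lexicographically smallest (x, y), so output is
#' reproducible. Breakends at the same genomic position but on different
#' tiles or lanes, or farther apart than `max_dist`, are all retained —
#' those are genuine recurrent breaks from different cells. Breakends
#' without flow-cell coordinates bypass deduplication entirely.
#'
#' @param bk Breakend `GRanges`.
#' @param max_dist Pixel radius (default 100).
#' @return Deduplicated breakends; removed count reported as a message.
#' @export
remove_optical_duplicates <- function(bk, max_dist = 100) {
  stopifnot(methods::is(bk, "GRanges"))
  if (length(bk) == 0L) return(bk)
  has_fc <- !is.na(bk$lane) & !is.na(bk$tile) & !is.na(bk$x) & !is.na(bk$y)
  key <- paste(bk$sample_id, as.character(GenomicRanges::seqnames(bk)),
               GenomicRanges::start(bk), as.character(GenomicRanges::strand(bk)),
               bk$lane, bk$tile, sep = "\r")
  keep <- rep(TRUE, length(bk))
  idx_fc <- which(has_fc)
  if (length(idx_fc)) {
    grp <- split(idx_fc, key[idx_fc])
    grp <- grp[lengths(grp) > 1L]
    for (ii in grp) {
      cl <- .xy_clusters(bk$x[ii], bk$y[ii], max_dist)
      for (c_id in unique(cl)) {
        jj <- ii[cl == c_id]
        if (length(jj) > 1L) {
          rep_i <- jj[order(bk$x[jj], bk$y[jj])][1L]
          keep[setdiff(jj, rep_i)] <- FALSE
        }
      }
    }
  }
  message("remove_optical_duplicates: removed ", sum(!keep),
          " optical duplicate(s)")
  bk[keep]
}

#' Call breakends from aligned reads
#'
#' The full calling pipeline, in fixed order: filter alignments (MAPQ,
#' soft-clips), assign 5'-terminal breakends, drop blacklisted positions,
#' remove optical duplicates. Output is sorted by (chrom, pos, strand), so
#' identical inputs give byte-identical output files. Each retained read
#' contributes exactly one breakend: read multiplicity at a position is the
#' number of cells broken there, with no amplification correction needed.
#'
#' @param reads Alignment `GRanges` from [read_alignments()], or a path to
#'   a SAM/BAM file.
#' @param config A [call_config()].
#' @param sample_id Sample label.
#' @return A sorted breakend `GRanges`.
#' @export
call_breakends <- function(reads, config = call_config(),
                           sample_id = "sample1") {
  if (is.character(reads)) reads <- read_alignments(reads)
  bk <- filter_alignments(reads, config)
  bk <- assign_breakends(bk, sample_id = sample_id,
                         convention = config$convention)
  bk <- apply_blacklist(bk, config$blacklist)
  bk <- remove_optical_duplicates(bk, config$optical_dup_max_dist)
  sort_breakends(bk)
}

#' Sort breakends deterministically by (chrom, pos, strand)
#' @param bk Breakend `GRanges`.
#' @return `bk`, reordered.
#' @export
sort_breakends <- function(bk) {
  o <- order(as.character(GenomicRanges::seqnames(bk)),
             GenomicRanges::start(bk),
             as.character(GenomicRanges::strand(bk)))
  bk[o]
}
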