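.coerce_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (methods::is(genome, "DNAString"))
    return(Biostrings::DNAStringSet(stats::setNames(
      as.character(genome), "chr1")))
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("chr", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

# mismatches of oriented window sequences against a pattern; positions where
# the pattern has N are wildcards and never count
.pattern_mismatches <- function(seqs, pattern, positions = NULL) {
  pat <- strsplit(pattern, "")[[1L]]
  live <- which(pat != "N")
  if (!is.null(positions)) live <- intersect(live, positions)
  if (length(seqs) == 0L) return(integer(0L))
  m <- matrix(unlist(strsplit(seqs, "")), nrow = nchar(pattern))
  as.integer(colSums(m[live, , drop = FALSE] != pat[live]))
}

.is_palindromic <- function(motif) {
  motif == as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
}

# one-strand mismatch scan of `pattern` (N = wildcard) over one chromosome;
# returns in-range matches as a data.frame(start, seq)
.scan_one <- function(chromseq, pattern, max_mm) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), chromseq, max.mismatch = max_mm,
    with.indels = FALSE,
    fixed = if (grepl("N", pattern, fixed = TRUE)) "subject" else TRUE)
  st <- Biostrings::start(hits)
  en <- Biostrings::end(hits)
  ok <- st >= 1L & en <= length(chromseq)
  st <- st[ok]
  seqs <- if (length(st))
    as.character(Biostrings::extractAt(
      chromseq, IRanges::IRanges(st, width = nchar(pattern)))) else
    character(0L)
  # assembly gaps and other ambiguity codes never match
  ok2 <- !grepl("[^ACGT]", seqs)
  data.frame(start = st[ok2], seq = seqs[ok2])
}

#' Locate a nuclease recognition motif with mismatch tolerance
#'
#' Reports every genomic window, on both strands, within Hamming distance
#' `max_mm` of `motif` (no indels). Windows containing `N` or any other
#' ambiguity code never match, which keeps assembly gaps and chromosome
#' ends out of the site set. For palindromic motifs (e.g. the restriction
#' sites AAGCTT and GCGATCGC) both orientations match at exactly the same
#' loci with the same distances, so by default each locus is reported once,
#' in forward orientation — per-site break counts then aggregate the
#' breakends of both strands.
#'
#' @param genome A `DNAStringSet` (or named character vector) of
#'   chromosomes.
#' @param motif Recognition sequence over A/C/G/T.
#' @param max_mm Maximum Hamming distance (default 0); must be less than
#'   the motif length.
#' @param collapse_palindromic Report palindromic motifs once per locus
#'   (default `TRUE`).
#' @return A `GRanges` of predicted sites with metadata columns
#'   `matched_seq` (motif-oriented genomic sequence) and `n_mismatch`.
#' @examples
#' locate_motif(c(chr1 = "TTAAGCTTGG"), "AAGCTT")
#' @export
locate_motif <- function(genome, motif, max_mm = 0L,
                         collapse_palindromic = TRUE) {
  genome <- .coerce_genome(genome)
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  if (max_mm >= nchar(motif)) stop("max_mm must be < motif length")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  one_locus <- collapse_palindromic && motif == rc
  res <- lapply(seq_along(genome), function(i) {
    chromseq <- genome[[i]]
    fwd <- .scan_one(chromseq, motif, max_mm)
    out <- list(data.frame(chrom = rep(names(genome)[i], nrow(fwd)),
                           start = fwd$start,
                           strand = rep("+", nrow(fwd)),
                           matched_seq = fwd$seq,
                           stringsAsFactors = FALSE))
    if (!one_locus) {
      rev <- .scan_one(chromseq, rc, max_mm)
      rev_seq <- if (nrow(rev)) as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rev$seq))) else character(0L)
      out <- c(out, list(data.frame(chrom = rep(names(genome)[i], nrow(rev)),
                                    start = rev$start,
                                    strand = rep("-", nrow(rev)),
                                    matched_seq = rev_seq,
                                    stringsAsFactors = FALSE)))
    }
    do.call(rbind, out)
  })
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, width = nchar(motif)),
    strand = df$strand,
    matched_seq = df$matched_seq,
    n_mismatch = .pattern_mismatches(df$matched_seq, motif))
  sort(gr, ignore.strand = TRUE)
}

#' Reduce AsiSI recognition sites to their two predicted breakend positions
#'
#' AsiSI cleaves its 8-bp site GCGATCGC leaving 2-nt 3' overhangs; after
#' end preparation, the sequenced 5' break ends sit at in-site position 6 on
#' the plus strand and position 3 on the minus strand (1-based within the
#' site). Each 8-bp site is therefore reduced to two stranded 1-bp
#' intervals at those offsets, against which breakends are intersected with
#' strand matching.
#'
#' @param sites `GRanges` of 8-bp AsiSI sites (from [locate_motif()]).
#' @return A `GRanges` of width-1 predicted breakend positions, two per
#'   site (plus then minus), with a `site_id` metadata column indexing the
#'   input site.
#' @export
reduce_asisi_site <- function(sites) {
  stopifnot(methods::is(sites, "GRanges"))
  if (length(sites) && any(GenomicRanges::width(sites) != 8L))
    stop("AsiSI sites must be 8 bp")
  s <- GenomicRanges::start(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  n <- length(sites)
  GenomicRanges::GRanges(
    seqnames = rep(chrom, each = 2L),
    ranges = IRanges::IRanges(
      start = as.vector(rbind(s + 5L, s + 2L)), width = 1L),
    strand = rep(c("+", "-"), times = n),
    site_id = rep(seq_len(n), each = 2L))
}

#' Drop sites on excluded chromosomes
#'
#' Used e.g. to remove chrY sites when the cell line is female.
#'
#' @param sites A `GRanges`.
#' @param chroms Character vector of chromosome names to exclude.
#' @return `sites` without the excluded chromosomes (seqlevels pruned).
#' @export
exclude_chromosomes <- function(sites, chroms) {
  stopifnot(methods::is(sites, "GRanges"))
  if (length(chroms) == 0L) return(sites)
  out <- sites[!as.character(GenomicRanges::seqnames(sites)) %in% chroms]
  GenomeInfoDb::dropSeqlevels(out, intersect(
    chroms, GenomeInfoDb::seqlevels(out)))
}

#' Expected CRISPR cut window of a protospacer+PAM site
#'
#' SpCas9 cuts bluntly 3 bp upstream of the PAM, i.e. between protospacer
#' bases 17 and 18 for a 20-nt spacer. Each oriented
#' protospacer+PAM site is reduced to the 2-bp interval flanking that cut:
#' the two bases whose 5' break ends a blunt cut produces. For a
#' plus-oriented site starting at s (1-based) with a 3-bp PAM the window is
#' [s+16, s+17]; for a minus-oriented site (PAM leftmost) it is
#' [s+5, s+6]. The window is unstranded: both break ends of a blunt cut
#' fall inside it.
#'
#' @param sites Oriented `GRanges` of protospacer+PAM sites.
#' @param pam_len PAM length (default 3).
#' @return A width-2 unstranded `GRanges`, parallel to `sites`.
#' @export
crispr_cut_window <- function(sites, pam_len = 3L) {
  stopifnot(methods::is(sites, "GRanges"))
  w <- GenomicRanges::width(sites)
  if (length(sites) && any(w < pam_len + 4L))
    stop("sites shorter than pam_len + 4")
  str <- as.character(GenomicRanges::strand(sites))
  if (any(str == "*")) stop("sites must be oriented (+/-)")
  s <- GenomicRanges::start(sites)
  spacer_len <- w - pam_len
  st <- as.integer(ifelse(str == "+", s + spacer_len - 4L,
                          s + pam_len + 2L))
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::IRanges(start = st, width = rep(2L, length(st))),
    strand = rep("*", length(st)))
}
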