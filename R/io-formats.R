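#' Read a reference genome from FASTA
#'
#' Loads a (multi-record) FASTA file into a `DNAStringSet`, uppercasing all
#' sequence. Record names are truncated at the first whitespace, as aligners
#' do. Duplicate record names are an error: downstream coordinates would be
#' ambiguous.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L)
    stop("malformed FASTA '", path, "': no records (line 1)")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in '", path, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Parse Illumina read names into flow-cell coordinates
#'
#' Standard Illumina read identifiers are colon-delimited:
#' `instrument:run:flowcell:lane:tile:x:y` (optionally followed by a
#' space-separated comment, which is ignored). The lane, tile and x/y pixel
#' coordinates are what optical-duplicate removal needs.
#'
#' @param name Character vector of read names.
#' @param strict If `TRUE` (default), any unparseable name is an error. If
#'   `FALSE`, unparseable names yield `NA` coordinates, which downstream
#'   exempts those reads from optical deduplication rather than dropping them.
#' @return A `data.frame` with integer columns `lane`, `tile`, `x`, `y`,
#'   one row per name.
#' @examples
#' parse_illumina_read_name("M01:5:FC1:1:1101:15000:20000")
#' @export
parse_illumina_read_name <- function(name, strict = TRUE) {
  stopifnot(is.character(name))
  # drop the space-separated comment ("1:N:0:ACGTAA" etc.)
  core <- sub("\\s.*$", "", name)
  parts <- strsplit(core, ":", fixed = TRUE)
  grab <- function(p) {
    if (length(p) < 7L) return(rep(NA_integer_, 4L))
    v <- suppressWarnings(as.integer(p[4:7]))
    if (anyNA(v) || any(v < 0L)) return(rep(NA_integer_, 4L))
    v
  }
  m <- vapply(parts, grab, integer(4L))
  out <- data.frame(lane = m[1L, ], tile = m[2L, ], x = m[3L, ], y = m[4L, ])
  if (strict && anyNA(out$lane)) {
    bad <- name[is.na(out$lane)]
    stop("cannot parse Illumina read name(s): ",
         paste(utils::head(bad, 3L), collapse = ", "),
         if (length(bad) > 3L) sprintf(" (and %d more)", length(bad) - 3L))
  }
  out
}

#' Read aligned reads from SAM/BAM
#'
#' Imports mapped records as a `GRanges` whose range is the reference span of
#' the alignment, with metadata columns `read_id`, `mapq`, `cigar` and
#' `has_softclip`. SAM text files are converted on the fly. Unmapped records
#' are dropped (with a message). Coordinates follow the usual R/Bioconductor
#' convention (1-based, closed); BED output converts at the boundary.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return A [GenomicRanges::GRanges] of alignments.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  mapped <- !is.na(b$pos) & !bitwAnd(b$flag, 4L)
  if (any(!mapped))
    message(sum(!mapped), " unmapped record(s) dropped")
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[mapped])
  gr <- GenomicRanges::GRanges(
    seqnames = droplevels(b$rname[mapped]),
    ranges = IRanges::IRanges(start = b$pos[mapped], width = w),
    strand = b$strand[mapped],
    read_id = b$qname[mapped],
    mapq = b$mapq[mapped],
    cigar = b$cigar[mapped],
    has_softclip = grepl("S", b$cigar[mapped], fixed = TRUE))
  gr
}

#' Construct a breakend set
#'
#' A breakend is a single-nucleotide, stranded genomic position: one end of
#' one double-strand break, carried by exactly one retained read (the digital
#' readout). Represented as a width-1 `GRanges` with metadata columns
#' `sample_id`, `read_id` and flow-cell coordinates `lane`, `tile`, `x`, `y`
#' (`NA` when the read name carries none).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param strand `"+"` or `"-"` per breakend (never `"*"`).
#' @param sample_id Sample label (recycled).
#' @param read_id Read identifiers; flow-cell coordinates are parsed from
#'   them when they follow the Illumina convention.
#' @return A width-1 [GenomicRanges::GRanges].
#' @export
breakends <- function(chrom, pos, strand, sample_id = "sample1",
                      read_id = NA_character_) {
  n <- length(pos)
  strand <- rep_len(as.character(strand), n)
  if (any(!strand %in% c("+", "-")))
    stop("breakend strand must be '+' or '-'")
  if (any(pos < 1L)) stop("breakend positions must be >= 1")
  read_id <- rep_len(read_id, n)
  fc <- parse_illumina_read_name(
    ifelse(is.na(read_id), "", read_id), strict = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    strand = strand,
    sample_id = rep_len(sample_id, n),
    read_id = read_id,
    lane = fc$lane, tile = fc$tile, x = fc$x, y = fc$y)
  gr
}

#' Write breakends to a BED6 file
#'
#' One width-1 interval per breakend: `chrom  pos  pos+1  read_id  .  strand`
#' with 0-based half-open coordinates as BED requires. The internal 1-based
#' position is converted at this boundary only.
#'
#' @param x Breakend `GRanges` (see [breakends()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakends <- function(x, path) {
  stopifnot(methods::is(x, "GRanges"))
  if (length(x) && any(GenomicRanges::width(x) != 1L))
    stop("breakends must be width-1 intervals")
  name <- if (!is.null(x$read_id)) as.character(x$read_id) else
    rep(NA_character_, length(x))
  name[is.na(name)] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::start(x),
    name = name,
    score = ".",
    strand = as.character(GenomicRanges::strand(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read breakends from a BED6 file
#'
#' Inverse of [write_breakends()]: the round trip preserves
#' (chrom, pos, strand, read_id) exactly. Malformed records — zero- or
#' negative-width intervals, width other than 1, negative coordinates, or a
#' strand symbol other than `+`/`-` — are fatal, with the offending record
#' count reported.
#'
#' @param path Path to a BED6 file of width-1 breakend intervals.
#' @param sample_id Sample label to attach.
#' @return A breakend `GRanges`.
#' @export
read_breakends <- function(path, sample_id = "sample1") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character",
                                         "character"),
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  bad <- df$end <= df$start | df$start < 0L | df$end - df$start != 1L |
    !(df$strand %in% c("+", "-"))
  if (any(bad))
    stop(sum(bad), " invalid breakend record(s) in '", path,
         "' (need 0-based half-open width-1 intervals with strand +/-)")
  read_id <- ifelse(df$name == ".", NA_character_, df$name)
  breakends(chrom = df$chrom, pos = df$start + 1L, strand = df$strand,
            sample_id = sample_id, read_id = read_id)
}

#' Read a blacklist (or any interval set) from BED
#'
#' Thin wrapper over [rtracklayer::import.bed()]; strand-less records come
#' back as `*`, which blacklist filtering treats as strand-blind.
#'
#' @param path Path to a BED3/BED6 file.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "BED")
}
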