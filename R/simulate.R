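#' Simulation configuration for digital break-sequencing data
#'
#' Defines the generative model behind the synthetic test bed: a random
#' genome with planted nuclease sites, per-site cutting efficiencies drawn
#' from a Beta distribution (matching the strongly skewed per-site cutting
#' observed in cell populations), per-cell Bernoulli cutting, uniform
#' Poisson endogenous background breaks, and error-free reads whose
#' 5'-terminal base sits at the break position on both sides of each cut,
#' with Illumina-style names carrying flow-cell coordinates and optionally
#' injected optical duplicates.
#'
#' @param genome_length Chromosome length(s) in bp (vector gives
#'   chr1..chrN). Default 1 Mb.
#' @param gc_content GC fraction of the random genome (default 0.41,
#'   human-like).
#' @param seed Integer master seed; every stage derives its randomness
#'   from it.
#' @param planted List of planted elements, each a list with `seq`
#'   (sequence, plus-strand orientation unless `strand = "-"`), `n`
#'   (copies), `label`, `chemistry` (one of `"asisi_3prime_overhang"`,
#'   `"hindiii_5prime_overhang"`, `"blunt"`, `"cas9"`), and optional
#'   `strand`. Default: 20 AsiSI sites.
#' @param efficiency Either `list(a, b)` for Beta(a, b) per-site cutting
#'   probabilities (default Beta(0.5, 2), strongly skewed) or an explicit
#'   numeric vector, one probability per planted site.
#' @param n_cells Cells in the population (default 5000).
#' @param background_rate Expected endogenous breaks per cell (Poisson;
#'   default 2, the endogenous level of untreated human cells).
#' @param read_length Read length in bp (default 75).
#' @param optical_dup_rate Per-read probability of injecting one optical
#'   duplicate (default 0).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6L, gc_content = 0.41, seed = 1L,
                       planted = list(list(seq = "GCGATCGC", n = 20L,
                                           label = "AsiSI",
                                           chemistry = "asisi_3prime_overhang")),
                       efficiency = list(a = 0.5, b = 2),
                       n_cells = 5000L, background_rate = 2,
                       read_length = 75L, optical_dup_rate = 0) {
  stopifnot(all(genome_length > 0), gc_content >= 0, gc_content <= 1,
            n_cells >= 0, background_rate >= 0, read_length > 0,
            optical_dup_rate >= 0, optical_dup_rate <= 1)
  planted <- lapply(planted, function(p) {
    p$seq <- toupper(p$seq)
    if (grepl("[^ACGT]", p$seq)) stop("planted sequences must be A/C/G/T")
    if (is.null(p$label)) p$label <- p$seq
    if (is.null(p$chemistry)) p$chemistry <- "blunt"
    if (is.null(p$strand)) p$strand <- "+"
    stopifnot(p$chemistry %in% c("asisi_3prime_overhang",
                                 "hindiii_5prime_overhang", "blunt",
                                 "cas9"),
              p$strand %in% c("+", "-"), p$n >= 0)
    p
  })
  if (is.numeric(efficiency)) {
    stopifnot(all(efficiency >= 0), all(efficiency <= 1))
  } else stopifnot(is.list(efficiency), efficiency$a > 0, efficiency$b > 0)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, seed = as.integer(seed),
                 planted = planted, efficiency = efficiency,
                 n_cells = as.integer(n_cells),
                 background_rate = background_rate,
                 read_length = as.integer(read_length),
                 optical_dup_rate = optical_dup_rate),
            class = "sim_config")
}

.random_chrom <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# loci (chrom, start) of exact occurrences of seq in either orientation
.exact_loci <- function(genome, seq) {
  hits <- locate_motif(genome, seq, max_mm = 0L,
                       collapse_palindromic = TRUE)
  # collapse the two orientations of non-palindromic hits to loci
  unique(paste(as.character(GenomicRanges::seqnames(hits)),
               GenomicRanges::start(hits), sep = ":"))
}

#' Generate a random genome with planted nuclease sites
#'
#' Seeded and reproducible. Planted copies are exact and non-overlapping;
#' after planting, the genome is rejection-checked so that no *spurious*
#' exact copy of any planted sequence exists elsewhere (chance matches are
#' scrambled and the check repeated), making planted-truth bookkeeping
#' exact.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (a `DNAStringSet`) and `sites` (a
#'   `GRanges` with metadata columns `label`, `seq`, `chemistry`; strand =
#'   planted orientation).
#' @export
make_genome <- function(cfg) {
  stopifnot(methods::is(cfg, "sim_config"))
  set.seed(cfg$seed)
  lens <- cfg$genome_length
  chroms <- paste0("chr", seq_along(lens))
  seqs <- vapply(lens, .random_chrom, character(1L), gc = cfg$gc_content)
  names(seqs) <- chroms
  # choose non-overlapping planting positions (>= 10 bp apart, away from
  # chromosome ends)
  margin <- 200L
  placed <- data.frame(chrom = character(0L), start = integer(0L),
                       end = integer(0L), label = character(0L),
                       seq = character(0L), chemistry = character(0L),
                       strand = character(0L))
  for (p in cfg$planted) {
    w <- nchar(p$seq)
    genomic_seq <- if (p$strand == "-")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(p$seq))) else p$seq
    k <- 0L
    tries <- 0L
    while (k < p$n) {
      tries <- tries + 1L
      if (tries > 1000L * max(p$n, 1L))
        stop("cannot place planted sites without overlap")
      ci <- sample.int(length(lens), 1L, prob = lens)
      if (lens[ci] < 2L * margin + w) next
      st <- sample.int(lens[ci] - 2L * margin - w, 1L) + margin
      same <- placed$chrom == chroms[ci]
      if (any(st <= placed$end[same] + 10L &
                st + w - 1L >= placed$start[same] - 10L)) next
      substr(seqs[ci], st, st + w - 1L) <- genomic_seq
      placed <- rbind(placed, data.frame(
        chrom = chroms[ci], start = st, end = st + w - 1L,
        label = p$label, seq = p$seq, chemistry = p$chemistry,
        strand = p$strand))
      k <- k + 1L
    }
  }
  # rejection-check: no exact copy of any planted sequence off the planted
  # loci; scramble chance matches and re-check
  for (iter in seq_len(50L)) {
    spurious <- FALSE
    for (p in unique(lapply(cfg$planted, `[`, c("seq", "label")))) {
      loci <- .exact_loci(seqs, p$seq)
      planted_keys <- paste(placed$chrom, placed$start, sep = ":")
      extra <- setdiff(loci, planted_keys)
      for (e in extra) {
        spurious <- TRUE
        parts <- strsplit(e, ":", fixed = TRUE)[[1L]]
        st <- as.integer(parts[2L])
        w <- nchar(p$seq)
        substr(seqs[parts[1L]], st, st + w - 1L) <-
          .random_chrom(w, cfg$gc_content)
      }
    }
    if (!spurious) break
    if (iter == 50L) stop("could not remove spurious planted-motif copies")
  }
  sites <- GenomicRanges::GRanges(
    seqnames = placed$chrom,
    ranges = IRanges::IRanges(placed$start, placed$end),
    strand = placed$strand,
    label = placed$label, seq = placed$seq, chemistry = placed$chemistry)
  o <- order(as.character(GenomicRanges::seqnames(sites)),
             GenomicRanges::start(sites))
  list(genome = Biostrings::DNAStringSet(seqs), sites = sites[o])
}

# the two breakend positions (1-based) of one cut at a site, by chemistry
.chemistry_offsets <- function(start, width, strand, chemistry) {
  switch(chemistry,
    asisi_3prime_overhang = c(plus = start + 5L, minus = start + 2L),
    hindiii_5prime_overhang = c(plus = start + 1L, minus = start + 4L),
    blunt = c(plus = start + width %/% 2L,
              minus = start + width %/% 2L - 1L),
    cas9 = if (strand == "+")
      c(plus = start + 17L, minus = start + 16L)
    else
      c(plus = start + 6L, minus = start + 5L),
    stop("unknown chemistry: ", chemistry))
}

#' Simulate per-cell break events
#'
#' Each site is assigned a cutting efficiency; each cell cuts each site
#' independently with that probability; every cut emits exactly two break
#' ends — one per strand — at the chemistry-determined offsets within the
#' site. Endogenous background breaks arrive as Poisson events
#' (`background_rate` per cell), uniformly positioned, each a blunt cut
#' also emitting two ends. This is the digital model: one labelled break
#' end, one eventual read.
#'
#' @param cfg A [sim_config()].
#' @param sites The `sites` element of [make_genome()].
#' @return An object of class `sim_truth`: list with `sites` (input sites
#'   plus `efficiency` and `planted_cuts` columns), `breakends` (a
#'   `GRanges`, metadata `origin`, `site_id`, `cell`), and `cfg`.
#' @export
simulate_breaks <- function(cfg, sites) {
  stopifnot(methods::is(cfg, "sim_config"), methods::is(sites, "GRanges"))
  set.seed(cfg$seed + 1L)
  n_sites <- length(sites)
  eff <- if (is.numeric(cfg$efficiency)) {
    stopifnot(length(cfg$efficiency) == n_sites)
    cfg$efficiency
  } else stats::rbeta(n_sites, cfg$efficiency$a, cfg$efficiency$b)
  cuts <- stats::rbinom(n_sites, cfg$n_cells, eff)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  st <- GenomicRanges::start(sites)
  w <- GenomicRanges::width(sites)
  strand <- as.character(GenomicRanges::strand(sites))
  recs <- vector("list", n_sites + 1L)
  for (i in seq_len(n_sites)) {
    if (cuts[i] == 0L) next
    off <- .chemistry_offsets(st[i], w[i], strand[i], sites$chemistry[i])
    cells <- sample.int(cfg$n_cells, cuts[i])
    recs[[i]] <- data.frame(
      chrom = chrom[i],
      pos = rep(c(off[["plus"]], off[["minus"]]), each = cuts[i]),
      strand = rep(c("+", "-"), each = cuts[i]),
      origin = sites$label[i], site_id = i, cell = rep(cells, 2L))
  }
  if (cfg$background_rate > 0 && cfg$n_cells > 0L) {
    n_bg <- stats::rpois(1L, cfg$n_cells * cfg$background_rate)
    if (n_bg > 0L) {
      lens <- cfg$genome_length
      ci <- sample.int(length(lens), n_bg, replace = TRUE, prob = lens)
      j <- vapply(ci, function(k) sample.int(lens[k] - 1L, 1L), integer(1L))
      cells <- sample.int(cfg$n_cells, n_bg, replace = TRUE)
      recs[[n_sites + 1L]] <- data.frame(
        chrom = rep(paste0("chr", ci), 2L),
        pos = c(j + 1L, j),
        strand = rep(c("+", "-"), each = n_bg),
        origin = "background", site_id = NA_integer_,
        cell = rep(cells, 2L))
    }
  }
  df <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  bk <- if (is.null(df)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(df$pos, width = 1L),
      strand = df$strand,
      origin = df$origin, site_id = df$site_id, cell = df$cell)
  out_sites <- sites
  S4Vectors::mcols(out_sites)$efficiency <- eff
  S4Vectors::mcols(out_sites)$planted_cuts <- cuts
  structure(list(sites = out_sites, breakends = bk, cfg = cfg),
            class = "sim_truth")
}

# flow-cell geometry: reads sharing (chrom, pos, strand) that land on the
# same lane/tile are placed on a sparse 300-px grid (jitter <= 20) so that
# distinct break events are never within the optical-duplicate radius of
# each other, directly or through an injected duplicate (placed within
# +/- 50 px of its parent).
.assign_flowcell <- function(key, lanes = 1:2,
                             tiles = c(1101:1114, 2101:2114)) {
  n <- length(key)
  lane <- sample(lanes, n, replace = TRUE)
  tile <- sample(tiles, n, replace = TRUE)
  x <- integer(n); y <- integer(n)
  sub <- paste(key, lane, tile, sep = "\r")
  for (ii in split(seq_len(n), sub)) {
    m <- length(ii)
    cells <- sample.int(10000L, m)  # 100 x 100 grid of 300-px cells
    x[ii] <- ((cells - 1L) %% 100L) * 300L +
      sample(0:20, m, replace = TRUE)
    y[ii] <- ((cells - 1L) %/% 100L) * 300L +
      sample(0:20, m, replace = TRUE)
  }
  data.frame(lane = lane, tile = tile, x = x, y = y)
}

#' Emit aligned reads for simulated breakends
#'
#' Every breakend yields one perfectly aligned, error-free read (MAPQ 60,
#' all-M CIGAR) whose 5'-terminal aligned base is the breakend: a
#' plus-strand breakend starts a plus-strand read, a minus-strand breakend
#' ends a minus-strand read. Reads are truncated at contig boundaries.
#' Read names follow the Illumina convention
#' `SIM:<serial>:FCSIM:<lane>:<tile>:<x>:<y>`; optical duplicates are
#' injected at `optical_dup_rate` as same-position reads on the same tile
#' within +/- 50 px.
#'
#' @param truth A [simulate_breaks()] result.
#' @param genome The matching `DNAStringSet`.
#' @param sam_path Output SAM path (default: tempfile).
#' @return A list: `sam` (path), `reads` (a `data.frame` of emitted
#'   records), `dup_read_ids` (names of the injected duplicates).
#' @export
emit_reads <- function(truth, genome,
                       sam_path = tempfile(fileext = ".sam")) {
  stopifnot(methods::is(truth, "sim_truth"))
  genome <- .coerce_genome(genome)
  cfg <- truth$cfg
  set.seed(cfg$seed + 2L)
  bk <- truth$breakends
  n <- length(bk)
  chrom <- as.character(GenomicRanges::seqnames(bk))
  pos <- GenomicRanges::start(bk)
  strand <- as.character(GenomicRanges::strand(bk))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  rl <- cfg$read_length
  rstart <- as.integer(ifelse(strand == "+", pos, pmax(1L, pos - rl + 1L)))
  rend <- as.integer(ifelse(strand == "+", pmin(clen[chrom], pos + rl - 1L),
                            pos))
  fc <- .assign_flowcell(paste(chrom, pos, strand, sep = "\r"))
  reads <- data.frame(chrom = chrom, start = rstart, end = rend,
                      strand = strand, lane = fc$lane, tile = fc$tile,
                      x = fc$x, y = fc$y, is_dup = FALSE)
  if (cfg$optical_dup_rate > 0 && n > 0L) {
    di <- which(stats::runif(n) < cfg$optical_dup_rate)
    if (length(di)) {
      dup <- reads[di, ]
      dup$x <- pmax(0L, dup$x + sample(-50:50, length(di), replace = TRUE))
      dup$y <- pmax(0L, dup$y + sample(-50:50, length(di), replace = TRUE))
      dup$is_dup <- TRUE
      reads <- rbind(reads, dup)
    }
  }
  reads$read_id <- sprintf("SIM:%d:FCSIM:%d:%d:%d:%d",
                           seq_len(nrow(reads)), reads$lane, reads$tile,
                           reads$x, reads$y)
  seqs <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ii <- reads$chrom == ch
    seqs[ii] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(reads$start[ii], reads$end[ii])))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), clen[names(genome)]))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 reads$read_id,
                 ifelse(reads$strand == "-", 16L, 0L),
                 reads$chrom, reads$start, 60L,
                 reads$end - reads$start + 1L,
                 seqs, strrep("I", nchar(seqs)))
  writeLines(c(hdr, rec), sam_path)
  list(sam = sam_path, reads = reads,
       dup_read_ids = reads$read_id[reads$is_dup])
}

#' Run the whole simulator
#'
#' Convenience wrapper: genome, break events, reads. Optionally writes
#' `genome.fa`, `sites.bed`, `truth_breaks.bed` and `reads.sam` under
#' `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory, or `NULL` (default) for in-memory only.
#' @return A list: `genome`, `sites`, `truth`, `emitted` (see
#'   [emit_reads()]), and file `paths` when `dir` is given.
#' @export
simulate_breakseq <- function(cfg, dir = NULL) {
  g <- make_genome(cfg)
  truth <- simulate_breaks(cfg, g$sites)
  paths <- NULL
  sam_path <- if (is.null(dir)) tempfile(fileext = ".sam") else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    file.path(dir, "reads.sam")
  }
  emitted <- emit_reads(truth, g$genome, sam_path)
  if (!is.null(dir)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(g$genome, fa)
    sites_bed <- file.path(dir, "sites.bed")
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(g$sites)),
                 GenomicRanges::start(g$sites) - 1L,
                 GenomicRanges::end(g$sites),
                 g$sites$label, 0L,
                 as.character(GenomicRanges::strand(g$sites))),
      sites_bed, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    truth_bed <- file.path(dir, "truth_breaks.bed")
    write_breakends(truth$breakends, truth_bed)
    paths <- list(genome = fa, sites = sites_bed, truth = truth_bed,
                  sam = sam_path)
  }
  list(genome = g$genome, sites = g$sites, truth = truth,
       emitted = emitted, paths = paths)
}
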