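# Independent oracles and fixture builders, deliberately naive: every
# window is evaluated directly, with none of the package's search
# machinery.

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# brute-force mismatch scan of one strand: Hamming distance of every
# window against `pat` (N = wildcard); windows containing non-ACGT are
# excluded
bf_scan_one <- function(seq, pat, max_mm) {
  s <- strsplit(seq, "")[[1L]]
  p <- strsplit(pat, "")[[1L]]
  L <- length(s); m <- length(p); nw <- L - m + 1L
  if (nw < 1L) return(data.frame(start = integer(0L), n_mm = integer(0L)))
  mm <- integer(nw)
  for (k in seq_len(m))
    if (p[k] != "N") mm <- mm + (s[k:(nw + k - 1L)] != p[k])
  bad <- !(s %in% c("A", "C", "G", "T"))
  cs <- c(0L, cumsum(bad))
  anyN <- (cs[seq_len(nw) + m] - cs[seq_len(nw)]) > 0L
  ok <- mm <= max_mm & !anyN
  data.frame(start = which(ok), n_mm = mm[ok])
}

# both strands; minus-orientation matches are windows matching the
# reverse complement of the pattern
bf_scan <- function(seq, pat, max_mm) {
  f <- bf_scan_one(seq, pat, max_mm)
  r <- bf_scan_one(seq, revcomp_chr(pat), max_mm)
  out <- rbind(
    if (nrow(f)) data.frame(start = f$start, strand = "+", n_mm = f$n_mm),
    if (nrow(r)) data.frame(start = r$start, strand = "-", n_mm = r$n_mm))
  if (is.null(out))
    out <- data.frame(start = integer(0L), strand = character(0L),
                      n_mm = integer(0L))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_df <- function(gr) {
  df <- data.frame(start = GenomicRanges::start(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   n_mm = if (!is.null(gr$n_mismatch)) gr$n_mismatch else
                     gr$n_mismatch_total)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# single-linkage connected components by BFS over the threshold graph
bf_components <- function(x, y, h) {
  n <- length(x)
  adj <- outer(x, x, "-")^2 + outer(y, y, "-")^2 <= h^2
  comp <- rep(NA_integer_, n)
  c_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    c_id <- c_id + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- c_id
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# breakends with synthetic Illumina names carrying given flow-cell fields
fc_breakends <- function(pos, strand = "+", lane = 1L, tile = 1101L,
                         x = 1000L, y = 1000L, sample_id = "s1",
                         chrom = "chr1") {
  n <- length(pos)
  ids <- sprintf("M:%d:FC:%d:%d:%d:%d", seq_len(n),
                 rep_len(lane, n), rep_len(tile, n),
                 rep_len(x, n), rep_len(y, n))
  breakends(chrom = chrom, pos = pos, strand = strand,
            sample_id = sample_id, read_id = ids)
}

# a mutated copy of a spacer: substitutions at the given 1-based
# spacer positions (cycled through the 3 alternative bases)
mutate_at <- function(seq, positions) {
  s <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), s[p])
    s[p] <- alt[1L + (p %% 3L)]
  }
  paste(s, collapse = "")
}
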