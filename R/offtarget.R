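#' Specify a CRISPR guide
#'
#' @param spacer 20-nt spacer sequence (DNA; `U` is mapped to `T`).
#'   Other lengths are accepted but flagged with a message.
#' @param pam PAM pattern, `N` acting as a wildcard (canonical SpCas9
#'   `"NGG"`).
#' @param name Guide label.
#' @return An object of class `guide_spec`.
#' @examples
#' guide_spec("GAGTCCGAGCAGAAGAAGAA", name = "EMX1")
#' @export
guide_spec <- function(spacer, pam = "NGG", name = "guide") {
  spacer <- chartr("Uu", "Tt", toupper(spacer))
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over A/C/G/T (or U)")
  pam <- toupper(pam)
  if (grepl("[^ACGTN]", pam)) stop("PAM pattern must be over A/C/G/T/N")
  if (nchar(spacer) != 20L)
    message("non-standard spacer length ", nchar(spacer))
  structure(list(spacer = spacer, pam = pam, name = name),
            class = "guide_spec")
}

#' Enumerate candidate off-target sites for a guide
#'
#' Finds every window on both strands whose combined mismatch count against
#' the spacer and the canonical PAM is at most `max_total_mm`. The `N` of
#' the PAM matches anything and never counts; each non-matching base at the
#' fixed PAM positions adds one mismatch, as does each spacer mismatch (no
#' indels/bulges). Each candidate carries its total and seed-region
#' mismatch counts — the seed being the 12 spacer nucleotides proximal to
#' the PAM — and its expected 2-bp cut window (see [crispr_cut_window()]).
#' Windows containing ambiguity codes are excluded.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param guide A [guide_spec()].
#' @param max_total_mm Combined spacer+PAM mismatch budget (the discovery
#'   pipeline uses 6 and 7; other values are accepted with a message).
#' @return An oriented `GRanges` of protospacer+PAM windows with metadata
#'   columns `site_seq` (spacer-then-PAM orientation), `n_mismatch_total`,
#'   `n_mismatch_seed`, and a parallel `GRanges` column `cut` (the 2-bp cut
#'   window).
#' @export
enumerate_candidates <- function(genome, guide, max_total_mm = 6L) {
  stopifnot(methods::is(guide, "guide_spec"))
  genome <- .coerce_genome(genome)
  if (!max_total_mm %in% c(6L, 7L))
    message("non-standard mismatch budget ", max_total_mm)
  pattern <- paste0(guide$spacer, guide$pam)
  plen <- nchar(pattern)
  slen <- nchar(guide$spacer)
  if (max_total_mm >= plen) stop("max_total_mm must be < site length")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  res <- lapply(seq_along(genome), function(i) {
    chromseq <- genome[[i]]
    fwd <- .scan_one(chromseq, pattern, max_total_mm)
    rev <- .scan_one(chromseq, rc, max_total_mm)
    rev_seq <- if (nrow(rev)) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rev$seq))) else character(0L)
    data.frame(chrom = rep(names(genome)[i], nrow(fwd) + nrow(rev)),
               start = c(fwd$start, rev$start),
               strand = rep(c("+", "-"), c(nrow(fwd), nrow(rev))),
               site_seq = c(fwd$seq, rev_seq),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  seed_pos <- (slen - 11L):slen  # 12 nt proximal to the PAM
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, width = plen),
    strand = df$strand,
    site_seq = df$site_seq,
    n_mismatch_total = .pattern_mismatches(df$site_seq, pattern),
    n_mismatch_seed = .pattern_mismatches(df$site_seq, pattern, seed_pos))
  gr <- sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$cut <- crispr_cut_window(gr, nchar(guide$pam))
  gr
}

#' Filter candidates on seed-region mismatches
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param max_seed_mm Maximum mismatches tolerated in the 12-nt
#'   PAM-proximal seed.
#' @return The retained candidates.
#' @export
seed_filter <- function(candidates, max_seed_mm) {
  stopifnot(methods::is(candidates, "GRanges"))
  candidates[candidates$n_mismatch_seed <= max_seed_mm]
}

#' The 32-condition off-target filter grid
#'
#' Candidate sets built at total mismatch budgets {6, 7}, seed budgets
#' {2, 3, 4, 5}, and recurrence thresholds n in {2, 3, 4, 5} under which a
#' site with more than n total mismatches needs more than one overlapping
#' break to be retained: 2 x 4 x 4 = 32 conditions.
#'
#' @param max_total_mm,max_seed_mm,recurrence_n Grid axes.
#' @return A `data.frame` with columns `condition_id`, `max_total_mm`,
#'   `max_seed_mm`, `recurrence_n`.
#' @export
filter_grid <- function(max_total_mm = c(6L, 7L), max_seed_mm = 2:5,
                        recurrence_n = 2:5) {
  g <- expand.grid(max_total_mm = as.integer(max_total_mm),
                   max_seed_mm = as.integer(max_seed_mm),
                   recurrence_n = as.integer(recurrence_n),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$max_total_mm, g$max_seed_mm, g$recurrence_n), ,
         drop = FALSE]
  data.frame(condition_id = seq_len(nrow(g)), g, row.names = NULL)
}

#' Build the seed-filtered candidate sets
#'
#' Enumerates candidates once at the largest total budget, then derives one
#' set per (total, seed) combination — with the default axes, 8 sets,
#' mirroring the 8 filtered site files of the discovery pipeline.
#'
#' @param genome,guide As in [enumerate_candidates()].
#' @param max_total_mm,max_seed_mm Axes of the candidate grid.
#' @return A named list of `GRanges` (`"mm<total>_seed<seed>"`).
#' @export
build_candidate_sets <- function(genome, guide, max_total_mm = c(6L, 7L),
                                 max_seed_mm = 2:5) {
  all <- enumerate_candidates(genome, guide, max(max_total_mm))
  sets <- list()
  for (tt in max_total_mm) for (ss in max_seed_mm)
    sets[[sprintf("mm%d_seed%d", tt, ss)]] <-
      seed_filter(all[all$n_mismatch_total <= tt], ss)
  sets
}

#' Call off-target sites under one filter condition
#'
#' Counts breakends (strand-blind — both ends of a blunt cut fall in the
#' window) inside each candidate's 2-bp cut window, then applies the
#' recurrence rule: a candidate is retained when it has at least one break
#' and either carries at most `recurrence_n` total mismatches or has more
#' than one break. High-mismatch candidates thus need independent break
#' recurrence to be believed.
#'
#' @param candidates Seed-filtered candidates (already consistent with the
#'   condition's mismatch budgets).
#' @param bk Breakend `GRanges` for one sample.
#' @param condition One row of [filter_grid()] (or a list with
#'   `recurrence_n`).
#' @return The called candidates with an `n_breaks` metadata column.
#' @export
call_offtargets <- function(candidates, bk, condition) {
  stopifnot(methods::is(candidates, "GRanges"), methods::is(bk, "GRanges"))
  n <- GenomicRanges::countOverlaps(candidates$cut, bk,
                                    ignore.strand = TRUE)
  keep <- n >= 1L &
    (candidates$n_mismatch_total <= condition$recurrence_n | n > 1L)
  out <- candidates[keep]
  S4Vectors::mcols(out)$n_breaks <- n[keep]
  out
}

#' Run the full filter matrix over samples
#'
#' Applies every condition of the grid to every sample's breakends,
#' producing one call set per (sample, condition) — 32 per sample with the
#' default grid.
#'
#' @param candidate_sets Named list from [build_candidate_sets()].
#' @param breakends_by_sample Named list of breakend `GRanges`.
#' @param grid A [filter_grid()].
#' @return An object of class `offtarget_matrix`: list with the `grid` and
#'   `calls`, where `calls[[sample]][[condition_id]]` is a called
#'   `GRanges`.
#' @export
run_filter_matrix <- function(candidate_sets, breakends_by_sample,
                              grid = filter_grid()) {
  stopifnot(is.list(candidate_sets), is.list(breakends_by_sample),
            !is.null(names(breakends_by_sample)))
  calls <- lapply(breakends_by_sample, function(bk) {
    lapply(seq_len(nrow(grid)), function(i) {
      cond <- grid[i, ]
      set_name <- sprintf("mm%d_seed%d", cond$max_total_mm,
                          cond$max_seed_mm)
      if (is.null(candidate_sets[[set_name]]))
        stop("candidate set '", set_name, "' missing")
      call_offtargets(candidate_sets[[set_name]], bk, cond)
    })
  })
  structure(list(grid = grid, calls = calls), class = "offtarget_matrix")
}

.site_keys <- function(gr) {
  unique(paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr),
               as.character(GenomicRanges::strand(gr)), sep = ":"))
}

# distinct site keys per condition, combined across a matrix's samples
.condition_sites <- function(m, combine) {
  n_cond <- nrow(m$grid)
  lapply(seq_len(n_cond), function(i) {
    per_sample <- lapply(m$calls, function(s) .site_keys(s[[i]]))
    if (combine == "union") unique(unlist(per_sample)) else
      Reduce(intersect, per_sample)
  })
}

#' Empirical FDR per filter condition
#'
#' True-positive off-targets are the distinct sites called across the
#' treated (nuclease-exposed) sample group; false positives are the
#' distinct sites called across the untreated control group, where any
#' call must be background. Per condition: `fdr = F / (T + F)` (0 when
#' both are 0); the alternative `F / T` is available.
#'
#' @param treated,control `offtarget_matrix` objects built on the same
#'   grid.
#' @param combine How calls are combined across replicate samples within a
#'   group: `"union"` (default) or `"intersection"`.
#' @param formula `"F/(T+F)"` (default) or `"F/T"`.
#' @return The grid `data.frame` extended with `n_treated_sites`,
#'   `n_control_sites`, `fdr`.
#' @export
fdr_by_condition <- function(treated, control,
                             combine = c("union", "intersection"),
                             formula = c("F/(T+F)", "F/T")) {
  stopifnot(methods::is(treated, "offtarget_matrix"),
            methods::is(control, "offtarget_matrix"))
  if (!identical(treated$grid, control$grid))
    stop("treated and control matrices use different grids")
  combine <- match.arg(combine)
  formula <- match.arg(formula)
  t_sites <- .condition_sites(treated, combine)
  c_sites <- .condition_sites(control, combine)
  out <- treated$grid
  out$n_treated_sites <- lengths(t_sites)
  out$n_control_sites <- lengths(c_sites)
  T_ <- out$n_treated_sites
  F_ <- out$n_control_sites
  out$fdr <- if (formula == "F/(T+F)") {
    ifelse(T_ + F_ == 0L, 0, F_ / (T_ + F_))
  } else {
    ifelse(T_ == 0L, ifelse(F_ == 0L, 0, Inf), F_ / T_)
  }
  out
}

#' Select the filter condition maximising discovery power
#'
#' Among conditions with `fdr <= alpha`, returns the one with the largest
#' treated-site yield; ties go to the stricter condition (smaller total
#' mismatch budget, then seed budget, then recurrence threshold). If no
#' condition meets `alpha`, the minimal-FDR condition is returned with a
#' warning.
#'
#' @param fdr_table Output of [fdr_by_condition()].
#' @param alpha FDR ceiling (default 0.05).
#' @return The selected row of `fdr_table`.
#' @export
select_condition <- function(fdr_table, alpha = 0.05) {
  stopifnot(is.data.frame(fdr_table), nrow(fdr_table) > 0L)
  ok <- fdr_table[fdr_table$fdr <= alpha, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no condition meets fdr <= ", alpha,
            "; returning the minimal-FDR condition")
    ok <- fdr_table[fdr_table$fdr == min(fdr_table$fdr), , drop = FALSE]
    o <- order(ok$max_total_mm, ok$max_seed_mm, ok$recurrence_n)
    return(ok[o[1L], , drop = FALSE])
  }
  o <- order(-ok$n_treated_sites, ok$max_total_mm, ok$max_seed_mm,
             ok$recurrence_n)
  ok[o[1L], , drop = FALSE]
}

#' Mismatch-annotated alignment of called off-targets
#'
#' Text rendering of each called site against the guide: matching bases as
#' dots, mismatches as the offending base, PAM separated by a space.
#'
#' @param calls Called candidates (with `site_seq`).
#' @param guide The [guide_spec()].
#' @return A character vector, one line per site.
#' @export
format_offtarget_alignment <- function(calls, guide) {
  stopifnot(methods::is(calls, "GRanges"), methods::is(guide, "guide_spec"))
  pattern <- paste0(guide$spacer, guide$pam)
  pat <- strsplit(pattern, "")[[1L]]
  slen <- nchar(guide$spacer)
  vapply(seq_along(calls), function(i) {
    s <- strsplit(calls$site_seq[i], "")[[1L]]
    shown <- ifelse(pat != "N" & s == pat, ".", s)
    sprintf("%s:%d:%s  %s %s  mm=%d seed_mm=%d",
            as.character(GenomicRanges::seqnames(calls[i])),
            GenomicRanges::start(calls[i]),
            as.character(GenomicRanges::strand(calls[i])),
            paste(shown[seq_len(slen)], collapse = ""),
            paste(shown[(slen + 1L):length(shown)], collapse = ""),
            calls$n_mismatch_total[i], calls$n_mismatch_seed[i])
  }, character(1L))
}
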