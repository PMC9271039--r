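emx1 <- "GAGTCCGAGCAGAAGAAGAA"

# a small genome with the on-target and controlled variants planted
planted_guide_genome <- function(variants, seed = 1, len = 20000L,
                                 pam = "AGG") {
  planted <- lapply(seq_along(variants), function(i)
    list(seq = paste0(variants[[i]], pam), n = 1L,
         label = paste0("v", i), chemistry = "cas9",
         strand = if (i %% 2L) "+" else "-"))
  cfg <- sim_config(genome_length = len, seed = seed, planted = planted,
                    n_cells = 0L, background_rate = 0)
  make_genome(cfg)
}

test_that("guide specification normalises RNA input and validates", {
  g <- guide_spec("GAGUCCGAGCAGAAGAAGAA")
  expect_identical(g$spacer, emx1)
  expect_error(guide_spec("GAGTCCGAGCAGAAGAAGAX"), "A/C/G/T")
  expect_error(guide_spec(emx1, pam = "NGQ"), "PAM")
  expect_message(guide_spec("ACGTACGT"), "non-standard")
})

test_that("candidate mismatch accounting covers spacer, PAM and seed", {
  g <- guide_spec(emx1)
  pad <- "TTTTTTTTTT"
  genome <- c(chr1 = paste0(pad, emx1, "AGG", pad))
  cand <- enumerate_candidates(genome, g, 6)
  on <- cand[cand$n_mismatch_total == 0L]
  expect_identical(length(on), 1L)
  expect_identical(on$n_mismatch_seed, 0L)
  expect_identical(GenomicRanges::start(on), 11L)

  # PAM "ATT": the N is free, each non-G at the GG positions adds one
  genome2 <- c(chr1 = paste0(pad, emx1, "ATT", pad))
  cand2 <- enumerate_candidates(genome2, g, 6)
  expect_identical(min(cand2$n_mismatch_total), 2L)

  # a seed mismatch (spacer position 15) counts in both tallies
  sp <- mutate_at(emx1, 15L)
  cand3 <- enumerate_candidates(c(chr1 = paste0(pad, sp, "CGG", pad)), g, 6)
  expect_identical(min(cand3$n_mismatch_total), 1L)
  expect_identical(cand3$n_mismatch_seed[which.min(cand3$n_mismatch_total)],
                   1L)
  # a PAM-distal mismatch (position 3) leaves the seed clean
  sp2 <- mutate_at(emx1, 3L)
  cand4 <- enumerate_candidates(c(chr1 = paste0(pad, sp2, "GGG", pad)), g, 6)
  i <- which.min(cand4$n_mismatch_total)
  expect_identical(cand4$n_mismatch_total[i], 1L)
  expect_identical(cand4$n_mismatch_seed[i], 0L)
})

test_that("candidate enumeration equals the brute-force window scan", {
  g <- guide_spec(emx1)
  pattern <- paste0(emx1, "NGG")
  for (seed in 1:8) {
    set.seed(seed)
    gen <- random_seq(8000L)
    mm <- 1L + seed %% 3L
    got <- enumerate_candidates(c(chr1 = gen), g, mm)
    want <- bf_scan(gen, pattern, mm)
    expect_identical(site_df(got), want, info = paste("seed", seed))
  }
})

test_that("seed filtering and the candidate sets behave as a grid", {
  g <- guide_spec(emx1)
  variants <- list(emx1, mutate_at(emx1, c(1, 2)),          # distal only
                   mutate_at(emx1, c(12, 15, 18)),          # 3 in seed
                   mutate_at(emx1, c(9, 11, 13, 16, 19)))   # 5 in seed
  gg <- planted_guide_genome(variants, seed = 5)
  cand <- enumerate_candidates(gg$genome, g, 7)
  expect_identical(length(seed_filter(cand, 5)), length(cand))
  expect_lt(length(seed_filter(cand, 2)), length(cand))
  expect_true(all(seed_filter(cand, 2)$n_mismatch_seed <= 2L))

  sets <- build_candidate_sets(gg$genome, g)
  expect_identical(length(sets), 8L)
  expect_identical(names(sets)[1L], "mm6_seed2")
  # relaxing either axis never loses candidates
  expect_lte(length(sets$mm6_seed2), length(sets$mm7_seed2))
  expect_lte(length(sets$mm6_seed2), length(sets$mm6_seed3))
})

test_that("the filter grid enumerates exactly 32 conditions", {
  grid <- filter_grid()
  expect_identical(nrow(grid), 32L)
  expect_identical(sort(unique(grid$max_total_mm)), c(6L, 7L))
  expect_identical(sort(unique(grid$max_seed_mm)), 2:5)
  expect_identical(sort(unique(grid$recurrence_n)), 2:5)
  expect_false(anyDuplicated(grid[, -1L]) > 0L)
})

test_that("the recurrence rule keeps high-mismatch sites only if recurrent", {
  cand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 123), "+",
                                 site_seq = paste0(emx1, "AGG"),
                                 n_mismatch_total = 6L,
                                 n_mismatch_seed = 2L)
  S4Vectors::mcols(cand)$cut <- crispr_cut_window(cand)
  cond <- list(recurrence_n = 5L)
  one_break <- breakends("chr1", 117L, "+")
  two_breaks <- breakends("chr1", c(117L, 118L), c("+", "-"))
  expect_identical(length(call_offtargets(cand, one_break, cond)), 0L)
  called <- call_offtargets(cand, two_breaks, cond)
  expect_identical(length(called), 1L)
  expect_identical(called$n_breaks, 2L)
  # low-mismatch sites survive on a single break
  cand$n_mismatch_total <- 2L
  expect_identical(
    length(call_offtargets(cand, one_break, list(recurrence_n = 2L))), 1L)
  # no break, no call
  expect_identical(
    length(call_offtargets(cand, breakends("chr1", 5L, "+"), cond)), 0L)
})

test_that("call sets are monotone along every relaxation axis", {
  set.seed(17)
  g <- guide_spec(emx1)
  variants <- list(emx1,
                   mutate_at(emx1, 2),
                   mutate_at(emx1, c(1, 5, 12)),
                   mutate_at(emx1, c(3, 9, 13, 16)),
                   mutate_at(emx1, c(1, 4, 10, 14, 17)),
                   mutate_at(emx1, c(2, 6, 11, 15, 18, 20)))
  gg <- planted_guide_genome(variants, seed = 23, len = 40000L)
  sets <- build_candidate_sets(gg$genome, g)
  # one or two breaks in each planted cut window
  all_cand <- enumerate_candidates(gg$genome, g, 7)
  cw <- all_cand$cut
  pos <- GenomicRanges::start(cw)
  nb <- 1L + (seq_along(pos) %% 2L)
  bk <- breakends(as.character(GenomicRanges::seqnames(cw)),
                  rep(pos, nb), "+")
  grid <- filter_grid()
  m <- run_filter_matrix(sets, list(s1 = bk), grid)
  keys <- lapply(m$calls$s1, function(g2)
    paste(GenomicRanges::seqnames(g2), GenomicRanges::start(g2),
          GenomicRanges::strand(g2)))
  relax <- function(cond, field) {
    vals <- sort(unique(grid[[field]]))
    nxt <- vals[vals > cond[[field]]][1L]
    if (is.na(nxt)) return(NULL)
    cond[[field]] <- nxt
    which(grid$max_total_mm == cond$max_total_mm &
            grid$max_seed_mm == cond$max_seed_mm &
            grid$recurrence_n == cond$recurrence_n)
  }
  for (i in seq_len(nrow(grid))) {
    for (field in c("max_total_mm", "max_seed_mm", "recurrence_n")) {
      j <- relax(grid[i, ], field)
      if (!is.null(j))
        expect_true(all(keys[[i]] %in% keys[[j]]),
                    info = sprintf("condition %d axis %s", i, field))
    }
  }
  # empty breakends give 32 empty call sets
  m0 <- run_filter_matrix(sets, list(s1 = bk[0]), grid)
  expect_true(all(vapply(m0$calls$s1, length, integer(1L)) == 0L))
})

test_that("the on-target with a break is called under every condition", {
  g <- guide_spec(emx1)
  gg <- planted_guide_genome(list(emx1), seed = 31)
  sets <- build_candidate_sets(gg$genome, g)
  on_cut <- crispr_cut_window(gg$sites)
  bk <- breakends(as.character(GenomicRanges::seqnames(on_cut)),
                  GenomicRanges::start(on_cut), "+")
  m <- run_filter_matrix(sets, list(s1 = bk))
  expect_true(all(vapply(m$calls$s1, function(x)
    any(x$n_mismatch_total == 0L), logical(1L))))
})

test_that("the empirical FDR formula behaves at its boundaries", {
  g <- guide_spec(emx1)
  gg <- planted_guide_genome(list(emx1, mutate_at(emx1, c(2, 4))),
                             seed = 41)
  sets <- build_candidate_sets(gg$genome, g)
  cw <- enumerate_candidates(gg$genome, g, 7)$cut
  bk <- breakends(as.character(GenomicRanges::seqnames(cw)),
                  rep(GenomicRanges::start(cw), 2L), "+")
  none <- bk[0]
  treated <- run_filter_matrix(sets, list(t1 = bk))
  control0 <- run_filter_matrix(sets, list(c1 = none))
  tab <- fdr_by_condition(treated, control0)
  expect_true(all(tab$fdr == 0))
  expect_true(all(tab$n_treated_sites > 0L))
  # T = 0, F > 0 -> fdr 1
  tab2 <- fdr_by_condition(control0, treated)
  expect_true(all(tab2$fdr == 1))
  # control identical to treated -> fdr exactly 1/2 wherever T = F > 0
  same <- run_filter_matrix(sets, list(c1 = bk))
  tab3 <- fdr_by_condition(treated, same)
  expect_true(all(tab3$fdr == 0.5))
  # the alternative F/T formula is exposed
  tab4 <- fdr_by_condition(treated, same, formula = "F/T")
  expect_true(all(tab4$fdr == 1))
})

test_that("condition selection maximises yield under the FDR ceiling", {
  tab <- filter_grid()
  tab$n_treated_sites <- 10L
  tab$n_control_sites <- 0L
  tab$fdr <- 0.2
  tab$fdr[tab$condition_id == 5L] <- 0.01
  sel <- select_condition(tab, alpha = 0.05)
  expect_identical(sel$condition_id, 5L)
  # two qualifying conditions with equal yield: the stricter wins
  tab$fdr[tab$condition_id == 6L] <- 0.04
  sel2 <- select_condition(tab, alpha = 0.05)
  expect_identical(sel2$condition_id, 5L)
  # larger yield wins over strictness
  tab$n_treated_sites[tab$condition_id == 6L] <- 20L
  expect_identical(select_condition(tab, 0.05)$condition_id, 6L)
  # nothing qualifies: minimal-FDR fallback with a warning
  tab$fdr <- 0.3
  tab$fdr[10L] <- 0.21
  expect_warning(sel3 <- select_condition(tab, 0.05), "no condition")
  expect_identical(sel3$condition_id, 10L)
})

test_that("alignment rendering marks mismatches against the guide", {
  g <- guide_spec(emx1)
  cand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 123), "+",
                                 site_seq = paste0(mutate_at(emx1, 4), "TGG"),
                                 n_mismatch_total = 1L, n_mismatch_seed = 0L)
  txt <- format_offtarget_alignment(cand, g)
  expect_match(txt, "^chr1:101:\\+")
  expect_match(txt, "mm=1")
  # 19 spacer dots, one substitution
  spacer_part <- sub("^\\S+  (\\S+) .*$", "\\1", txt)
  expect_identical(nchar(gsub("[^.]", "", spacer_part)), 19L)
})
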