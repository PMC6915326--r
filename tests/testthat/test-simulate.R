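test_that("simulation configs validate their probabilities and geometry", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(motif_prevalence = 1.2), "motif_prevalence")
  expect_error(sim_config(dist_lo = 50, dist_hi = 20), "dist_lo")
  expect_error(sim_config(dist_hi = 120, utr_len_range = c(100, 300)),
               "long enough")
})

test_that("generators are fully deterministic in (config, seed)", {
  cfg <- sim_config(seed = 9, n_rp = 20, n_nonrp = 20)
  a <- gen_transcripts(cfg); b <- gen_transcripts(cfg)
  expect_identical(a, b)
  expect_identical(gen_structures(a$transcripts, a$truth),
                   gen_structures(b$transcripts, b$truth))
  g1 <- gen_depletion_groups(seed = 4); g2 <- gen_depletion_groups(seed = 4)
  expect_identical(g1, g2)
  ab1 <- gen_biased_abundance(g1$index_by_rp, beta = 3, seed = 8)
  ab2 <- gen_biased_abundance(g1$index_by_rp, beta = 3, seed = 8)
  expect_identical(ab1, ab2)
  # distinct substreams: another generator name does not disturb the stream
  expect_false(identical(substream_seed(9, "transcripts"),
                         substream_seed(9, "clip")))
})

test_that("planted transcripts carry the motif exactly where the truth table says", {
  cfg <- sim_config(seed = 21, n_rp = 100, n_nonrp = 50)
  tr <- gen_transcripts(cfg)
  tt <- tr$truth
  expect_equal(nrow(tt), 150L)
  for (i in which(tt$has_motif)) {
    seq <- tr$transcripts[[i]]$utr5_seq
    expect_equal(substr(seq, tt$planted_start[i] + 1, tt$planted_start[i] + 8),
                 tt$planted_seq[i])
    expect_equal(tt$utr_length[i] - (tt$planted_start[i] + 8),
                 tt$planted_dist[i])
    expect_true(tt$planted_dist[i] >= 20 && tt$planted_dist[i] <= 80)
  }
  # purine-only background: scanning recovers the planted labels with no error
  hits <- best_cuic_hits(tr$transcripts)
  expect_identical(hits$is_cuic, tt$has_motif)
  m <- tt$has_motif
  expect_equal(hits$start[m], tt$planted_start[m])
})

test_that("prevalence extremes and recovery behave as planted", {
  all_in <- gen_transcripts(sim_config(seed = 2, n_rp = 30, n_nonrp = 5,
                                       motif_prevalence = 1))
  hits <- best_cuic_hits(all_in$transcripts)
  expect_true(all(hits$is_cuic[all_in$truth$is_rp]))
  none <- gen_transcripts(sim_config(seed = 2, n_rp = 30, n_nonrp = 5,
                                     motif_prevalence = 0))
  expect_false(any(best_cuic_hits(none$transcripts)$is_cuic))
  # prevalence 0.7 recovered within 3 binomial SE at n_rp = 200
  tr <- gen_transcripts(sim_config(seed = 1, n_rp = 200, n_nonrp = 0))
  got <- mean(best_cuic_hits(tr$transcripts)$is_cuic)
  se <- sqrt(0.7 * 0.3 / 200)
  expect_lt(abs(got - 0.7), 3 * se)
})

test_that("uniform background exercises false-positive handling", {
  tr <- gen_transcripts(sim_config(seed = 6, n_rp = 40, n_nonrp = 40,
                                   background = "uniform"))
  hits <- best_cuic_hits(tr$transcripts)
  # spurious matches can appear, but planted motifs are still found
  m <- tr$truth$has_motif
  expect_true(all(hits$is_cuic[m]))
})

test_that("clip generator hits the planted overlap probability in expectation", {
  cfg <- sim_config(seed = 15, n_rp = 60, n_nonrp = 0)
  tr <- gen_transcripts(cfg)
  tt <- tr$truth[tr$truth$has_motif, ]
  regions <- cbind(data.frame(transcript_id = tt$transcript_id),
                   cuic_region(tt$planted_start, tt$planted_start + 8,
                               tt$utr_length),
                   data.frame(utr_length = tt$utr_length))
  cl <- gen_clip(c(hi = 1, lo = 0, mid = 0.5), regions, n_clusters = 80,
                 seed = 15)
  sc <- specificity_scores(cl$clusters, regions, tt$transcript_id)
  expect_equal(sc$score[sc$rbp == "hi"], 1)
  expect_equal(sc$score[sc$rbp == "lo"], 0)
  expect_lt(abs(sc$score[sc$rbp == "mid"] - 0.5),
            3 * sqrt(0.5 * 0.5 / 80) + 0.05)
})

test_that("toy complexes require an integral interface count", {
  expect_error(gen_toy_complex(10, 0.35), "integer")
  tc <- gen_toy_complex(10, 0)
  expect_equal(interface_index(tc$peptide, tc$rna, mode = "contact")$index, 0)
})

test_that("biased abundance is null at beta 0 and strongly biased at large beta", {
  set.seed(77)
  folds <- numeric(30); ps <- numeric(30)
  for (r in 1:30) {
    g <- gen_depletion_groups(fold = 1, seed = 1000 + r)
    ab0 <- gen_biased_abundance(g$index_by_rp, beta = 0, seed = 2000 + r)
    b <- tryCatch(suppressWarnings(abundance_bias(g$index_by_rp, ab0$fpkm)),
                  error = function(e) NULL)
    folds[r] <- if (is.null(b)) NA else b$fold_depletion
    ps[r] <- if (is.null(b)) NA else b$ks_p
  }
  # null: log fold-depletion centred near 0, KS p roughly uniform
  expect_lt(abs(mean(log(folds), na.rm = TRUE)), 0.35)
  expect_gt(mean(ps > 0.05, na.rm = TRUE), 0.8)
  # strong bias separates the group means
  g <- gen_depletion_groups(fold = 1, seed = 555)
  abb <- gen_biased_abundance(g$index_by_rp, beta = 12, seed = 556)
  # a strong enough bias can empty the abundant group of high-index proteins,
  # which abundance_bias legitimately flags as an infinite fold
  bb <- suppressWarnings(abundance_bias(g$index_by_rp, abb$fpkm))
  expect_lt(bb$group_hi_mean, bb$group_lo_mean)
  expect_lt(bb$ks_p, 0.05)
})

test_that("depletion groups plant the requested expected fold", {
  g <- gen_depletion_groups(n_rp = 80, n_abundant = 30, high_frac = 0.25,
                            fold = 5, seed = 3)
  expect_equal(g$truth$q_non_abundant / g$truth$q_abundant, 5)
  expect_equal(30 * g$truth$q_abundant + 50 * g$truth$q_non_abundant, 80 * 0.25)
  expect_length(g$abundant, 30)
  expect_error(gen_depletion_groups(high_frac = 0.9, fold = 10), "too large")
})

test_that("FASTA and annotation round-trip preserves transcript records", {
  cfg <- sim_config(seed = 12, n_rp = 6, n_nonrp = 4)
  tr <- gen_transcripts(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(tr$transcripts, fa)
  annot <- data.frame(
    transcript_id = tr$truth$transcript_id,
    gene_symbol = tr$truth$transcript_id,
    is_rp = as.integer(tr$truth$is_rp))
  back <- read_utr_fasta(fa, annot)
  expect_length(back, 10L)
  for (i in seq_along(back)) {
    expect_equal(toupper(back[[i]]$utr5_seq),
                 toupper(tr$transcripts[[i]]$utr5_seq))
    expect_equal(back[[i]]$is_rp, tr$transcripts[[i]]$is_rp)
  }
})
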