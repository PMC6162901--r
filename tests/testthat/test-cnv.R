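test_that("bin depth counting follows the overlap convention", {
  bins <- make_bins(0, 200, 50)
  none <- bin_depths(data.frame(pos = numeric(0), cigar = character(0)), bins)
  expect_equal(none, rep(0L, 4))
  # one read spanning the boundary between bins 1 and 2 increments both
  one <- data.frame(pos = 40, cigar = "30M", stringsAsFactors = FALSE)
  expect_equal(bin_depths(one, bins), c(1L, 1L, 0L, 0L))
  # start-position counting increments only the first
  expect_equal(bin_depths(one, bins, count = "start"), c(1L, 0L, 0L, 0L))
})

test_that("uniform simulated coverage gives near-Poisson bin counts", {
  model <- test_model()
  reads <- test_reads()
  span <- gene_exon_span(model, as.character(12:15))
  bins <- make_bins(span[1], span[1] + 400, 50)
  gene_reads <- reads[startsWith(reads$origin, "gene"), ]
  aln <- data.frame(pos = gene_reads$true_pos,
                    cigar = "115M", stringsAsFactors = FALSE)
  counts <- bin_depths(aln, bins)
  # expected overlapping reads per 50 bp bin at depth 250 (gene block holds
  # half of it): depth * (bin + read - 1) / read
  lambda <- 250 * (50 + 115 - 1) / 115
  expect_true(all(abs(counts - lambda) < 4 * sqrt(lambda)))
})

test_that("two-stage median normalization matches hand-computed medians", {
  # constant matrix -> all ones
  dm <- depth_matrix(make_bins(0, 500, 50), matrix(500, 10, 5))
  expect_true(all(normalize_depths(dm)$normalized == 1))
  # a sample at global 2x depth is scale-normalized away in stage one
  raw <- matrix(500, 10, 5); raw[, 3] <- 1000
  dm2 <- normalize_depths(depth_matrix(make_bins(0, 500, 50), raw))
  expect_true(all(dm2$normalized[, 3] == 1))
  # hand-computed 5x10 case: one sample at 0.75 in two bins
  raw3 <- matrix(400, 5, 10)
  raw3[2:3, 1] <- 300
  dm3 <- normalize_depths(depth_matrix(make_bins(0, 250, 50), raw3))
  # stage 1: sample 1 median 400 -> bins 2:3 become 0.75; stage 2 bin
  # medians are 1 (9 of 10 samples at 1), so values persist
  expect_equal(unname(dm3$normalized[2:3, 1]), c(0.75, 0.75))
  expect_equal(unname(dm3$normalized[1, 1]), 1)
  expect_true(all(dm3$normalized[, 2:10] == 1))
  # invariant: per-bin median of the final matrix is 1
  expect_equal(unname(apply(dm3$normalized, 1, median)), rep(1, 5))
})

test_that("zero-median bins are masked rather than propagating NaN", {
  raw <- matrix(500, 6, 5)
  raw[4, ] <- 0
  expect_message(dm <- normalize_depths(depth_matrix(make_bins(0, 300, 50),
                                                     raw)), "masking")
  expect_equal(attr(dm, "masked_bins"), 4L)
  expect_true(all(is.na(dm$normalized[4, ])))
  expect_true(all(is.finite(dm$normalized[-4, ])))
})

test_that("the HMM calls the derived single-event examples", {
  # flat row: negative
  flat <- call_cnv(rep(1, 20), baseline = 4, sigma = 0.05)
  expect_equal(flat$status, "NEGATIVE")
  expect_equal(flat$delta, 0)
  # baseline 4, one exon at 0.75 -> single-copy deletion over those bins
  row <- rep(1, 20); row[8:11] <- 0.75
  del <- call_cnv(row, baseline = 4, sigma = 0.05)
  expect_equal(nrow(del), 1)
  expect_equal(del$called_copy, 3)
  expect_equal(c(del$bin_from, del$bin_to), c(8, 11))
  expect_equal(del$status, "CALL")
  # baseline 2, bins at 0.5 -> copy 1
  row2 <- rep(1, 12); row2[4:6] <- 0.5
  del2 <- call_cnv(row2, baseline = 2, sigma = 0.05)
  expect_equal(del2$called_copy, 1)
  expect_equal(del2$status, "CALL")
  # duplication side
  row3 <- rep(1, 12); row3[4:6] <- 1.25
  dup <- call_cnv(row3, baseline = 4, sigma = 0.05)
  expect_equal(dup$called_copy, 5)
  expect_error(call_cnv(1, baseline = 4), "2 bins")
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  set.seed(91)
  for (i in 1:12) {
    n <- sample(4:9, 1)
    baseline <- sample(c(2, 4), 1)
    row <- 1 + rnorm(n, 0, 0.05)
    k <- sample(0:n, 1)
    if (k >= 2) {
      at <- sample(n - k + 1, 1)
      row[at:(at + k - 1)] <- row[at:(at + k - 1)] - 1 / baseline
    }
    v <- cnv_viterbi(row, baseline, sigma = 0.05)
    e <- cnv_enumerate(row, baseline, sigma = 0.05)
    expect_equal(v$log_prob, e$log_prob, tolerance = 1e-10)
    expect_equal(as.numeric(v$states), as.numeric(e$states))
  }
})

test_that("deletion quality grows monotonically as the depth ratio drops", {
  quals <- vapply(seq(1.0, 0.75, by = -0.05), function(r) {
    row <- rep(1, 16); row[5:8] <- r
    calls <- call_cnv(row, baseline = 4, sigma = 0.05)
    if (all(calls$status == "NEGATIVE")) 0 else
      max(calls$quality[calls$delta < 0])
  }, numeric(1))
  expect_true(all(diff(quals) >= 0))
})

test_that("shallow events become NO_CALL instead of confident calls", {
  row <- rep(1, 16)
  row[5:6] <- 0.875  # halfway to a deletion: weak evidence
  calls <- call_cnv(row, baseline = 4, sigma = 0.05, q_min = 30)
  expect_true(all(calls$status %in% c("NO_CALL", "NEGATIVE")))
})

test_that("exon-11 calling works on gene-partitioned site depths", {
  set.seed(95)
  n_sites <- 7; n_samples <- 24
  raw <- matrix(rpois(n_sites * n_samples, 200), n_sites, n_samples,
                dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  bins <- data.frame(start = seq(0, by = 30, length.out = n_sites),
                     end = seq(0, by = 30, length.out = n_sites) + 1)
  # unmutated sample: negative
  dm <- depth_matrix(bins, raw)
  neg <- call_cnv_exon11(dm, "s2")
  expect_equal(neg$status, "NEGATIVE")
  # single-copy exon-11 deletion halves partitioned depth across all sites;
  # the panel-wide sample medians anchor stage one
  raw2 <- raw
  raw2[, 1] <- rpois(n_sites, 100)
  med <- c(100, rep(200, n_samples - 1)); names(med) <- colnames(raw)
  med["s1"] <- 200  # deletion is local to exon 11; panel median unchanged
  dm2 <- depth_matrix(bins, raw2)
  del <- call_cnv_exon11(dm2, "s1", sample_medians = med)
  expect_equal(del$called_copy[1], 1)
  expect_equal(del$status[1], "CALL")
  # fewer than two usable sites: explicit no-call
  nc <- call_cnv_exon11(depth_matrix(bins[1, , drop = FALSE],
                                     raw[1, , drop = FALSE]), "s1")
  expect_equal(nc$status, "NO_CALL")
})

test_that("a pseudogene-only deletion leaves the gene exon-11 call negative", {
  model <- test_model()
  s <- generate_cohort(model, 1, seed = 97)[[1]]
  s <- add_cnv(s, "pseudogene", "11", "11", delta = -1L, haplotype = 1L)
  reads <- simulate_reads(s, model,
                          read_sim_config("hybrid_capture", mean_depth = 150,
                                          error_rate = 0, seed = 98))
  ex11 <- gene_exon_span(model, "11")
  off <- model$homology$pseudo_start - model$homology$gene_start
  near <- (reads$frag_start < ex11[2] + 300 & reads$frag_end > ex11[1] - 300) |
    (reads$frag_start < ex11[2] + off + 300 &
     reads$frag_end > ex11[1] + off - 300)
  aln <- align_readset(reads[near, ], model$sequence)
  part <- partition_exon11_reads(aln, perfect_catalog(model))
  # gene-partitioned depth at the distinguishing sites is unaffected
  sites <- perfect_catalog(model)
  depths <- vapply(sites$gene_pos, function(p) {
    ends <- alignment_end(part$gene_reads$pos, part$gene_reads$cigar)
    sum(part$gene_reads$pos <= p & ends > p)
  }, numeric(1))
  pseudo_depths <- vapply(sites$pseudo_pos, function(p) {
    ends <- alignment_end(part$pseudogene_reads$pos,
                          part$pseudogene_reads$cigar)
    sum(part$pseudogene_reads$pos <= p & ends > p)
  }, numeric(1))
  # pseudogene partition shows the deletion, gene partition does not
  expect_lt(mean(pseudo_depths), 0.65 * mean(depths))
})
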