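# independent likelihood oracle: binomial log-pmf assembled from log
# factorials, not dbinom
oracle_loglik <- function(k, n, p) {
  lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
}

oracle_dosage <- function(n_alt, depth, ploidy, eps) {
  d <- 0:ploidy
  p <- (d / ploidy) * (1 - eps) + (1 - d / ploidy) * (eps / 3)
  d[which.max(oracle_loglik(n_alt, depth, p))]
}

mk_col <- function(ref = "A", counts) {
  structure(list(position = 0L, ref_allele = ref, allele_counts = counts,
                 depth = sum(counts)), class = "PileupColumn")
}

test_that("pileup counts reference and indel alleles at their anchors", {
  ref <- strrep("ACGT", 50)
  aln <- data.frame(read_id = paste0("r", 1:40), mate = 1L, pos = 10,
                    strand = "+", cigar = "40M",
                    seq = substring(ref, 11, 50), score = 40,
                    stringsAsFactors = FALSE)
  cols <- build_pileup(aln, c(10, 50), ref)
  expect_length(cols, 40)
  expect_equal(cols[[1]]$allele_counts,
               structure(40L, names = substring(ref, 11, 11)))
  expect_equal(cols[[1]]$ref_allele, substring(ref, 11, 11))
  expect_equal(cols[[1]]$depth, 40)

  # 1 bp deletion: allele keyed at its anchor, anchor base not double-counted
  del <- data.frame(read_id = "d1", mate = 1L, pos = 10, strand = "+",
                    cigar = "20M1D19M",
                    seq = paste0(substring(ref, 11, 30), substring(ref, 32, 50)),
                    score = 36, stringsAsFactors = FALSE)
  cols2 <- build_pileup(rbind(aln, del), c(10, 50), ref)
  anchor <- cols2[[20]]
  expect_equal(anchor$allele_counts[["-1"]], 1L)
  expect_equal(anchor$depth, 41)
  expect_equal(cols2[[21]]$depth, 40)  # deleted base: no contribution

  # insertion allele keyed at its anchor
  ins <- data.frame(read_id = "i1", mate = 1L, pos = 10, strand = "+",
                    cigar = "20M2I18M",
                    seq = paste0(substring(ref, 11, 30), "TT",
                                 substring(ref, 31, 48)),
                    score = 34, stringsAsFactors = FALSE)
  cols3 <- build_pileup(rbind(aln, ins), c(10, 50), ref)
  expect_equal(cols3[[20]]$allele_counts[["+TT"]], 1L)

  expect_length(build_pileup(aln, c(10, 10), ref), 0)  # empty region
})

test_that("dosage calls match exhaustive likelihood evaluation", {
  # fixed examples: values derived from the binomial oracle
  expect_equal(genotype_site(mk_col(counts = c(A = 100L)), 4)$dosage, 0)
  expect_equal(genotype_site(mk_col(counts = c(A = 74L, T = 26L)), 4)$dosage,
               1)
  expect_equal(oracle_dosage(26, 100, 4, 0.01), 1)
  expect_equal(genotype_site(mk_col(counts = c(A = 2L, T = 48L)), 2)$dosage,
               2)
  expect_equal(oracle_dosage(48, 50, 2, 0.01), 2)
  # randomized agreement with the oracle across ploidies and depths
  set.seed(31)
  for (i in 1:200) {
    ploidy <- sample(c(2L, 4L), 1)
    depth <- sample(30:400, 1)
    n_alt <- rbinom(1, depth, runif(1))
    call <- genotype_site(mk_col(counts = c(A = depth - n_alt, T = n_alt)),
                          ploidy, error_rate = 0.01)
    expect_equal(call$dosage, oracle_dosage(n_alt, depth, ploidy, 0.01))
  }
})

test_that("likelihoods normalize and ref/alt swap mirrors the dosage", {
  set.seed(32)
  for (i in 1:50) {
    ploidy <- sample(c(2L, 4L), 1)
    depth <- sample(50:300, 1)
    n_alt <- rbinom(1, depth, sample(0:ploidy, 1) / ploidy)
    call <- genotype_site(mk_col(counts = c(A = depth - n_alt, T = n_alt)),
                          ploidy)
    post <- exp(call$log_likelihoods - max(call$log_likelihoods))
    expect_equal(sum(post / sum(post)), 1)
    # exchange the ref and alt roles: the alt count becomes depth - n_alt
    swapped <- genotype_site(mk_col(ref = "T",
                                    counts = c(T = n_alt, A = depth - n_alt)),
                             ploidy)
    expect_equal(swapped$dosage, ploidy - call$dosage)
  }
})

test_that("ploidy and depth contracts hold", {
  expect_error(genotype_site(mk_col(counts = c(A = 10L)), 3), "ploidy")
  low <- genotype_site(mk_col(counts = c(A = 5L, T = 5L)), 2)
  expect_equal(low$filter, "LOW_DEPTH")
  ok <- genotype_site(mk_col(counts = c(A = 15L, T = 15L)), 2)
  expect_equal(ok$filter, "PASS")
  expect_equal(ok$dosage, 1)
})

test_that("an unmutated sample yields zero variant records", {
  model <- test_model()
  s <- generate_cohort(model, 1, seed = 77)[[1]]
  reads <- simulate_reads(s, model,
                          read_sim_config("hybrid_capture", mean_depth = 150,
                                          error_rate = 0, seed = 78))
  aln <- align_readset(reads, model$sequence)
  agg <- aggregate_exons12_15(pair_alignments(aln, pairing_region(model)),
                              model)
  calls <- call_region(agg, gene_exon_span(model, as.character(12:15)),
                       ploidy = 4, model$sequence)
  expect_equal(nrow(calls), 0)
})

test_that("pseudogene het SNV appears as a tetraploid dosage-1 record at the gene coordinate", {
  model <- test_model()
  tv <- test_truth_variants()
  agg <- test_aggregated()
  calls <- call_region(agg, gene_exon_span(model, as.character(12:15)),
                       ploidy = 4, model$sequence)
  snv <- calls[calls$pos == tv$snv13$gene_pos, ]
  expect_equal(nrow(snv), 1)
  expect_equal(snv$dosage, 1)
  expect_equal(snv$alt, tv$snv13$alt)
  expect_equal(snv$filter, "PASS")
  # the het pseudogene deletion is also recovered at dosage 1
  del <- calls[calls$pos == tv$del14$gene_pos & startsWith(calls$alt, "-"), ]
  expect_equal(nrow(del), 1)
  expect_equal(del$dosage, 1)
  expect_equal(del$alt, "-2")
})

test_that("gene het SNV in exon 11 is a diploid dosage-1 record after partitioning", {
  model <- test_model()
  tv <- test_truth_variants()
  part <- test_partition_clean()
  calls <- call_region(part$gene_reads, gene_exon_span(model, "11"),
                       ploidy = 2, model$sequence)
  snv <- calls[calls$pos == tv$snv11$pos, ]
  expect_equal(nrow(snv), 1)
  expect_equal(snv$dosage, 1)
  expect_equal(snv$ploidy, 2)
})

test_that("VCF output encodes dosage in the GT field and spells out indels", {
  model <- test_model()
  calls <- data.frame(pos = c(100L, 200L), ref = c("A", "C"),
                      alt = c(substring(model$sequence, 101, 101), "-2"),
                      ploidy = 4L, dosage = c(1L, 3L), qual = c(50, 60),
                      filter = "PASS", depth = c(400L, 380L),
                      n_alt = c(98L, 290L), stringsAsFactors = FALSE)
  calls$ref <- c(substring(model$sequence, 101, 101),
                 substring(model$sequence, 201, 201))
  calls$alt[1] <- setdiff(c("A", "C", "G", "T"), calls$ref[1])[1]
  path <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, path, model$contig_name, model$sequence)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[2], "101")            # 1-based POS
  expect_equal(f1[10], "0/0/0/1")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(nchar(f2[4]), 3)         # deletion REF includes anchor + 2
  expect_equal(nchar(f2[5]), 1)
  expect_equal(f2[10], "0/1/1/1")       # dosage 3 at ploidy 4
})
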