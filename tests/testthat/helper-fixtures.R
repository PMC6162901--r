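# Shared fixtures, built lazily once per test run. The end-to-end objects
# (simulated reads, alignments, partitions) are the expensive part, so every
# test file reuses the same cached run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# compact locus: the post-catalog configuration (7 reliable exon-11 sites,
# none in exons 12-15) keeps end-to-end runs fast
test_model <- function() fixture("model", function() {
  generate_locus(exon_lengths = c(`11` = 240, `12` = 120, `13` = 120,
                                  `14` = 120, `15` = 120),
                 n_distinguishing = c(7, 0, 0, 0, 0), seed = 101)
})

# one sample with known truth variants:
#   gene het SNV in exon 11, pseudogene het SNV in exon 13,
#   pseudogene het 2 bp deletion in exon 14
test_truth_variants <- function() fixture("truth", function() {
  model <- test_model()
  sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  off <- model$homology$pseudo_start - model$homology$gene_start
  pos11 <- gene_exon_span(model, "11")[1] + 120
  pos13 <- gene_exon_span(model, "13")[1] + 60 + off
  pos14 <- gene_exon_span(model, "14")[1] + 55 + off
  list(
    snv11 = list(paralog = "gene", hap = "gene_h1", pos = pos11,
                 ref = sc[pos11 + 1],
                 alt = setdiff(c("A", "C", "G", "T"), sc[pos11 + 1])[1],
                 type = "SNV"),
    snv13 = list(paralog = "pseudogene", hap = "pseudo_h1", pos = pos13,
                 ref = sc[pos13 + 1],
                 alt = setdiff(c("A", "C", "G", "T"), sc[pos13 + 1])[1],
                 type = "SNV", gene_pos = pos13 - off),
    del14 = list(paralog = "pseudogene", hap = "pseudo_h2", pos = pos14,
                 ref = paste(sc[(pos14 + 1):(pos14 + 3)], collapse = ""),
                 alt = sc[pos14 + 1],
                 type = "indel", gene_pos = pos14 - off))
})

test_sample <- function() fixture("sample", function() {
  model <- test_model()
  tv <- test_truth_variants()
  s <- generate_cohort(model, 1, seed = 7)[[1]]
  for (v in tv) {
    s$haplotypes[[v$hap]] <- rbind(
      s$haplotypes[[v$hap]],
      data.frame(pos = v$pos, ref = v$ref, alt = v$alt, type = v$type,
                 converted = FALSE, stringsAsFactors = FALSE))
  }
  s
})

# hybrid-capture run at 250x with typical sequencing error
test_reads <- function() fixture("reads", function() {
  simulate_reads(test_sample(), test_model(),
                 read_sim_config("hybrid_capture", mean_depth = 250,
                                 error_rate = 0.001, seed = 11))
})

test_alignments <- function() fixture("alignments", function() {
  align_readset(test_reads(), test_model()$sequence)
})

test_pairs <- function() fixture("pairs", function() {
  pair_alignments(test_alignments(), pairing_region(test_model()))
})

test_aggregated <- function() fixture("aggregated", function() {
  aggregate_exons12_15(test_pairs(), test_model())
})

# error-free run for purity checks
test_reads_clean <- function() fixture("reads_clean", function() {
  simulate_reads(test_sample(), test_model(),
                 read_sim_config("hybrid_capture", mean_depth = 150,
                                 error_rate = 0, seed = 23))
})

test_partition_clean <- function() fixture("partition_clean", function() {
  model <- test_model()
  reads <- test_reads_clean()
  ex11 <- gene_exon_span(model, "11")
  off <- model$homology$pseudo_start - model$homology$gene_start
  near <- (reads$frag_start < ex11[2] + 300 & reads$frag_end > ex11[1] - 300) |
    (reads$frag_start < ex11[2] + off + 300 &
     reads$frag_end > ex11[1] + off - 300)
  aln <- align_readset(reads[near, ], model$sequence)
  partition_exon11_reads(aln, perfect_catalog(model))
})

# plain-R exhaustive Smith-Waterman with the same affine scheme: the
# independent oracle for the seed-and-extend scores (small instances only)
sw_oracle_score <- function(read, ref, match = 1, mismatch = 1,
                            gap_open = 2, gap_extend = 1) {
  m <- nchar(read); n <- nchar(ref)
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref, "", fixed = TRUE)[[1]]
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open, F[i - 1, j] - gap_extend)
      s <- if (rd[i - 1] == rf[j - 1]) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# random mutation of a sequence for oracle cases
mutate_seq <- function(seq, n_sub = 0, n_gap = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    at <- sample(seq_along(chars), n_sub)
    chars[at] <- vapply(chars[at], function(b) {
      setdiff(c("A", "C", "G", "T"), b)[sample.int(3, 1)]
    }, character(1))
  }
  if (n_gap > 0) {
    at <- sample(seq_along(chars)[-1], 1)
    if (runif(1) < 0.5) {
      chars <- append(chars, sample(c("A", "C", "G", "T"), n_gap,
                                    replace = TRUE), after = at)
    } else {
      chars <- chars[-(at:min(length(chars), at + n_gap - 1))]
    }
  }
  paste(chars, collapse = "")
}
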