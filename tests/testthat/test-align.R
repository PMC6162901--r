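test_that("a read identical to both paralog copies gets two equal-score alignments", {
  model <- generate_locus(exon_lengths = c(`11` = 120, `12` = 120,
                                           `13` = 120, `14` = 120,
                                           `15` = 120),
                          n_distinguishing = 0, seed = 8)
  span12 <- gene_exon_span(model, "12")
  read <- substring(model$sequence, span12[1] + 1, span12[1] + 115)
  hits <- seed_and_extend(read, c(locus = model$sequence))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 2)
  expect_equal(fwd$score, c(115, 115))
  off <- model$homology$pseudo_start - model$homology$gene_start
  expect_setequal(fwd$pos, c(span12[1], span12[1] + off))
})

test_that("one mismatch in a 115 nt read scores 113 and matches the oracle", {
  set.seed(120)
  ref <- random_dna(400)
  read <- substring(ref, 101, 215)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  chars[58] <- setdiff(c("A", "C", "G", "T"), chars[58])[1]
  read_mm <- paste(chars, collapse = "")
  hits <- seed_and_extend(read_mm, c(ref = ref))
  expect_equal(max(hits$score), 113)
  expect_equal(max(hits$score), sw_oracle_score(read_mm, ref))
})

test_that("alignments below the score threshold are suppressed", {
  set.seed(121)
  ref <- random_dna(300)
  # 19 matching bases: best local score 19, under the threshold of 20
  read <- substring(ref, 51, 69)
  expect_equal(sw_oracle_score(read, ref), 19)
  hits <- seed_and_extend(read, c(ref = ref))
  expect_equal(nrow(hits), 0)
  # 20 matching bases clear it
  read20 <- substring(ref, 51, 70)
  hits20 <- seed_and_extend(read20, c(ref = ref))
  expect_gte(nrow(hits20), 1)
  expect_equal(max(hits20$score), 20)
})

test_that("empty reference raises a validation error", {
  expect_error(seed_and_extend("ACGTACGTACGTACGT", c(ref = "")), "empty")
})

test_that("seed-and-extend scores equal the exhaustive Smith-Waterman oracle", {
  set.seed(77)
  for (case in 1:25) {
    ref <- random_dna(sample(100:300, 1))
    start <- sample(1:(nchar(ref) - 50), 1)
    len <- sample(25:50, 1)
    read <- substring(ref, start, start + len - 1)
    read <- mutate_seq(read, n_sub = sample(0:2, 1),
                       n_gap = sample(0:2, 1) * (runif(1) < 0.4))
    hits <- seed_and_extend(read, c(ref = ref))
    oracle <- sw_oracle_score(read, ref)
    has_seed <- length(paralogr:::.seed_diagonals(
      read, seed_index(ref, 11))) > 0
    if (has_seed && oracle >= 20) {
      expect_equal(max(hits$score), oracle,
                   info = sprintf("case %d", case))
    }
  }
})

test_that("emitted scores equal the scheme value recomputed from the alignment", {
  aln <- test_alignments()
  idx <- sample(seq_len(nrow(aln)), 50)
  model <- test_model()
  for (i in idx) {
    expect_equal(rescore_alignment(aln$pos[i], aln$cigar[i], aln$seq[i],
                                   model$sequence), aln$score[i])
  }
  # consumed query length equals read length (soft clips included)
  expect_true(all(vapply(aln$cigar[idx], paralogr:::cigar_query_len,
                         numeric(1)) == 115))
})

test_that("pair rescue applies the four rules", {
  region <- data.frame(copy = "gene", start = 1000, end = 3000)
  mk <- function(read_id, mate, pos, score) {
    data.frame(read_id = read_id, mate = mate, pos = pos, strand = "+",
               cigar = "115M", score = score, seq = strrep("A", 115),
               origin = NA_character_, stringsAsFactors = FALSE)
  }
  # mates 300 bp apart inside the region pair up
  ok <- pair_alignments(rbind(mk("r1", 1, 1100, 115), mk("r1", 2, 1400, 115)),
                        region)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$pair_score, 230)
  # mates 1500 bp apart do not
  far <- pair_alignments(rbind(mk("r2", 1, 1100, 115),
                               mk("r2", 2, 2600, 115)), region)
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "n_discarded"), 1)
  # highest-scoring candidate pair wins
  multi <- pair_alignments(rbind(mk("r3", 1, 1100, 115),
                                 mk("r3", 1, 2000, 110),
                                 mk("r3", 2, 1300, 110),
                                 mk("r3", 2, 2100, 100)), region)
  expect_equal(nrow(multi), 1)
  expect_equal(multi$pair_score, 225)
  expect_equal(c(multi$pos1, multi$pos2), c(1100, 1300))
  # a mate outside the region blocks pairing
  out <- pair_alignments(rbind(mk("r4", 1, 1100, 115), mk("r4", 2, 500, 115)),
                         region)
  expect_equal(nrow(out), 0)
})

test_that("ties across locus copies keep one pair per copy", {
  model <- test_model()
  region <- pairing_region(model)
  off <- model$homology$pseudo_start - model$homology$gene_start
  g <- gene_exon_span(model, "13")[1]
  mk <- function(mate, pos) {
    data.frame(read_id = "t1", mate = mate, pos = pos, strand = "+",
               cigar = "115M", score = 115, seq = strrep("A", 115),
               origin = NA_character_, stringsAsFactors = FALSE)
  }
  aln <- rbind(mk(1, g), mk(1, g + off), mk(2, g + 200), mk(2, g + 200 + off))
  pairs <- pair_alignments(aln, region)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$copy, c("gene", "pseudogene"))
})

test_that("nearly all error-free exon 12-15 pairs survive pairing", {
  model <- test_model()
  reads <- test_reads_clean()
  aln <- align_readset(reads, model$sequence)
  pairs <- pair_alignments(aln, pairing_region(model))
  off <- model$homology$pseudo_start - model$homology$gene_start
  g12 <- gene_exon_span(model, "12")[1]
  g15 <- gene_exon_span(model, "15")[2]
  is_gene <- startsWith(reads$origin, "gene")
  fs <- ifelse(is_gene, reads$frag_start, reads$frag_start - off)
  fe <- ifelse(is_gene, reads$frag_end, reads$frag_end - off)
  truth <- unique(reads$read_id[fs < g15 & fe > g12])
  expect_gte(mean(truth %in% pairs$read_id), 0.999)
})

test_that("aggregation stacks four haplotypes at about twice the single-paralog depth", {
  model <- test_model()
  agg <- test_aggregated()
  span <- gene_exon_span(model, as.character(12:15))
  pu <- build_pileup(agg, span, model$sequence)
  depth <- mean(vapply(pu, function(x) x$depth, numeric(1)))
  expect_lt(abs(depth / 250 - 2), 0.2)
  # origin tags preserved and pseudogene alleles visible at gene coordinates
  expect_true(all(c("gene_h1", "pseudo_h1") %in% agg$origin))
  tv <- test_truth_variants()
  col <- build_pileup(agg, c(tv$snv13$gene_pos, tv$snv13$gene_pos + 1),
                      model$sequence)[[1]]
  expect_gt(col$allele_counts[[tv$snv13$alt]], 0)
})

test_that("aggregating an empty pair set yields an empty alignment set", {
  empty <- pair_alignments(
    data.frame(read_id = character(0), mate = integer(0), pos = integer(0),
               strand = character(0), cigar = character(0),
               score = integer(0), seq = character(0),
               origin = character(0), stringsAsFactors = FALSE),
    pairing_region(test_model()))
  agg <- aggregate_exons12_15(empty, test_model())
  expect_equal(nrow(agg), 0)
})

test_that("exon-11 partition assigns by distinguishing-base alleles", {
  part <- test_partition_clean()
  # purity: with reliable sites and zero errors every assignment matches truth
  expect_true(all(startsWith(part$gene_reads$origin, "gene")))
  expect_true(all(startsWith(part$pseudogene_reads$origin, "pseudo")))
  expect_gt(part$counts$gene, 0)
  expect_gt(part$counts$pseudogene, 0)
  # discarded reads overlap no reliable site (or conflict)
  expect_gt(part$counts$discarded, 0)
})

test_that("partition discards reads with no informative site or conflicting alleles", {
  model <- test_model()
  catalog <- perfect_catalog(model)
  sites <- catalog[catalog$exon == "11", ]
  s1 <- sites[1, ]; s2 <- sites[2, ]
  sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  mk <- function(read_id, pos, seq) {
    data.frame(read_id = read_id, mate = 1L, pos = pos, strand = "+",
               cigar = paste0(nchar(seq), "M"), score = nchar(seq), seq = seq,
               origin = NA_character_, stringsAsFactors = FALSE)
  }
  # read carrying the gene allele at one reliable site -> gene
  p0 <- s1$gene_pos - 20
  gene_read <- paste(sc[(p0 + 1):(p0 + 60)], collapse = "")
  # read covering no reliable site (exon 12 has none) -> discarded
  far <- gene_exon_span(model, "12")[1] + 5
  no_site <- paste(sc[(far + 1):(far + 30)], collapse = "")
  res <- partition_exon11_reads(rbind(mk("g", p0, gene_read),
                                      mk("n", far, no_site)), catalog)
  expect_equal(res$counts$gene, 1)
  expect_equal(res$counts$discarded, 1)
  # read spanning two reliable sites with mixed alleles -> discarded
  if (s2$gene_pos - s1$gene_pos < 100) {
    p1 <- s1$gene_pos - 2
    chars <- sc[(p1 + 1):(s2$gene_pos + 3)]
    chars[s2$gene_pos - p1 + 1] <- s2$pseudo_allele
    mixed <- paste(chars, collapse = "")
    res2 <- partition_exon11_reads(mk("m", p1, mixed), catalog)
    expect_equal(res2$counts$discarded, 1)
  }
})

test_that("an empty reliable-site catalog is an explicit error", {
  catalog <- perfect_catalog(test_model())
  catalog$reliable <- FALSE
  expect_error(partition_exon11_reads(test_alignments()[1:2, ], catalog),
               "impossible")
})
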