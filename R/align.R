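#' Default permissive alignment parameters
#'
#' Seed length 11, mismatch penalty 1, gap open 2 and a score threshold of 20
#' are the permissive settings that let a 115 nt read align to both paralog
#' copies; the match reward (+1) and gap extension (1) complete the scheme so
#' that the threshold is meaningful.
#'
#' @param seed_len exact-seed length (nt)
#' @param match match reward
#' @param mismatch mismatch penalty (positive)
#' @param gap_open penalty of the first base of a gap (positive)
#' @param gap_extend penalty of each further gap base (positive)
#' @param min_score minimum alignment score emitted
#' @return parameter list
#' @export
align_params <- function(seed_len = 11, match = 1, mismatch = 1,
                         gap_open = 2, gap_extend = 1, min_score = 20) {
  list(seed_len = as.integer(seed_len), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, min_score = min_score)
}

#' Build an exact k-mer seed index over a reference
#'
#' Every k-mer is indexed (no minimizer sampling): the loci are tiny, so
#' exhaustiveness is preferred over speed.
#'
#' @param reference reference sequence (single string)
#' @param k seed length
#' @return a `SeedIndex` list
#' @export
seed_index <- function(reference, k = 11) {
  n <- nchar(reference)
  assert_that(n >= k, "reference shorter than the seed length")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(reference, starts, starts + k - 1L)
  pos <- split(starts - 1L, kmers)  # 0-based start positions
  structure(list(kmers = names(pos), pos = unname(pos), k = k,
                 length = n), class = "SeedIndex")
}

# candidate 0-based read-start diagonals from exact seed hits
.seed_diagonals <- function(seq, idx) {
  L <- nchar(seq); k <- idx$k
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  m <- match(kmers, idx$kmers)
  hit <- which(!is.na(m))
  if (!length(hit)) return(integer(0))
  d <- unlist(Map(function(p, s) p - (s - 1L), idx$pos[m[hit]], starts[hit]),
              use.names = FALSE)
  sort(unique(d))
}

.extend_candidates <- function(seq, reference, idx, params, strand,
                               pad = 16L, cluster_gap = 30L) {
  d <- .seed_diagonals(seq, idx)
  if (!length(d)) return(NULL)
  grp <- cumsum(c(1L, diff(d) > cluster_gap))
  L <- nchar(seq)
  pos <- integer(0); cigar <- character(0); score <- integer(0)
  for (dd in split(d, grp)) {
    ws <- max(0L, min(dd) - pad)
    we <- min(idx$length, max(dd) + L + pad)
    # restrict the DP to the seed diagonals +/- pad (gaps beyond the padding
    # are not discoverable from these seeds anyway)
    hit <- .sw_align_cpp(seq, substring(reference, ws + 1L, we),
                         params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         band_lo = 0L,
                         band_hi = (max(dd) - min(dd)) + 2L * pad)
    if (hit$score < params$min_score) next
    pos <- c(pos, ws + hit$ref_start)
    cigar <- c(cigar, hit$cigar)
    score <- c(score, hit$score)
  }
  if (!length(pos)) return(NULL)
  list(pos = pos, strand = rep(strand, length(pos)), cigar = cigar,
       score = score)
}

#' Seed-and-extend alignment of a single read
#'
#' Finds all alignments discoverable by an exact seed match, extends each
#' candidate window with affine-gap local alignment, and emits every
#' alignment scoring at least `min_score` (the "emit all" behaviour). Both
#' orientations of the read are searched.
#'
#' @param read read sequence
#' @param references named character vector of reference sequences
#' @param params see [align_params()]
#' @param index optional prebuilt [seed_index()] when `references` has one
#'   sequence (avoids rebuilding per read)
#' @return data frame of alignments (`ref`, `pos` 0-based, `strand`, `cigar`
#'   with soft clips, `score`, `seq` oriented to the reference strand), or an
#'   empty data frame
#' @export
seed_and_extend <- function(read, references, params = align_params(),
                            index = NULL) {
  assert_that(all(nchar(references) > 0), "empty reference")
  assert_that(nchar(read) >= params$seed_len,
              "read shorter than the seed length")
  out <- list()
  for (rn in seq_along(references)) {
    ref <- references[[rn]]
    idx <- if (!is.null(index) && length(references) == 1L) index else
      seed_index(ref, params$seed_len)
    rc <- revcomp(read)
    fwd <- .extend_candidates(read, ref, idx, params, "+")
    rev <- .extend_candidates(rc, ref, idx, params, "-")
    rows <- data.frame(
      pos = c(fwd$pos, rev$pos),
      strand = c(fwd$strand, rev$strand),
      cigar = c(fwd$cigar, rev$cigar),
      score = c(fwd$score, rev$score),
      seq = c(rep(read, length(fwd$pos)), rep(rc, length(rev$pos))),
      stringsAsFactors = FALSE)
    if (nrow(rows)) {
      rows$ref <- names(references)[rn] %||% as.character(rn)
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      score = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("ref", "pos", "strand", "cigar")]), ]
  rownames(res) <- NULL
  res[, c("ref", "pos", "strand", "cigar", "score", "seq")]
}

#' Align a whole ReadSet to a locus reference
#'
#' @param reads a `ReadSet` (or data frame with read_id, mate, seq columns)
#' @param reference single reference sequence (the locus contig)
#' @param params see [align_params()]
#' @return data frame of alignments with read metadata (`read_id`, `mate`,
#'   `origin` if present) plus `pos`, `strand`, `cigar`, `score`, `seq`
#' @export
align_readset <- function(reads, reference, params = align_params()) {
  idx <- seed_index(reference, params$seed_len)
  has_origin <- "origin" %in% names(reads)
  n <- nrow(reads)
  # bulk reverse complement (much faster than per-read)
  rc_all <- if (n) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$seq))) else character(0)
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    fwd <- .extend_candidates(reads$seq[i], reference, idx, params, "+")
    rev <- .extend_candidates(rc_all[i], reference, idx, params, "-")
    k_f <- length(fwd$pos); k_r <- length(rev$pos)
    if (k_f + k_r == 0L) next
    acc[[i]] <- list(i = rep(i, k_f + k_r),
                     pos = c(fwd$pos, rev$pos),
                     strand = c(fwd$strand, rev$strand),
                     cigar = c(fwd$cigar, rev$cigar),
                     score = c(fwd$score, rev$score),
                     seq = c(rep(reads$seq[i], k_f), rep(rc_all[i], k_r)))
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) {
    return(data.frame(read_id = character(0), mate = integer(0),
                      pos = integer(0), strand = character(0),
                      cigar = character(0), score = integer(0),
                      seq = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  ri <- unlist(lapply(acc, `[[`, "i"), use.names = FALSE)
  res <- data.frame(
    read_id = reads$read_id[ri],
    mate = if ("mate" %in% names(reads)) reads$mate[ri] else 1L,
    pos = unlist(lapply(acc, `[[`, "pos"), use.names = FALSE),
    strand = unlist(lapply(acc, `[[`, "strand"), use.names = FALSE),
    cigar = unlist(lapply(acc, `[[`, "cigar"), use.names = FALSE),
    score = unlist(lapply(acc, `[[`, "score"), use.names = FALSE),
    seq = unlist(lapply(acc, `[[`, "seq"), use.names = FALSE),
    origin = if (has_origin) reads$origin[ri] else NA_character_,
    stringsAsFactors = FALSE)
  res <- res[!duplicated(res[, c("read_id", "mate", "pos", "strand",
                                 "cigar")]), ]
  rownames(res) <- NULL
  res
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_ref_len <- function(cigar) {
  c_ops <- parse_cigar(cigar)
  sum(c_ops$len[c_ops$op %in% c("M", "D")])
}

cigar_query_len <- function(cigar) {
  c_ops <- parse_cigar(cigar)
  sum(c_ops$len[c_ops$op %in% c("M", "I", "S")])
}

alignment_end <- function(pos, cigar) {
  pos + vapply(cigar, cigar_ref_len, numeric(1), USE.NAMES = FALSE)
}

#' Recompute an alignment score from its CIGAR
#'
#' Walks the alignment against the reference and recomputes the score under
#' the scoring scheme; used to check the invariant that emitted scores equal
#' the scheme value of the reported alignment.
#'
#' @param pos 0-based reference start
#' @param cigar CIGAR string (M/I/D/S)
#' @param seq read sequence oriented to the reference
#' @param reference reference string
#' @param params scoring parameters
#' @return integer score
#' @export
rescore_alignment <- function(pos, cigar, seq, reference,
                              params = align_params()) {
  ops <- parse_cigar(cigar)
  refp <- pos; readp <- 0L; score <- 0
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "S") {
      readp <- readp + len
    } else if (op == "M") {
      rb <- strsplit(substring(reference, refp + 1L, refp + len), "")[[1]]
      qb <- strsplit(substring(seq, readp + 1L, readp + len), "")[[1]]
      score <- score + sum(rb == qb) * params$match -
        sum(rb != qb) * params$mismatch
      refp <- refp + len; readp <- readp + len
    } else if (op == "D") {
      score <- score - params$gap_open - (len - 1L) * params$gap_extend
      refp <- refp + len
    } else if (op == "I") {
      score <- score - params$gap_open - (len - 1L) * params$gap_extend
      readp <- readp + len
    }
  }
  score
}

#' Pairing region spanning the ambiguous exons
#'
#' The interval pair (gene exons 12--15 and the homologous pseudogene exons
#' 3--6, each padded) inside which both mates of a rescued pair must map.
#' The default padding exceeds the longest simulated fragment minus one read,
#' so a mate of any read overlapping the exon span still falls inside the
#' region (the real extraction region spans several kb of introns, which has
#' the same effect).
#'
#' @param model a `ParalogLocusModel`
#' @param pad padding in nt
#' @return data frame with columns copy, start, end
#' @export
pairing_region <- function(model, pad = 500) {
  g <- gene_exon_span(model, as.character(12:15), pad = pad)
  off <- model$homology$pseudo_start - model$homology$gene_start
  data.frame(copy = c("gene", "pseudogene"),
             start = c(g[1], g[1] + off), end = c(g[2], g[2] + off),
             stringsAsFactors = FALSE)
}

#' Rescue read pairs with the four-rule algorithm
#'
#' A pair is formed when (1) both single-end alignments share a read name,
#' (2) both map within the target region, (3) the mates start within
#' `max_sep` bp of each other, and (4) among multiple candidate pairs the
#' highest-scoring one is chosen. Reads failing all rules are discarded (the
#' count is kept in the `n_discarded` attribute). When the best pair score is
#' achieved at both locus copies, one pair per copy is kept -- this is what
#' stacks four haplotypes on one locus after aggregation.
#'
#' @param alignments single-end alignments from [align_readset()]
#' @param region data frame of target intervals (see [pairing_region()])
#' @param max_sep maximum distance between mate start positions (bp)
#' @return data frame with one row per rescued pair: read_id, copy,
#'   pair_score, and pos/end/cigar/strand/score/seq for each mate
#' @export
pair_alignments <- function(alignments, region, max_sep = 1000) {
  aln <- alignments
  aln$end <- alignment_end(aln$pos, aln$cigar)
  in_region <- rep(FALSE, nrow(aln))
  for (i in seq_len(nrow(region))) {
    in_region <- in_region | overlaps(aln$pos, aln$end,
                                      region$start[i], region$end[i])
  }
  aln <- aln[in_region, , drop = FALSE]
  total_reads <- length(unique(alignments$read_id))
  groups <- split(seq_len(nrow(aln)), aln$read_id)
  res <- vector("list", length(groups))
  gi <- 0L
  for (g in groups) {
    a1 <- aln[g[aln$mate[g] == 1L], , drop = FALSE]
    a2 <- aln[g[aln$mate[g] == 2L], , drop = FALSE]
    if (!nrow(a1) || !nrow(a2)) next
    cand <- expand.grid(i = seq_len(nrow(a1)), j = seq_len(nrow(a2)))
    sep_ok <- abs(a1$pos[cand$i] - a2$pos[cand$j]) <= max_sep
    cand <- cand[sep_ok, , drop = FALSE]
    if (!nrow(cand)) next
    ps <- a1$score[cand$i] + a2$score[cand$j]
    best <- ps == max(ps)
    cand <- cand[best, , drop = FALSE]
    # copy of each candidate pair, by mate-1 position
    copy <- vapply(cand$i, function(i) {
      hits <- which(overlaps(a1$pos[i], a1$end[i], region$start, region$end))
      region$copy[hits[1]]
    }, character(1))
    keep <- !duplicated(copy)  # one pair per locus copy on ties
    cand <- cand[keep, , drop = FALSE]; copy <- copy[keep]
    rows <- data.frame(
      read_id = a1$read_id[cand$i], copy = copy, pair_score = max(ps),
      pos1 = a1$pos[cand$i], end1 = a1$end[cand$i],
      cigar1 = a1$cigar[cand$i], strand1 = a1$strand[cand$i],
      score1 = a1$score[cand$i], seq1 = a1$seq[cand$i],
      pos2 = a2$pos[cand$j], end2 = a2$end[cand$j],
      cigar2 = a2$cigar[cand$j], strand2 = a2$strand[cand$j],
      score2 = a2$score[cand$j], seq2 = a2$seq[cand$j],
      origin = if ("origin" %in% names(a1)) a1$origin[cand$i] else
        NA_character_,
      stringsAsFactors = FALSE)
    gi <- gi + 1L
    res[[gi]] <- rows
  }
  out <- if (gi) do.call(rbind, res[seq_len(gi)]) else
    data.frame(read_id = character(0), copy = character(0),
               pair_score = numeric(0), pos1 = numeric(0), end1 = numeric(0),
               cigar1 = character(0), strand1 = character(0),
               score1 = numeric(0), seq1 = character(0), pos2 = numeric(0),
               end2 = numeric(0), cigar2 = character(0),
               strand2 = character(0), score2 = numeric(0),
               seq2 = character(0), origin = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- total_reads - length(unique(out$read_id))
  out
}

#' Aggregate rescued pairs onto the gene copy
#'
#' Each rescued pair is positioned once on the gene copy: pairs already at
#' the gene position are kept as-is; pairs placed only at the pseudogene
#' position are translated through the homology bijection. Origin truth tags
#' are preserved, so a duplication-free sample stacks its four haplotypes'
#' reads on the one locus (about twice the single-paralog depth).
#'
#' @param pairs output of [pair_alignments()]
#' @param model a `ParalogLocusModel`
#' @return long-format alignment data frame (two rows per pair) on gene
#'   coordinates: read_id, mate, pos, strand, cigar, score, seq, origin,
#'   src_copy
#' @export
aggregate_exons12_15 <- function(pairs, model) {
  if (!nrow(pairs)) {
    return(data.frame(read_id = character(0), mate = integer(0),
                      pos = numeric(0), strand = character(0),
                      cigar = character(0), score = numeric(0),
                      seq = character(0), origin = character(0),
                      src_copy = character(0), stringsAsFactors = FALSE))
  }
  off <- model$homology$pseudo_start - model$homology$gene_start
  picked <- do.call(rbind, lapply(split(pairs, pairs$read_id), function(p) {
    if (any(p$copy == "gene")) p[p$copy == "gene", ][1, ] else p[1, ]
  }))
  shift <- ifelse(picked$copy == "pseudogene", -off, 0)
  long <- rbind(
    data.frame(read_id = picked$read_id, mate = 1L,
               pos = picked$pos1 + shift, strand = picked$strand1,
               cigar = picked$cigar1, score = picked$score1,
               seq = picked$seq1, origin = picked$origin,
               src_copy = picked$copy, stringsAsFactors = FALSE),
    data.frame(read_id = picked$read_id, mate = 2L,
               pos = picked$pos2 + shift, strand = picked$strand2,
               cigar = picked$cigar2, score = picked$score2,
               seq = picked$seq2, origin = picked$origin,
               src_copy = picked$copy, stringsAsFactors = FALSE))
  long <- long[order(long$pos), ]
  rownames(long) <- NULL
  long
}

#' Base carried by an alignment at a reference position
#'
#' @param pos 0-based alignment start
#' @param cigar CIGAR string
#' @param seq read sequence oriented to the reference
#' @param refpos 0-based reference position
#' @return single base, or `NA` when the position is not covered by an
#'   aligned (M) base
#' @export
read_base_at <- function(pos, cigar, seq, refpos) {
  ops <- parse_cigar(cigar)
  refp <- pos; readp <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "S" || op == "I") {
      readp <- readp + len
    } else if (op == "M") {
      if (refpos >= refp && refpos < refp + len) {
        return(substring(seq, readp + (refpos - refp) + 1L,
                         readp + (refpos - refp) + 1L))
      }
      refp <- refp + len; readp <- readp + len
    } else if (op == "D") {
      if (refpos >= refp && refpos < refp + len) return(NA_character_)
      refp <- refp + len
    }
  }
  NA_character_
}

#' Partition exon-11 reads by distinguishing-base alleles
#'
#' Only reads whose best alignment overlaps at least one reliable
#' distinguishing site are retained. A read (pair: both mates are examined
#' jointly) is assigned to the paralog whose allele it carries at every
#' overlapped reliable site; reads overlapping no reliable site, carrying
#' conflicting alleles, or carrying a base matching neither paralog are
#' discarded.
#'
#' @param alignments single-end alignments over the locus (emit-all)
#' @param catalog a `SiteCatalog` (or the model's distinguishing bases with a
#'   `reliable` column); only reliable exon-11 sites are used
#' @return list with `gene_reads`, `pseudogene_reads`, `discarded` (alignment
#'   data frames) and a `counts` list
#' @export
partition_exon11_reads <- function(alignments, catalog) {
  sites <- as.data.frame(catalog)
  if (!"exon" %in% names(sites)) sites$exon <- "11"
  sites <- sites[sites$reliable & sites$exon == "11", , drop = FALSE]
  if (!nrow(sites)) {
    stop("no reliable exon-11 distinguishing sites: exon-11 calling impossible",
         call. = FALSE)
  }
  aln <- alignments
  aln$end <- alignment_end(aln$pos, aln$cigar)
  groups <- split(seq_len(nrow(aln)), aln$read_id)
  gene_idx <- integer(0); pseudo_idx <- integer(0); disc_idx <- integer(0)
  for (g in groups) {
    votes <- character(0)
    keep_rows <- integer(0)
    for (mate in unique(aln$mate[g])) {
      gm <- g[aln$mate[g] == mate]
      best <- gm[aln$score[gm] == max(aln$score[gm])]
      for (r in best) {
        ovl_g <- which(sites$gene_pos >= aln$pos[r] &
                       sites$gene_pos < aln$end[r])
        ovl_p <- which(sites$pseudo_pos >= aln$pos[r] &
                       sites$pseudo_pos < aln$end[r])
        for (s in ovl_g) {
          b <- read_base_at(aln$pos[r], aln$cigar[r], aln$seq[r],
                            sites$gene_pos[s])
          if (is.na(b)) next
          votes <- c(votes, if (b == sites$gene_allele[s]) "gene"
                     else if (b == sites$pseudo_allele[s]) "pseudogene"
                     else "conflict")
          keep_rows <- c(keep_rows, r)
        }
        for (s in ovl_p) {
          b <- read_base_at(aln$pos[r], aln$cigar[r], aln$seq[r],
                            sites$pseudo_pos[s])
          if (is.na(b)) next
          votes <- c(votes, if (b == sites$pseudo_allele[s]) "pseudogene"
                     else if (b == sites$gene_allele[s]) "gene"
                     else "conflict")
          keep_rows <- c(keep_rows, r)
        }
      }
    }
    if (!length(votes) || length(unique(votes)) > 1L ||
        votes[1] == "conflict") {
      disc_idx <- c(disc_idx, g)
    } else if (votes[1] == "gene") {
      gene_idx <- c(gene_idx, unique(keep_rows))
    } else {
      pseudo_idx <- c(pseudo_idx, unique(keep_rows))
    }
  }
  list(gene_reads = aln[gene_idx, , drop = FALSE],
       pseudogene_reads = aln[pseudo_idx, , drop = FALSE],
       discarded = aln[disc_idx, , drop = FALSE],
       counts = list(gene = length(unique(aln$read_id[gene_idx])),
                     pseudogene = length(unique(aln$read_id[pseudo_idx])),
                     discarded = length(unique(aln$read_id[disc_idx]))))
}

#' Write alignments as SAM
#'
#' @param alignments alignment data frame (from [align_readset()] or
#'   [aggregate_exons12_15()])
#' @param contig contig name
#' @param contig_len contig length
#' @param path output path
#' @return the path, invisibly
#' @export
write_alignments_sam <- function(alignments, contig, contig_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    tag <- if ("origin" %in% names(alignments))
      paste0("\tXO:Z:", alignments$origin) else ""
    writeLines(sprintf("%s\t%d\t%s\t%d\t30\t%s\t*\t0\t0\t%s\t*\tAS:i:%d%s",
                       alignments$read_id, flag, contig,
                       as.integer(alignments$pos) + 1L, alignments$cigar,
                       alignments$seq, as.integer(alignments$score), tag),
               con)
  }
  invisible(path)
}
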