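#' Build a pileup over a region
#'
#' Tallies per-position allele counts from alignments. Indel alleles are
#' keyed at their anchor position VCF-style: an insertion of SEQ after the
#' anchor is the allele `+SEQ`, a deletion of L reference bases after the
#' anchor is `-L`. A read carrying an indel contributes its indel allele at
#' the anchor instead of the anchor base, so column depth always equals the
#' number of reads informative at that column; interior deleted positions
#' receive no contribution from that read.
#'
#' @param alignments alignment data frame (pos, cigar, seq)
#' @param region 0-based half-open interval `c(start, end)`
#' @param reference reference sequence string
#' @return a list of `PileupColumn`s (position, ref_allele, allele_counts,
#'   depth), one per reference position in the region
#' @export
build_pileup <- function(alignments, region, reference) {
  start <- region[1]; end <- region[2]
  npos <- end - start
  if (npos <= 0) return(list())
  pos_acc <- vector("list", nrow(alignments))
  allele_acc <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    cigar <- alignments$cigar[i]
    seq <- alignments$seq[i]
    p0 <- alignments$pos[i]
    if (grepl("^[0-9]+M$", cigar)) {                       # fast path
      len <- as.integer(sub("M$", "", cigar))
      positions <- p0:(p0 + len - 1L)
      alleles <- strsplit(seq, "", fixed = TRUE)[[1]]
    } else {
      ops <- parse_cigar(cigar)
      refp <- p0; readp <- 0L
      positions <- integer(0); alleles <- character(0)
      for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        if (op == "S") {
          readp <- readp + len
        } else if (op == "M") {
          positions <- c(positions, refp:(refp + len - 1L))
          alleles <- c(alleles,
                       strsplit(substring(seq, readp + 1L, readp + len),
                                "", fixed = TRUE)[[1]])
          refp <- refp + len; readp <- readp + len
        } else if (op == "I") {
          anchor <- refp - 1L
          ins <- substring(seq, readp + 1L, readp + len)
          drop <- which(positions == anchor)
          if (length(drop)) {
            alleles[drop[length(drop)]] <- paste0("+", ins)
          } else {
            positions <- c(positions, anchor)
            alleles <- c(alleles, paste0("+", ins))
          }
          readp <- readp + len
        } else if (op == "D") {
          anchor <- refp - 1L
          drop <- which(positions == anchor)
          if (length(drop)) {
            alleles[drop[length(drop)]] <- paste0("-", len)
          } else {
            positions <- c(positions, anchor)
            alleles <- c(alleles, paste0("-", len))
          }
          refp <- refp + len
        }
      }
    }
    inr <- positions >= start & positions < end
    pos_acc[[i]] <- positions[inr]
    allele_acc[[i]] <- alleles[inr]
  }
  positions <- unlist(pos_acc, use.names = FALSE)
  alleles <- unlist(allele_acc, use.names = FALSE)
  ref_chars <- strsplit(substring(reference, start + 1L, end), "",
                        fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- integer(0)
  uniq <- sort(unique(alleles))
  counts <- if (length(uniq)) {
    matrix(tabulate((match(alleles, uniq) - 1L) * npos +
                    (positions - start + 1L), nbins = npos * length(uniq)),
           nrow = npos, ncol = length(uniq),
           dimnames = list(NULL, uniq))
  } else matrix(0L, npos, 0L)
  lapply(seq_len(npos), function(j) {
    ac <- counts[j, counts[j, ] > 0L, drop = TRUE]
    if (is.matrix(ac)) ac <- ac[1, ]
    ac <- ac[order(-ac)]
    structure(list(position = start + j - 1L,
                   ref_allele = ref_chars[j],
                   allele_counts = ac,
                   depth = sum(ac)), class = "PileupColumn")
  })
}

#' Genotype one pileup column at a given ploidy
#'
#' Pure maximum-likelihood dosage model: for alternate-allele dosage d out of
#' `ploidy` copies, each read shows the alternate allele with probability
#' `p_d = (d/ploidy)(1-e) + (1-d/ploidy)(e/3)` where `e` is the per-base
#' error rate, and the alternate read count is binomial. The call is the
#' dosage maximizing the likelihood (ties go to the lower dosage), with a
#' Phred-scaled quality from the normalized likelihoods (uniform prior over
#' dosages). Columns below `min_depth` reads are flagged LOW_DEPTH.
#'
#' @param column a `PileupColumn`
#' @param ploidy 2 (partitioned exon 11) or 4 (aggregated exons 12--15)
#' @param error_rate per-read error probability toward a specific alternate
#' @param min_depth minimum depth for a PASS call
#' @return a `GenotypeCall` (position, ref, alt, ploidy, dosage,
#'   log_likelihoods, qual, filter, depth)
#' @export
genotype_site <- function(column, ploidy, error_rate = 0.01,
                          min_depth = 20) {
  if (!ploidy %in% c(2L, 4L)) {
    stop("ploidy must be 2 or 4", call. = FALSE)
  }
  assert_that(column$depth >= 1, "column depth must be >= 1")
  ac <- column$allele_counts
  non_ref <- ac[names(ac) != column$ref_allele]
  alt <- if (length(non_ref)) names(non_ref)[which.max(non_ref)] else
    NA_character_
  n_alt <- if (is.na(alt)) 0L else as.integer(non_ref[[alt]])
  depth <- column$depth
  d <- 0:ploidy
  p_d <- (d / ploidy) * (1 - error_rate) +
    (1 - d / ploidy) * (error_rate / 3)
  ll <- dbinom(n_alt, depth, p_d, log = TRUE)
  dosage <- d[which.max(ll)]  # which.max takes the first (lower) on ties
  post <- exp(ll - max(ll)); post <- post / sum(post)
  qual <- -10 * log10(max(1e-12, 1 - post[dosage + 1L]))
  structure(list(position = column$position, ref = column$ref_allele,
                 alt = alt, ploidy = as.integer(ploidy), dosage = dosage,
                 log_likelihoods = ll, qual = qual,
                 filter = if (depth < min_depth) "LOW_DEPTH" else "PASS",
                 depth = depth, n_alt = n_alt),
            class = "GenotypeCall")
}

#' @export
print.GenotypeCall <- function(x, ...) {
  cat(sprintf("GenotypeCall pos=%d %s>%s dosage=%d/%d qual=%.1f %s\n",
              x$position, x$ref, x$alt %||% ".", x$dosage, x$ploidy,
              x$qual, x$filter))
  invisible(x)
}

#' Call variants over a region at a fixed ploidy
#'
#' Builds the pileup and genotypes every column; only non-reference dosages
#' are reported. For ploidy 2 the alignments are expected to be
#' gene-partitioned exon-11 reads; for ploidy 4, aggregated exon 12--15
#' reads. Columns below the depth minimum still emit (with a LOW_DEPTH
#' filter) when their dosage is non-zero.
#'
#' @param alignments alignment data frame
#' @param region 0-based half-open `c(start, end)`
#' @param ploidy 2 or 4
#' @param reference reference sequence string
#' @param error_rate,min_depth see [genotype_site()]
#' @return data frame of calls: pos (0-based), ref, alt, ploidy, dosage,
#'   qual, filter, depth, n_alt
#' @export
call_region <- function(alignments, region, ploidy, reference,
                        error_rate = 0.01, min_depth = 20) {
  cols <- build_pileup(alignments, region, reference)
  out <- lapply(cols, function(cl) {
    if (cl$depth < 1) return(NULL)
    has_alt <- any(names(cl$allele_counts) != cl$ref_allele)
    if (!has_alt) return(NULL)
    call <- genotype_site(cl, ploidy, error_rate, min_depth)
    if (call$dosage == 0L) return(NULL)
    data.frame(pos = call$position, ref = call$ref, alt = call$alt,
               ploidy = call$ploidy, dosage = call$dosage, qual = call$qual,
               filter = call$filter, depth = call$depth, n_alt = call$n_alt,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), ploidy = integer(0),
                      dosage = integer(0), qual = numeric(0),
                      filter = character(0), depth = integer(0),
                      n_alt = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write genotype calls as VCF 4.2
#'
#' Indel alleles are spelled out VCF-style from the reference (left-anchored,
#' anchor base included). The GT field encodes the dosage at the call's
#' ploidy, e.g. `0/0/0/1` for dosage 1 at ploidy 4.
#'
#' @param calls data frame from [call_region()]
#' @param path output path
#' @param contig contig name
#' @param reference reference sequence string
#' @return the path, invisibly
#' @export
write_calls_vcf <- function(calls, path, contig, reference) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig,
                       nchar(reference)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"),
             con)
  for (i in seq_len(nrow(calls))) {
    pos0 <- calls$pos[i]; alt <- calls$alt[i]
    anchor <- substring(reference, pos0 + 1L, pos0 + 1L)
    if (startsWith(alt, "+")) {
      ref_f <- anchor; alt_f <- paste0(anchor, substring(alt, 2L))
    } else if (startsWith(alt, "-")) {
      len <- as.integer(substring(alt, 2L))
      ref_f <- substring(reference, pos0 + 1L, pos0 + 1L + len)
      alt_f <- anchor
    } else {
      ref_f <- calls$ref[i]; alt_f <- alt
    }
    gt <- paste(c(rep("0", calls$ploidy[i] - calls$dosage[i]),
                  rep("1", calls$dosage[i])), collapse = "/")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\t%s\tDP=%d\tGT\t%s",
                       contig, pos0 + 1L, ref_f, alt_f, calls$qual[i],
                       calls$filter[i], calls$depth[i], gt), con)
  }
  invisible(path)
}
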