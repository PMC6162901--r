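#' Read-simulation configuration
#'
#' @param mode "hybrid_capture" (fragments from all four haplotypes across
#'   both paralog blocks), "amplicon_gene" or "amplicon_pseudogene"
#'   (fragments only from the named paralog's two haplotypes, emulating a
#'   paralog-specific long-range amplicon)
#' @param read_length read length in nt
#' @param paired paired-end reads (mate 2 is the reverse complement of the
#'   fragment's 3' end)
#' @param mean_depth target mean fold-coverage over the targeted block
#' @param error_rate per-base substitution error probability in \[0,1);
#'   errors are uniform over the three alternative bases
#' @param dropout_fraction relative amplification of the second haplotype in
#'   amplicon mode: each of its fragments is retained with this probability
#'   (1 = no dropout). Models PCR allelic dropout by per-fragment Bernoulli
#'   thinning.
#' @param fragment_range uniform fragment-length range in nt
#' @param seed integer seed
#' @return a `ReadSimConfig` list
#' @export
read_sim_config <- function(mode = c("hybrid_capture", "amplicon_gene",
                                     "amplicon_pseudogene"),
                            read_length = 115, paired = TRUE,
                            mean_depth = 500, error_rate = 0.001,
                            dropout_fraction = 1.0,
                            fragment_range = c(250, 600), seed = 1) {
  mode <- match.arg(mode)
  assert_that(error_rate >= 0 && error_rate < 1, "error_rate must be in [0,1)")
  assert_that(mean_depth > 0, "mean_depth must be > 0")
  assert_that(dropout_fraction > 0 && dropout_fraction <= 1,
              "dropout_fraction must be in (0,1]")
  assert_that(fragment_range[1] >= read_length,
              "fragments must be at least one read long")
  structure(list(mode = mode, read_length = as.integer(read_length),
                 paired = isTRUE(paired), mean_depth = mean_depth,
                 error_rate = error_rate,
                 dropout_fraction = dropout_fraction,
                 fragment_range = fragment_range, seed = seed),
            class = "ReadSimConfig")
}

# apply SNV/indel variants (VCF-style ref/alt, 0-based anchor pos relative to
# `chars`) to a character vector; returns the haplotype chars and a map from
# reference index (1-based) to haplotype index (NA inside deletions)
apply_variants_chars <- function(chars, vars) {
  n <- length(chars)
  if (is.null(vars) || nrow(vars) == 0L) {
    return(list(chars = chars, map = seq_len(n)))
  }
  del <- logical(n)
  ins <- vector("list", n)
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i] + 1L
    ref <- vars$ref[i]; alt <- vars$alt[i]
    lr <- nchar(ref); la <- nchar(alt)
    if (lr == 1L && la == 1L) {
      chars[p] <- alt
    } else if (lr == 1L && la > 1L) {
      ins[[p]] <- strsplit(substring(alt, 2L), "", fixed = TRUE)[[1]]
    } else if (lr > 1L && la == 1L) {
      del[(p + 1L):(p + lr - 1L)] <- TRUE
    } else {
      stop("unsupported variant representation (MNVs not modelled)",
           call. = FALSE)
    }
  }
  emit <- as.integer(!del) + lengths(ins)
  cum <- cumsum(emit)
  map <- ifelse(del, NA_integer_, cum - lengths(ins) - as.integer(!del) + 1L)
  hap <- character(cum[n])
  hap[map[!del]] <- chars[!del]
  for (p in which(lengths(ins) > 0L)) {
    k <- length(ins[[p]])
    at <- cum[p] - k + 1L
    hap[at:(at + k - 1L)] <- ins[[p]]
  }
  list(chars = hap, map = map)
}

# forward/backward-filled lookup of reference position -> haplotype position
map_pos <- function(map, idx, fill = c("forward", "backward")) {
  fill <- match.arg(fill)
  v <- map[idx]
  if (anyNA(v)) {
    for (k in which(is.na(v))) {
      i <- idx[k]
      if (fill == "forward") {
        while (i <= length(map) && is.na(map[i])) i <- i + 1L
        v[k] <- if (i <= length(map)) map[i] else max(map, na.rm = TRUE)
      } else {
        while (i >= 1L && is.na(map[i])) i <- i - 1L
        v[k] <- if (i >= 1L) map[i] else 1L
      }
    }
  }
  v
}

#' Simulate short reads from a sample genome
#'
#' Draws sequencing fragments uniformly (by midpoint) over the targeted
#' paralog block(s), honouring copy-number events: a haplotype's deleted span
#' yields no fragments, a duplicated span yields twice as many. In
#' hybrid-capture mode all four haplotypes contribute; in amplicon mode only
#' the named paralog's two haplotypes do, and the second haplotype may be
#' thinned to model allelic dropout. Per-base substitution errors are applied
#' independently. In amplicon mode a deletion spanning all five exons removes
#' the primer site, so the affected haplotype drops out entirely (with a
#' warning).
#'
#' @param sample a `SampleGenome`
#' @param model a `ParalogLocusModel`
#' @param config a `ReadSimConfig`
#' @return a `ReadSet` data frame (one row per read) with columns `read_id`,
#'   `mate`, `seq`, `qual`, `origin` (truth haplotype), `frag_start`,
#'   `frag_end`, `true_pos` and `true_strand`; reference coordinates are
#'   0-based
#' @export
simulate_reads <- function(sample, model, config) {
  assert_that(inherits(model, "ParalogLocusModel"), "model required")
  assert_that(inherits(config, "ReadSimConfig"), "config required")
  set.seed(config$seed)
  sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  h <- model$homology
  rl <- config$read_length
  haps <- switch(config$mode,
    hybrid_capture = c("gene_h1", "gene_h2", "pseudo_h1", "pseudo_h2"),
    amplicon_gene = c("gene_h1", "gene_h2"),
    amplicon_pseudogene = c("pseudo_h1", "pseudo_h2"))

  out <- list()
  for (hap in haps) {
    paralog <- if (startsWith(hap, "gene")) "gene" else "pseudogene"
    hap_no <- as.integer(substring(hap, nchar(hap)))
    bs <- if (paralog == "gene") h$gene_start else h$pseudo_start
    be <- bs + h$length

    ev <- sample$copy_events
    ev <- ev[ev$paralog == paralog & ev$haplotype == hap_no, , drop = FALSE]
    spans <- if (nrow(ev)) {
      t(vapply(seq_len(nrow(ev)), function(i) {
        s <- gene_exon_span(model, as.character(ev$exon_from[i]:ev$exon_to[i]))
        if (paralog == "pseudogene") s <- s + (h$pseudo_start - h$gene_start)
        s
      }, numeric(2)))
    } else matrix(numeric(0), 0, 2)

    if (config$mode != "hybrid_capture" && nrow(ev) &&
        any(ev$delta == -1L & ev$exon_from == "11" & ev$exon_to == "15")) {
      warning(sprintf(
        "amplicon primer site deleted on %s of %s: haplotype drops out",
        hap, sample$sample_id))
      next
    }

    # haplotype sequence for the block
    block <- sc[(bs + 1L):be]
    vars <- sample$haplotypes[[hap]]
    vars_rel <- vars
    if (nrow(vars_rel)) vars_rel$pos <- vars_rel$pos - bs
    hv <- apply_variants_chars(block, vars_rel)
    hap_seq <- paste(hv$chars, collapse = "")

    # per-haplotype depth is mean_depth/2 (two haplotypes per targeted locus)
    bases_per_frag <- rl * (if (config$paired) 2L else 1L)
    if (config$mode == "hybrid_capture") {
      # capture pulls down fragments from beyond the block too; sampling
      # midpoints over an extended window keeps coverage uniform across the
      # whole block instead of tapering at its edges
      ext <- round(mean(config$fragment_range) / 2)
      region_len <- h$length + 2 * ext
      n_frag <- round((config$mean_depth / 2) * region_len / bases_per_frag)
      if (n_frag == 0L) next
      fl <- round(runif(n_frag, config$fragment_range[1],
                        config$fragment_range[2]))
      mid <- (bs - ext) + runif(n_frag) * region_len
      fs <- pmax(0L, as.integer(round(mid - fl / 2)))
      fe <- pmin(length(sc), fs + as.integer(fl))
    } else {
      # an amplicon only yields fragments contained in the amplified block
      n_frag <- round((config$mean_depth / 2) * h$length / bases_per_frag)
      if (n_frag == 0L) next
      fl <- pmin(round(runif(n_frag, config$fragment_range[1],
                             config$fragment_range[2])), h$length)
      fs <- as.integer(bs + floor(runif(n_frag) * (h$length - fl + 1)))
      fe <- fs + as.integer(fl)
    }

    keep <- rep(TRUE, n_frag)
    extra <- integer(0)
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        hit <- overlaps(fs, fe, spans[i, 1], spans[i, 2])
        if (ev$delta[i] == -1L) keep <- keep & !hit
        else extra <- c(extra, which(hit))
      }
    }
    if (config$mode != "hybrid_capture" && hap_no == 2L &&
        config$dropout_fraction < 1) {
      keep <- keep & (runif(n_frag) < config$dropout_fraction)
    }
    idx <- c(which(keep), extra[keep[extra]])
    if (!length(idx)) next
    fs <- fs[idx]; fe <- fe[idx]

    # extract haplotype-coordinate fragments (block-relative, forward filled
    # across deletions); fragments outside the block carry plain reference
    in_block <- fe > bs & fs < be
    rs <- pmax(1L, fs - bs + 1L); re <- pmin(h$length, fe - bs)
    frag_seq <- character(length(fs))
    if (any(in_block)) {
      hs <- map_pos(hv$map, rs[in_block], "forward")
      he <- map_pos(hv$map, re[in_block], "backward")
      core <- substring(hap_seq, hs, he)
      # fragments overhanging the block keep reference sequence there
      left_ext <- ifelse(fs[in_block] < bs,
                         substring(model$sequence, fs[in_block] + 1L, bs), "")
      right_ext <- ifelse(fe[in_block] > be,
                          substring(model$sequence, be + 1L, fe[in_block]),
                          "")
      frag_seq[in_block] <- paste0(left_ext, core, right_ext)
    }
    if (any(!in_block)) {
      frag_seq[!in_block] <- substring(model$sequence, fs[!in_block] + 1L,
                                       fe[!in_block])
    }
    ok <- nchar(frag_seq) >= rl
    fs <- fs[ok]; fe <- fe[ok]; frag_seq <- frag_seq[ok]
    n <- length(frag_seq)
    if (!n) next

    ids <- sprintf("%s_%s_f%06d", sample$sample_id, hap, seq_len(n))
    r1 <- substring(frag_seq, 1L, rl)
    rows <- data.frame(read_id = ids, mate = 1L, seq = r1,
                       origin = hap, frag_start = fs, frag_end = fe,
                       true_pos = fs, true_strand = "+",
                       stringsAsFactors = FALSE)
    if (config$paired) {
      flen <- nchar(frag_seq)
      r2 <- revcomp(substring(frag_seq, flen - rl + 1L, flen))
      rows <- rbind(rows,
        data.frame(read_id = ids, mate = 2L, seq = r2, origin = hap,
                   frag_start = fs, frag_end = fe, true_pos = fe - rl,
                   true_strand = "-", stringsAsFactors = FALSE))
    }
    out[[hap]] <- rows
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), mate = integer(0), seq = character(0),
               origin = character(0), frag_start = integer(0),
               frag_end = integer(0), true_pos = integer(0),
               true_strand = character(0), stringsAsFactors = FALSE)
  rownames(reads) <- NULL

  # sequencing errors: per-base substitution, uniform over alternatives
  if (config$error_rate > 0 && nrow(reads)) {
    n_err <- rbinom(nrow(reads), rl, config$error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
      at <- sample.int(rl, n_err[i])
      chars[at] <- vapply(chars[at], substitute_base, character(1))
      reads$seq[i] <- paste(chars, collapse = "")
    }
  }
  reads$qual <- strrep("I", rl)
  structure(reads, class = c("ReadSet", "data.frame"),
            contig = model$contig_name, config = config,
            sample_id = sample$sample_id)
}

#' Write a ReadSet as FASTQ
#'
#' Paired reads go to `<prefix>_1.fastq` / `<prefix>_2.fastq`; single-end
#' reads to `<prefix>.fastq`. Qualities are Phred+33.
#'
#' @param reads a `ReadSet`
#' @param prefix output path prefix
#' @return character vector of paths written, invisibly
#' @export
write_fastq <- function(reads, prefix) {
  fq <- function(df, path) {
    if (nrow(df) == 0) { writeLines(character(0), path); return(path) }
    writeLines(as.vector(rbind(paste0("@", df$read_id, "/", df$mate),
                               df$seq, "+", df$qual)), path)
    path
  }
  if (any(reads$mate == 2L)) {
    p <- c(fq(reads[reads$mate == 1L, ], paste0(prefix, "_1.fastq")),
           fq(reads[reads$mate == 2L, ], paste0(prefix, "_2.fastq")))
  } else {
    p <- fq(reads, paste0(prefix, ".fastq"))
  }
  invisible(p)
}

#' Read FASTQ files into a ReadSet-like data frame
#'
#' @param paths one (single-end) or two (paired) FASTQ paths
#' @return data frame with read_id, mate, seq, qual
#' @export
read_fastq <- function(paths) {
  one <- function(path, mate) {
    x <- readLines(path)
    if (!length(x)) return(data.frame(read_id = character(0),
                                      mate = integer(0), seq = character(0),
                                      qual = character(0)))
    ids <- sub("^@", "", x[seq(1, length(x), by = 4)])
    ids <- sub("/[12]$", "", ids)
    data.frame(read_id = ids, mate = mate,
               seq = x[seq(2, length(x), by = 4)],
               qual = x[seq(4, length(x), by = 4)], stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(paths), function(i) one(paths[i], i)))
}

#' Write truth alignments as SAM
#'
#' Records each read at its generative position with its origin haplotype in
#' the `XO` tag, for downstream evaluation of pairing and partitioning. The
#' CIGAR is recorded as full-length match; small indel variants on the source
#' haplotype are not spelled out in the truth CIGAR.
#'
#' @param reads a `ReadSet`
#' @param model the `ParalogLocusModel` the reads were simulated from
#' @param path output SAM path
#' @return the path, invisibly
#' @export
write_truth_sam <- function(reads, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", model$contig_name,
                       nchar(model$sequence))), con)
  if (nrow(reads)) {
    paired <- any(reads$mate == 2L)
    flag <- rep(0L, nrow(reads))
    if (paired) {
      flag <- 1L + 2L +
        ifelse(reads$mate == 1L, 64L, 128L) +
        ifelse(reads$true_strand == "-", 16L, 32L)
    } else {
      flag <- ifelse(reads$true_strand == "-", 16L, 0L)
    }
    rl <- nchar(reads$seq)
    seq_out <- ifelse(reads$true_strand == "-", revcomp(reads$seq), reads$seq)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tXO:Z:%s",
                       reads$read_id, flag, attr(reads, "contig"),
                       reads$true_pos + 1L, rl, seq_out, reads$qual,
                       reads$origin), con)
  }
  invisible(path)
}
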