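#' Inject a synthetic single-copy CNV
#'
#' Deletions subsample reads (or bin counts) in the target span to 75%;
#' duplications scale read number to 125% by resampling 25% extra. On a
#' tetraploid baseline these are the depth signatures of one lost or gained
#' copy out of four.
#'
#' @param x a numeric raw-count row, or an alignment data frame
#' @param span for a count row, integer bin indices; for alignments, a
#'   0-based half-open `c(start, end)` reference interval
#' @param kind "deletion" or "duplication"
#' @param p retention (deletion) / resampling (duplication) fraction
#' @param seed optional integer seed
#' @return object of the same type with the event injected
#' @export
inject_cnv <- function(x, span, kind = c("deletion", "duplication"),
                       p = 0.25, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  UseMethod("inject_cnv")
}

#' @export
inject_cnv.numeric <- function(x, span, kind = c("deletion", "duplication"),
                               p = 0.25, seed = NULL) {
  kind <- match.arg(kind)
  assert_that(all(span >= 1 & span <= length(x)), "span outside the row")
  if (kind == "deletion") {
    x[span] <- rbinom(length(span), x[span], 1 - p)
  } else {
    x[span] <- x[span] + rbinom(length(span), x[span], p)
  }
  x
}

#' @export
inject_cnv.data.frame <- function(x, span,
                                  kind = c("deletion", "duplication"),
                                  p = 0.25, seed = NULL) {
  kind <- match.arg(kind)
  ends <- alignment_end(x$pos, x$cigar)
  hit <- which(overlaps(x$pos, ends, span[1], span[2]))
  if (kind == "deletion") {
    drop <- hit[runif(length(hit)) < p]
    if (length(drop)) x <- x[-drop, , drop = FALSE]
  } else {
    extra <- hit[runif(length(hit)) < p]
    if (length(extra)) {
      dup <- x[extra, , drop = FALSE]
      dup$read_id <- paste0(dup$read_id, "_dup")
      x <- rbind(x, dup)
    }
  }
  rownames(x) <- NULL
  x
}

#' Contiguous exon spans for the sweep
#'
#' @param exons exon labels in order
#' @return data frame with from, to and size columns (all contiguous
#'   combinations)
#' @export
contiguous_exon_spans <- function(exons) {
  n <- length(exons)
  out <- do.call(rbind, lapply(seq_len(n), function(size) {
    do.call(rbind, lapply(seq_len(n - size + 1L), function(i) {
      data.frame(from = exons[i], to = exons[i + size - 1L], size = size,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' CNV sensitivity sweep over contiguous exon spans
#'
#' For every contiguous combination of the given exons and both event kinds,
#' repeatedly draws a CNV-negative background sample from the cohort, injects
#' the event into its raw bin counts, renormalizes against the cohort, calls
#' CNVs and scores a detection when a confidently called event overlaps the
#' injected span with the correct sign. Replicates are distributed uniformly
#' over span x kind combinations. Stage-one normalization of the injected row
#' is anchored on the sample's pre-injection median: the matrix covers only
#' the swept exons, while a production sample median is dominated by the rest
#' of the panel and is unmoved by a local event.
#'
#' @param dm raw `DepthMatrix` of CNV-negative samples
#' @param exon_bins named list mapping exon label to the bin indices tiling it
#' @param n_replicates total number of simulated samples (the study-scale
#'   default is 2186)
#' @param baseline 2 or 4
#' @param p_cnv,q_min see [call_cnv()]
#' @param seed integer seed
#' @return list with `detail` (per span x kind) and `by_size` (per size x
#'   kind sensitivity) data frames
#' @export
cnv_sensitivity_sweep <- function(dm, exon_bins, n_replicates = 2186,
                                  baseline = 4L, p_cnv = 0.01, q_min = 3,
                                  seed = 1) {
  set.seed(seed)
  dmn <- normalize_depths(dm)
  sigma <- estimate_sigma(dmn)
  bin_med <- attr(dmn, "bin_medians")
  spans <- contiguous_exon_spans(names(exon_bins))
  combos <- rbind(cbind(spans, kind = "deletion"),
                  cbind(spans, kind = "duplication"))
  n_each <- rep(n_replicates %/% nrow(combos), nrow(combos))
  extra <- n_replicates %% nrow(combos)
  if (extra) n_each[seq_len(extra)] <- n_each[seq_len(extra)] + 1L
  labels <- names(exon_bins)
  detail <- lapply(seq_len(nrow(combos)), function(ci) {
    from <- combos$from[ci]; to <- combos$to[ci]; kind <- combos$kind[ci]
    bins_hit <- unlist(exon_bins[which(labels == from):which(labels == to)])
    detected <- 0L
    for (r in seq_len(n_each[ci])) {
      s <- sample.int(ncol(dm$raw), 1L)
      row_raw <- inject_cnv(dm$raw[, s], bins_hit, kind)
      row <- normalize_row(row_raw, bin_med,
                           sample_median = median(dm$raw[, s]))
      calls <- call_cnv(row, baseline, p_cnv, sigma, q_min)
      want_sign <- if (kind == "deletion") -1L else 1L
      hit <- calls$status == "CALL" & sign(calls$delta) == want_sign &
        calls$bin_from <= max(bins_hit) & calls$bin_to >= min(bins_hit)
      if (any(hit)) detected <- detected + 1L
    }
    data.frame(from = from, to = to, size = combos$size[ci], kind = kind,
               n = n_each[ci], detected = detected,
               sensitivity = detected / n_each[ci], stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  by_size <- do.call(rbind, lapply(split(detail,
                                         list(detail$kind, detail$size)),
    function(d) data.frame(kind = d$kind[1], size = d$size[1],
                           n = sum(d$n), detected = sum(d$detected),
                           sensitivity = sum(d$detected) / sum(d$n))))
  by_size <- by_size[order(by_size$kind, by_size$size), ]
  rownames(by_size) <- NULL
  list(detail = detail, by_size = by_size)
}

#' Frequency-weighted aggregate sensitivity
#'
#' The overall sensitivity is the per-size sensitivities weighted by the
#' observed frequency distribution of CNV length, reported in percent to one
#' decimal.
#'
#' @param sensitivities per-class sensitivities, in percent
#' @param weights observed frequency weights, summing to 1
#' @return weighted sensitivity in percent, one decimal
#' @export
weighted_aggregate_sensitivity <- function(sensitivities, weights) {
  if (length(sensitivities) != length(weights)) {
    stop("sensitivities and weights must have the same length", call. = FALSE)
  }
  assert_that(abs(sum(weights) - 1) <= 1e-9, "weights must sum to 1")
  round_half_up(sum(sensitivities * weights), 1)
}

#' Merge two diploid alignment sets into a synthetic tetraploid
#'
#' Two diploid samples (at least one carrying an indel of known dosage) are
#' merged into a four-copy alignment; when one sample has more reads in the
#' 100 bp window centered on the indel, it is binomially downsampled so both
#' contribute approximately equally. The expected tetraploid dosage is the
#' sum of the two diploid dosages.
#'
#' @param aln_a,aln_b diploid alignment data frames
#' @param indel_site 0-based position of the indel anchor
#' @param dosage_a,dosage_b diploid alt dosages (0..2)
#' @param window window width (bp) over which depths are equalized
#' @param seed optional integer seed
#' @return list with `alignments` (merged), `expected_dosage` and
#'   `downsampled` ("a", "b" or "none")
#' @export
merge_diploid_to_tetraploid <- function(aln_a, aln_b, indel_site,
                                        dosage_a, dosage_b, window = 100,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- c(indel_site - window / 2, indel_site + window / 2)
  in_win <- function(a) {
    ends <- alignment_end(a$pos, a$cigar)
    which(overlaps(a$pos, ends, w[1], w[2]))
  }
  ia <- in_win(aln_a); ib <- in_win(aln_b)
  if (!length(ia) || !length(ib)) {
    stop("indel site not covered in both samples", call. = FALSE)
  }
  downsampled <- "none"
  thin <- function(a, idx, target) {
    # binomial downsampling of window reads to the target count
    keep_w <- idx[runif(length(idx)) < target / length(idx)]
    rbind(a[setdiff(seq_len(nrow(a)), idx), , drop = FALSE],
          a[keep_w, , drop = FALSE])
  }
  if (length(ia) > length(ib)) {
    aln_a <- thin(aln_a, ia, length(ib)); downsampled <- "a"
  } else if (length(ib) > length(ia)) {
    aln_b <- thin(aln_b, ib, length(ia)); downsampled <- "b"
  }
  aln_a$read_id <- paste0("A_", aln_a$read_id)
  aln_b$read_id <- paste0("B_", aln_b$read_id)
  merged <- rbind(aln_a, aln_b)
  rownames(merged) <- NULL
  list(alignments = merged, expected_dosage = dosage_a + dosage_b,
       downsampled = downsampled)
}

#' Indel sensitivity over a merged tetraploid cohort
#'
#' @param results data frame with `expected_dosage` and `called_dosage`
#'   (0 when the indel was not called)
#' @return list with presence-level sensitivity (indel detected at all, over
#'   samples with expected dosage > 0) and dosage-level concordance (called
#'   dosage equals expected)
#' @export
indel_sensitivity <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("empty merged cohort", call. = FALSE)
  }
  pos <- results$expected_dosage > 0
  assert_that(any(pos), "no indel-positive merges to assess")
  list(presence = mean(results$called_dosage[pos] > 0),
       dosage_concordance = mean(results$called_dosage == results$expected_dosage),
       n = nrow(results))
}
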