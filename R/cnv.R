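#' Construct a depth matrix
#'
#' @param bins data frame of 0-based half-open bin intervals (start, end),
#'   sorted and non-overlapping
#' @param raw numeric matrix of raw counts, bins x samples
#' @param samples sample ids (defaults to raw's colnames)
#' @return a `DepthMatrix`
#' @export
depth_matrix <- function(bins, raw, samples = colnames(raw)) {
  assert_that(nrow(bins) == nrow(raw), "bins and raw must agree")
  assert_that(!is.unsorted(bins$start) &&
              all(bins$start[-1] >= head(bins$end, -1)),
              "bins must be sorted and non-overlapping")
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(raw)))
  colnames(raw) <- samples
  structure(list(bins = bins, samples = samples, raw = raw,
                 normalized = NULL), class = "DepthMatrix")
}

#' Tile a region into equal-sized bins
#'
#' @param start,end 0-based half-open region
#' @param width bin width (50 bp is the amplicon-mode convention)
#' @return data frame of bin intervals
#' @export
make_bins <- function(start, end, width = 50) {
  s <- seq(start, end - 1, by = width)
  data.frame(start = s, end = pmin(s + width, end))
}

#' Count read depth in bins
#'
#' @param alignments alignment data frame (pos, cigar)
#' @param bins bin intervals (see [make_bins()])
#' @param count one read increments every bin its alignment overlaps
#'   ("any_overlap", the 50 bp amplicon convention) or only the bin holding
#'   its start ("start", the one-bin-per-target capture convention)
#' @return integer vector of counts, one per bin
#' @export
bin_depths <- function(alignments, bins,
                       count = c("any_overlap", "start")) {
  count <- match.arg(count)
  assert_that(!is.unsorted(bins$start) &&
              all(bins$start[-1] >= head(bins$end, -1)),
              "bins must be sorted and non-overlapping")
  n <- nrow(bins)
  out <- integer(n)
  if (!nrow(alignments)) return(out)
  if (count == "start") {
    idx <- findInterval(alignments$pos, bins$start)
    ok <- idx >= 1L & alignments$pos < bins$end[pmax(idx, 1L)]
    t <- tabulate(idx[ok], nbins = n)
    return(as.integer(t))
  }
  ends <- alignment_end(alignments$pos, alignments$cigar)
  for (b in seq_len(n)) {
    out[b] <- sum(alignments$pos < bins$end[b] & ends > bins$start[b])
  }
  out
}

#' Two-stage median normalization of a depth matrix
#'
#' Stage one divides each sample's bin counts by that sample's median bin
#' depth; stage two divides each bin's values by the median of that bin
#' across samples. Bins whose cross-sample median is zero are masked (NA) and
#' recorded in the `masked_bins` attribute.
#'
#' When the matrix covers only a small target (e.g. the exon-11 sites alone),
#' an event spanning every bin would be absorbed into the stage-one median;
#' pass `sample_medians` computed over the whole panel (the sample's median
#' bin depth across all targets) to anchor stage one externally, as a
#' production pipeline does.
#'
#' @param dm a `DepthMatrix` (needs >= 3 samples so bin medians are a cohort
#'   statistic)
#' @param sample_medians optional named per-sample stage-one divisors
#' @return the `DepthMatrix` with `normalized` filled in
#' @export
normalize_depths <- function(dm, sample_medians = NULL) {
  assert_that(inherits(dm, "DepthMatrix"), "DepthMatrix required")
  assert_that(ncol(dm$raw) >= 3, "normalization needs at least 3 samples")
  sample_med <- if (is.null(sample_medians)) apply(dm$raw, 2, median) else
    sample_medians[dm$samples]
  assert_that(all(sample_med > 0), "a sample has zero median depth")
  stage1 <- sweep(dm$raw, 2, sample_med, "/")
  bin_med <- apply(stage1, 1, median)
  masked <- which(bin_med == 0)
  if (length(masked)) {
    message(sprintf("masking %d bin(s) with zero cross-sample median",
                    length(masked)))
    bin_med[masked] <- NA_real_
  }
  dm$normalized <- sweep(stage1, 1, bin_med, "/")
  attr(dm, "masked_bins") <- masked
  attr(dm, "sample_medians") <- sample_med
  attr(dm, "bin_medians") <- bin_med
  dm
}

# normalize one raw row against a cohort's stored normalization constants;
# sample_median can be anchored externally (e.g. panel-wide, or pre-injection)
normalize_row <- function(raw_row, bin_medians,
                          sample_median = median(raw_row)) {
  (raw_row / sample_median) / bin_medians
}

.cnv_hmm <- function(baseline, p_cnv, return_p = 0.1) {
  copies <- baseline + c(-1L, 0L, 1L)
  means <- copies / baseline
  log_trans <- matrix(-Inf, 3, 3)
  log_trans[2, ] <- log(c(p_cnv / 2, 1 - p_cnv, p_cnv / 2))
  log_trans[1, ] <- log(c(1 - return_p, return_p, 0))
  log_trans[3, ] <- log(c(0, return_p, 1 - return_p))
  log_init <- log(c(p_cnv / 2, 1 - p_cnv, p_cnv / 2))
  list(copies = copies, means = means, log_trans = log_trans,
       log_init = log_init)
}

#' Viterbi decoding of the copy-number HMM
#'
#' Three copy states (baseline - 1, baseline, baseline + 1) with Gaussian
#' emissions centered at copy/baseline. The probability of leaving the
#' baseline state is `p_cnv` (split over the two CNV states); CNV states
#' return to baseline with probability 0.1. Masked bins (NA) contribute no
#' emission.
#'
#' @param row normalized depth ratios (one sample)
#' @param baseline expected wild-type copy number (2 or 4)
#' @param p_cnv transition probability from wild type into a CNV state
#' @param sigma Gaussian emission standard deviation; scalar or per-bin
#' @return list with `states` (copy number per bin), `log_prob` of the best
#'   path, and `baseline_log_prob` of the all-baseline path
#' @export
cnv_viterbi <- function(row, baseline, p_cnv = 0.01, sigma = 0.05) {
  hmm <- .cnv_hmm(baseline, p_cnv)
  n <- length(row)
  sigma <- rep_len(sigma, n)
  emit <- function(t) {
    if (is.na(row[t])) return(c(0, 0, 0))
    stats::dnorm(row[t], hmm$means, sigma[t], log = TRUE)
  }
  v <- hmm$log_init + emit(1)
  ptr <- matrix(0L, nrow = max(n, 1), ncol = 3)
  if (n > 1) {
    for (t in 2:n) {
      e <- emit(t)
      cand <- v + hmm$log_trans  # [from, to]
      ptr[t, ] <- apply(cand, 2, which.max)
      v <- apply(cand, 2, max) + e
    }
  }
  best_end <- which.max(v)
  states <- integer(n)
  states[n] <- best_end
  if (n > 1) for (t in n:2) states[t - 1L] <- ptr[t, states[t]]
  base_lp <- hmm$log_init[2] +
    sum(vapply(seq_len(n), function(t) emit(t)[2], numeric(1))) +
    (n - 1) * hmm$log_trans[2, 2]
  list(states = hmm$copies[states], log_prob = max(v),
       baseline_log_prob = base_lp)
}

# log-probability of a fixed state path (states as copy numbers)
.cnv_path_logprob <- function(row, baseline, states, p_cnv = 0.01,
                              sigma = 0.05) {
  hmm <- .cnv_hmm(baseline, p_cnv)
  idx <- match(states, hmm$copies)
  n <- length(row)
  sigma <- rep_len(sigma, n)
  lp <- hmm$log_init[idx[1]]
  for (t in seq_len(n)) {
    if (!is.na(row[t]))
      lp <- lp + stats::dnorm(row[t], hmm$means[idx[t]], sigma[t], log = TRUE)
    if (t > 1) lp <- lp + hmm$log_trans[idx[t - 1L], idx[t]]
  }
  lp
}

#' Call copy-number events from one normalized depth row
#'
#' Viterbi-decodes the three-state HMM and merges contiguous non-baseline
#' states into one event per run. Each event's quality is the log-odds of the
#' decoded path against the same path with the event flattened to baseline;
#' events with quality below `q_min` (but a non-baseline Viterbi path) are
#' NO_CALL. When the whole path is baseline a single NEGATIVE record covering
#' the row is returned.
#'
#' @param row normalized depth ratios
#' @param baseline 2 or 4
#' @param p_cnv HMM wild-type-to-CNV transition probability
#' @param sigma emission standard deviation (scalar or per-bin)
#' @param q_min minimum log-odds for a confident CALL
#' @param bins optional bin data frame to report genomic intervals
#' @return data frame of `CnvCall` rows: bin_from, bin_to, start, end,
#'   baseline, called_copy, delta, quality, status
#' @export
call_cnv <- function(row, baseline, p_cnv = 0.01, sigma = 0.05, q_min = 3,
                     bins = NULL) {
  assert_that(baseline %in% c(2L, 4L), "baseline must be 2 or 4")
  if (length(row) < 2) stop("need at least 2 bins", call. = FALSE)
  vit <- cnv_viterbi(row, baseline, p_cnv, sigma)
  states <- vit$states
  r <- rle(states != baseline)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values)
  mkint <- function(b1, b2) {
    if (is.null(bins)) c(NA_real_, NA_real_) else
      c(bins$start[b1], bins$end[b2])
  }
  if (!length(ev)) {
    iv <- mkint(1L, length(row))
    return(data.frame(bin_from = 1L, bin_to = length(row), start = iv[1],
                      end = iv[2], baseline = baseline,
                      called_copy = baseline, delta = 0L, quality = 0,
                      status = "NEGATIVE", stringsAsFactors = FALSE))
  }
  out <- lapply(ev, function(k) {
    b1 <- starts[k]; b2 <- ends[k]
    copy <- states[b1]  # runs are single-state: no del<->dup transition
    flat <- states
    flat[b1:b2] <- baseline
    q <- .cnv_path_logprob(row, baseline, states, p_cnv, sigma) -
      .cnv_path_logprob(row, baseline, flat, p_cnv, sigma)
    iv <- mkint(b1, b2)
    data.frame(bin_from = b1, bin_to = b2, start = iv[1], end = iv[2],
               baseline = baseline, called_copy = copy,
               delta = copy - baseline, quality = q,
               status = if (q >= q_min) "CALL" else "NO_CALL",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exon-11 CNV calling on gene-partitioned depths
#'
#' Exon-11 copy number has a baseline of two because pseudogenic reads were
#' filtered out by distinguishing-base partitioning; depth is well defined
#' only at the distinguishing-site positions, so those act as the bins. The
#' site-by-sample matrix is normalized two-stage and the requested sample's
#' row decoded at baseline 2.
#'
#' @param dm `DepthMatrix` of gene-partitioned depths at reliable exon-11
#'   sites (sites x samples)
#' @param sample_id which sample to call
#' @param sample_medians optional per-sample stage-one divisors computed over
#'   the whole panel; required to see events spanning every site (see
#'   [normalize_depths()])
#' @param p_cnv,sigma,q_min see [call_cnv()]
#' @return data frame of CnvCall rows; a single NO_CALL row when fewer than
#'   two usable sites exist
#' @export
call_cnv_exon11 <- function(dm, sample_id, sample_medians = NULL,
                            p_cnv = 0.01, sigma = NULL, q_min = 3) {
  if (nrow(dm$raw) < 2) {
    return(data.frame(bin_from = NA_integer_, bin_to = NA_integer_,
                      start = NA_real_, end = NA_real_, baseline = 2L,
                      called_copy = NA_integer_, delta = NA_integer_,
                      quality = NA_real_, status = "NO_CALL",
                      stringsAsFactors = FALSE))
  }
  if (is.null(dm$normalized)) dm <- normalize_depths(dm, sample_medians)
  if (is.null(sigma)) sigma <- estimate_sigma(dm)
  row <- dm$normalized[, sample_id]
  call_cnv(row, baseline = 2L, p_cnv = p_cnv, sigma = sigma, q_min = q_min,
           bins = dm$bins)
}

#' Estimate the per-bin emission noise from a cohort
#'
#' Median absolute deviation of the normalized ratios per bin, floored to
#' avoid degenerate zero-noise bins; returns a per-bin vector.
#'
#' @param dm a normalized `DepthMatrix`
#' @param floor minimum sigma
#' @return numeric vector, one sigma per bin
#' @export
estimate_sigma <- function(dm, floor = 0.01) {
  assert_that(!is.null(dm$normalized), "normalize first")
  s <- apply(dm$normalized, 1, mad, na.rm = TRUE)
  pmax(s, floor)
}

#' Exhaustive path enumeration for the copy-number HMM
#'
#' Scores every possible state path (3^n for n bins) and returns the best;
#' the independent check that Viterbi decoding is exact on short rows.
#'
#' @param row normalized depth ratios (keep n small; 3^n paths)
#' @param baseline 2 or 4
#' @param p_cnv,sigma see [cnv_viterbi()]
#' @return list with `states` and `log_prob`
#' @export
cnv_enumerate <- function(row, baseline, p_cnv = 0.01, sigma = 0.05) {
  n <- length(row)
  assert_that(n <= 12, "enumeration limited to 12 bins")
  hmm <- .cnv_hmm(baseline, p_cnv)
  grid <- expand.grid(rep(list(hmm$copies), n))
  best <- -Inf; best_states <- NULL
  for (i in seq_len(nrow(grid))) {
    st <- as.integer(grid[i, ])
    lp <- .cnv_path_logprob(row, baseline, st, p_cnv, sigma)
    if (lp > best) { best <- lp; best_states <- st }
  }
  list(states = best_states, log_prob = best)
}
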