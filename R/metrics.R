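#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Central interval from beta-quantile inversion of the binomial tails:
#' `low = qbeta(a/2, k, n-k+1)`, `high = qbeta(1-a/2, k+1, n-k)`, with
#' `low = 0` when `k = 0` and `high = 1` when `k = n`.
#'
#' @param k number of successes (0..n)
#' @param n number of trials (>= 1)
#' @param level confidence level
#' @return numeric `c(low, high)` on the fraction scale
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n) {
    stop("invalid k/n for a Clopper-Pearson interval", call. = FALSE)
  }
  a <- 1 - level
  low <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  c(low = low, high = high)
}

rate_estimate <- function(k, n, level = 0.95, point = k / n) {
  ci <- clopper_pearson(k, n, level)
  structure(list(point = point, ci_low = ci[["low"]], ci_high = ci[["high"]],
                 level = level, n = n, k = k), class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  counts <- if (is.na(x$k)) sprintf("%d draws", x$n) else
    sprintf("%d/%d", x$k, x$n)
  cat(sprintf("%s (%s), %.0f%% CI %s-%s\n", fmt_pct1(x$point), counts,
              100 * x$level, fmt_pct1(x$ci_low), fmt_pct1(x$ci_high)))
  invisible(x)
}

#' Dosage-aware concordance matrix
#'
#' Compares tetraploid hybrid-capture dosages (0--4) against the combined
#' truth dosage from paired gene- and pseudogene-specific amplicons (each
#' 0--2, summed to 0--4). Cell classes: (0,0) true negative -- counted only at
#' sites polymorphic in the cohort; equal non-zero dosages true positive;
#' unequal non-zero dosages a permissible dosage error (presence detected,
#' copy count discordant); hybrid-only false positive; amplicon-only false
#' negative. Site/sample pairs where both calls are reference at a
#' non-polymorphic site are not evaluated.
#'
#' @param hybrid_calls data frame: site, sample, dosage (0..4)
#' @param gene_amplicon_calls data frame: site, sample, dosage (0..2)
#' @param pseudogene_amplicon_calls data frame: site, sample, dosage (0..2)
#' @param polymorphic_sites site ids at which true negatives are counted
#' @return a `ConcordanceMatrix`: 5x5 `cells` (hybrid dosage x combined
#'   dosage), class `counts` (tp, pde, fp, fn, tn) and `n_evaluated`
#' @export
concordance <- function(hybrid_calls, gene_amplicon_calls,
                        pseudogene_amplicon_calls, polymorphic_sites) {
  key <- function(d) paste(d$site, d$sample, sep = "\r")
  kh <- key(hybrid_calls); kg <- key(gene_amplicon_calls)
  kp <- key(pseudogene_amplicon_calls)
  if (!setequal(kh, kg) || !setequal(kh, kp)) {
    stop("site/sample sets differ between the three call sets", call. = FALSE)
  }
  assert_that(all(gene_amplicon_calls$dosage %in% 0:2) &&
              all(pseudogene_amplicon_calls$dosage %in% 0:2),
              "amplicon dosages must be diploid (0..2)")
  truth <- gene_amplicon_calls$dosage[match(kh, kg)] +
    pseudogene_amplicon_calls$dosage[match(kh, kp)]
  hyb <- hybrid_calls$dosage
  poly <- hybrid_calls$site %in% polymorphic_sites
  eval_pair <- poly | hyb > 0 | truth > 0
  hyb <- hyb[eval_pair]; truth <- truth[eval_pair]
  cells <- matrix(0L, 5, 5, dimnames = list(hybrid = 0:4, combined = 0:4))
  for (i in seq_along(hyb)) {
    cells[hyb[i] + 1L, truth[i] + 1L] <- cells[hyb[i] + 1L, truth[i] + 1L] + 1L
  }
  counts <- list(
    tn = cells[1, 1],
    tp = sum(diag(cells)[-1]),
    pde = sum(cells[-1, -1]) - sum(diag(cells)[-1]),
    fp = sum(cells[-1, 1]),
    fn = sum(cells[1, -1]))
  structure(list(cells = cells, counts = counts,
                 n_evaluated = sum(eval_pair)),
            class = "ConcordanceMatrix")
}

#' @export
print.ConcordanceMatrix <- function(x, ...) {
  cat("ConcordanceMatrix (hybrid dosage x combined amplicon dosage)\n")
  print(x$cells)
  cat(sprintf("TP %d | permissible dosage errors %d | FP %d | FN %d | TN %d\n",
              x$counts$tp, x$counts$pde, x$counts$fp, x$counts$fn,
              x$counts$tn))
  invisible(x)
}

#' Sensitivity and specificity with exact intervals
#'
#' Sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP), each with a
#' Clopper-Pearson interval. Permissible dosage errors detect the presence of
#' the alternate allele (they would trigger reflex testing and be corrected),
#' so by default they count toward sensitivity; with
#' `treat_permissible_as = "separate"` they are excluded and reported on
#' their own.
#'
#' @param x a `ConcordanceMatrix` or a list/vector with tp, fp, tn, fn (and
#'   optionally pde)
#' @param treat_permissible_as "TP" or "separate"
#' @param level confidence level
#' @return list with `sensitivity` and `specificity` `RateEstimate`s (NA
#'   rates where the denominator is zero) and `permissible_rate` when
#'   separate
#' @export
sens_spec <- function(x, treat_permissible_as = c("TP", "separate"),
                      level = 0.95) {
  treat_permissible_as <- match.arg(treat_permissible_as)
  cnt <- if (inherits(x, "ConcordanceMatrix")) x$counts else as.list(x)
  pde <- cnt$pde %||% 0
  tp <- cnt$tp; fp <- cnt$fp; tn <- cnt$tn; fn <- cnt$fn
  assert_that(all(c(tp, fp, tn, fn, pde) >= 0), "counts must be non-negative")
  if (treat_permissible_as == "TP") tp <- tp + pde
  mk <- function(k, n) if (n == 0) NA else rate_estimate(k, n, level)
  out <- list(sensitivity = mk(tp, tp + fn),
              specificity = mk(tn, tn + fp))
  if (treat_permissible_as == "separate") {
    out$permissible_rate <- if (tp + pde + fn > 0)
      rate_estimate(pde, tp + pde + fn, level) else NA
  }
  out
}

#' Allelic-dropout QC on amplicon calls
#'
#' Allelic dropout in a paralog-specific amplicon is suspected when no
#' heterozygous site is observed, or when every heterozygous site shows an
#' allele balance far below the expected 50%.
#'
#' @param het_balances numeric vector of allele balances at heterozygous
#'   sites (alt reads / depth)
#' @param threshold balance below which a het site looks dropped out
#' @return "pass", "dropout_suspected" or "review_no_hets"
#' @export
qc_allelic_dropout <- function(het_balances, threshold = 0.2) {
  het_balances <- het_balances[!is.na(het_balances)]
  if (!length(het_balances)) return("review_no_hets")
  if (all(het_balances < threshold)) return("dropout_suspected")
  "pass"
}
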