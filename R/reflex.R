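CLASSIFICATIONS <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic",
                     "Pathogenic")

#' Construct a variant record for the reflex engine
#'
#' @param variant_type "SNV", "indel" or "CNV"
#' @param location exon label: "11", "12", "13", "14" or "15"
#' @param classification five-tier classification: Benign, LikelyBenign, VUS,
#'   LikelyPathogenic or Pathogenic
#' @param cnv_status "CALL" or "NO_CALL" for CNVs, "n/a" otherwise
#' @return a `VariantRecord`
#' @export
variant_record <- function(variant_type, location, classification,
                           cnv_status = if (variant_type == "CNV") "CALL"
                                        else "n/a") {
  assert_that(variant_type %in% c("SNV", "indel", "CNV"),
              "unknown variant type")
  assert_that(as.character(location) %in% as.character(11:15),
              "location must be an exon label 11..15")
  if (!classification %in% CLASSIFICATIONS) {
    stop(sprintf("unknown classification '%s'", classification),
         call. = FALSE)
  }
  if (variant_type == "CNV") {
    assert_that(cnv_status %in% c("CALL", "NO_CALL"),
                "CNVs need cnv_status CALL or NO_CALL")
  } else {
    assert_that(cnv_status == "n/a", "cnv_status is n/a for SNVs and indels")
  }
  structure(list(variant_type = variant_type,
                 location = as.character(location),
                 classification = classification,
                 cnv_status = cnv_status), class = "VariantRecord")
}

#' Reflex decision for one variant
#'
#' The decision rules of the reflex workflow: benign and likely-benign
#' variants are neither reported nor reflexed; a CNV no-call is unresolved
#' and reflexes (configurable, since retesting usually resolves it); a
#' non-benign CNV anywhere in exons 11--15 reflexes; a non-benign SNV or
#' indel in exons 12--15 reflexes for disambiguation; the same variant in
#' exon 11 is reported without reflex because partitioned reads already
#' identify the gene copy.
#'
#' @param record a `VariantRecord`
#' @param reflex_on_nocall treat CNV no-calls as needing reflex (default) or
#'   as resolved-by-retest (no_report)
#' @return a `ReflexDecision` with `action` ("report_no_reflex", "reflex" or
#'   "no_report") and `reason`
#' @export
decide <- function(record, reflex_on_nocall = TRUE) {
  assert_that(inherits(record, "VariantRecord"), "VariantRecord required")
  mk <- function(action, reason) {
    structure(list(action = action, reason = reason),
              class = "ReflexDecision")
  }
  if (record$variant_type == "CNV" && record$cnv_status == "NO_CALL") {
    if (reflex_on_nocall) {
      return(mk("reflex", "CNV no-call is unresolved"))
    }
    return(mk("no_report", "CNV no-call resolved by retest"))
  }
  if (record$classification %in% c("Benign", "LikelyBenign")) {
    return(mk("no_report", "benign variants are neither reported nor reflexed"))
  }
  if (record$variant_type == "CNV") {
    return(mk("reflex", "non-benign CNV in the last five exons"))
  }
  if (record$location == "11") {
    return(mk("report_no_reflex",
              "exon-11 SNV/indel is unambiguous after read partitioning"))
  }
  mk("reflex", "non-benign SNV/indel in exons 12-15 needs disambiguation")
}

#' @export
print.ReflexDecision <- function(x, ...) {
  cat(sprintf("ReflexDecision: %s (%s)\n", x$action, x$reason))
  invisible(x)
}

#' Per-component reflex rates over a cohort
#'
#' Applies [decide()] to every variant and counts each sample at most once
#' per component: SNV/indel reflexes, confident CNV-call reflexes, and CNV
#' no-call reflexes. Component denominators may differ (e.g. only part of a
#' cohort is assessed for CNV no-calls), so they are supplied explicitly.
#'
#' @param variants data frame with columns sample_id, variant_type, location,
#'   classification and cnv_status ("n/a" for SNV/indel)
#' @param cohort_sizes named vector with denominators `snv_indel`,
#'   `cnv_call` and `cnv_nocall`
#' @param reflex_on_nocall see [decide()]
#' @return list of component rates (each with k, n, rate and percent to one
#'   decimal) plus `overall_percent`, the sum of component percents
#' @export
cohort_reflex_rate <- function(variants, cohort_sizes,
                               reflex_on_nocall = TRUE) {
  assert_that(all(c("snv_indel", "cnv_call", "cnv_nocall") %in%
                  names(cohort_sizes)), "cohort_sizes is missing components")
  if (is.null(variants) || nrow(variants) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  actions <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    rec <- variant_record(variants$variant_type[i], variants$location[i],
                          variants$classification[i], variants$cnv_status[i])
    actions[i] <- decide(rec, reflex_on_nocall)$action
  }
  reflexed <- actions == "reflex"
  comp <- function(sel, n) {
    k <- length(unique(variants$sample_id[sel & reflexed]))
    list(k = k, n = n, rate = k / n,
         percent = round_half_up(100 * k / n, 1))
  }
  is_cnv <- variants$variant_type == "CNV"
  out <- list(
    snv_indel = comp(!is_cnv, cohort_sizes[["snv_indel"]]),
    cnv_call = comp(is_cnv & variants$cnv_status == "CALL",
                    cohort_sizes[["cnv_call"]]),
    cnv_nocall = comp(is_cnv & variants$cnv_status == "NO_CALL",
                      cohort_sizes[["cnv_nocall"]]))
  out$overall_percent <- round_half_up(
    out$snv_indel$percent + out$cnv_call$percent + out$cnv_nocall$percent, 1)
  out
}

#' Extrapolate the overall reflex rate by posterior simulation
#'
#' Each observed component count (k, n) gets an independent
#' Beta(k + 1, n - k + 1) posterior (binomial likelihood, uniform prior); the
#' overall rate is the sum of the component rates, whose posterior is
#' estimated by Monte-Carlo draws (clipped at 1). Reported as the posterior
#' mean and central interval. Rates are scale-free under this beta-binomial
#' model, so the target cohort size affects only the framing, not the
#' estimate.
#'
#' @param components list of `c(k, n)` observed counts per component
#' @param cohort_size cohort size the estimate is extrapolated to
#' @param n_draws number of Monte-Carlo draws (>= 1e4)
#' @param seed integer seed
#' @param level central-interval level
#' @return a `RateEstimate` for the summed rate (point = posterior mean),
#'   with the draws' analytic mean in the `analytic_mean` attribute
#' @export
estimate_reflex_rate <- function(components, cohort_size = 13000,
                                 n_draws = 1e5, seed = 1, level = 0.95) {
  assert_that(n_draws >= 1e4, "n_draws must be >= 10^4")
  for (kn in components) {
    if (kn[1] > kn[2] || kn[1] < 0 || kn[2] < 1) {
      stop("invalid component counts (need 0 <= k <= n)", call. = FALSE)
    }
  }
  set.seed(seed)
  draws <- rowSums(vapply(components, function(kn) {
    rbeta(n_draws, kn[1] + 1, kn[2] - kn[1] + 1)
  }, numeric(n_draws)))
  draws <- pmin(draws, 1)
  q <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  est <- structure(list(point = mean(draws), ci_low = q[1], ci_high = q[2],
                        level = level, n = n_draws, k = NA_integer_,
                        cohort_size = cohort_size),
                   class = "RateEstimate")
  attr(est, "analytic_mean") <- sum(vapply(components, function(kn) {
    (kn[1] + 1) / (kn[2] + 2)
  }, numeric(1)))
  est
}
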