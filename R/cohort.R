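#' Simulate a cohort of sample genomes
#'
#' Each sample carries four haplotypes: two gene copies and two pseudogene
#' copies. Variants are drawn independently per haplotype from the site
#' frequency specification (Hardy-Weinberg within each paralog). Gene
#' conversion models population-level sequence exchange between the paralogs:
#' at each distinguishing base, every haplotype independently carries the
#' partner paralog's allele with the given probability, which is what erodes
#' a distinguishing base's reliability downstream.
#'
#' @param model a `ParalogLocusModel`
#' @param n_samples number of samples (>= 1)
#' @param site_frequency_spec optional data frame with columns `paralog`
#'   ("gene"/"pseudogene"), `pos` (0-based), `ref`, `alt`, `type`
#'   ("SNV"/"indel") and `freq` (allele frequency in \[0,1\])
#' @param gene_conversion_rate per-haplotype probability that a distinguishing
#'   base carries the partner allele; scalar or one value per distinguishing
#'   base (in `model$distinguishing_bases` row order)
#' @param seed integer seed
#' @return list of `SampleGenome` objects, each with `sample_id`,
#'   `haplotypes` (gene_h1, gene_h2, pseudo_h1, pseudo_h2 variant data frames
#'   with columns pos/ref/alt/type/converted) and `copy_events`
#' @export
generate_cohort <- function(model, n_samples, site_frequency_spec = NULL,
                            gene_conversion_rate = 0, seed = 1) {
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  sfs <- site_frequency_spec
  if (!is.null(sfs)) {
    assert_that(all(c("paralog", "pos", "ref", "alt", "type", "freq") %in%
                    names(sfs)), "site_frequency_spec is missing columns")
    if (any(sfs$freq < 0 | sfs$freq > 1))
      stop("site frequencies must lie in [0, 1]", call. = FALSE)
    assert_that(all(sfs$paralog %in% c("gene", "pseudogene")),
                "paralog must be 'gene' or 'pseudogene'")
    blocks <- region_span(model)
    for (i in seq_len(nrow(sfs))) {
      b <- blocks[blocks$copy == sfs$paralog[i], ]
      assert_that(sfs$pos[i] >= b$start && sfs$pos[i] < b$end,
                  "variant site outside its paralog region")
    }
  }
  db <- model$distinguishing_bases
  rate <- rep_len(gene_conversion_rate, max(1L, nrow(db)))
  assert_that(all(rate >= 0 & rate < 1),
              "gene_conversion_rate must lie in [0, 1)")

  set.seed(seed)
  hap_names <- c("gene_h1", "gene_h2", "pseudo_h1", "pseudo_h2")
  empty_var <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), type = character(0),
                          converted = logical(0), stringsAsFactors = FALSE)
  lapply(seq_len(n_samples), function(s) {
    haps <- lapply(hap_names, function(h) {
      paralog <- if (startsWith(h, "gene")) "gene" else "pseudogene"
      vars <- empty_var
      if (!is.null(sfs)) {
        mine <- sfs[sfs$paralog == paralog, , drop = FALSE]
        if (nrow(mine)) {
          keep <- runif(nrow(mine)) < mine$freq
          if (any(keep)) {
            vars <- data.frame(pos = mine$pos[keep], ref = mine$ref[keep],
                               alt = mine$alt[keep], type = mine$type[keep],
                               converted = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
      if (nrow(db)) {
        conv <- runif(nrow(db)) < rate
        if (any(conv)) {
          cv <- if (paralog == "gene") {
            data.frame(pos = db$gene_pos[conv], ref = db$gene_allele[conv],
                       alt = db$pseudo_allele[conv], type = "SNV",
                       converted = TRUE, stringsAsFactors = FALSE)
          } else {
            data.frame(pos = db$pseudo_pos[conv], ref = db$pseudo_allele[conv],
                       alt = db$gene_allele[conv], type = "SNV",
                       converted = TRUE, stringsAsFactors = FALSE)
          }
          vars <- rbind(vars, cv)
        }
      }
      vars <- vars[!duplicated(vars$pos), , drop = FALSE]
      vars[order(vars$pos), , drop = FALSE]
    })
    names(haps) <- hap_names
    structure(list(sample_id = sprintf("sample%04d", s),
                   haplotypes = haps,
                   copy_events = data.frame(paralog = character(0),
                                            exon_from = character(0),
                                            exon_to = character(0),
                                            delta = integer(0),
                                            haplotype = integer(0),
                                            stringsAsFactors = FALSE)),
              class = "SampleGenome")
  })
}

#' Add a copy-number event to a sample
#'
#' Registers a single-copy deletion or duplication of a contiguous exon span
#' on one haplotype of the chosen paralog. Read simulation honours the event:
#' fragments from a deleted span are absent from that haplotype; fragments in
#' a duplicated span are produced at twice the rate.
#'
#' @param sample a `SampleGenome`
#' @param paralog "gene" or "pseudogene"
#' @param exon_from,exon_to gene exon labels bounding the contiguous span
#' @param delta -1 (deletion) or +1 (duplication)
#' @param haplotype which haplotype of the paralog carries the event (1 or 2)
#' @return the modified `SampleGenome`
#' @export
add_cnv <- function(sample, paralog, exon_from, exon_to = exon_from,
                    delta, haplotype = 1L) {
  assert_that(paralog %in% c("gene", "pseudogene"), "unknown paralog")
  assert_that(delta %in% c(-1L, 1L), "delta must be -1 or +1")
  sample$copy_events <- rbind(sample$copy_events,
    data.frame(paralog = paralog, exon_from = as.character(exon_from),
               exon_to = as.character(exon_to), delta = as.integer(delta),
               haplotype = as.integer(haplotype), stringsAsFactors = FALSE))
  sample
}

#' Realized allele frequency in a cohort
#'
#' Counts haplotypes of one paralog carrying the given alternate allele at a
#' position, over 2n haplotypes.
#'
#' @param cohort list of `SampleGenome`
#' @param paralog "gene" or "pseudogene"
#' @param pos 0-based position
#' @param alt alternate allele
#' @return fraction in \[0,1\]
#' @export
cohort_allele_frequency <- function(cohort, paralog, pos, alt) {
  haps <- if (paralog == "gene") c("gene_h1", "gene_h2") else
    c("pseudo_h1", "pseudo_h2")
  k <- sum(vapply(cohort, function(s) {
    sum(vapply(haps, function(h) {
      v <- s$haplotypes[[h]]
      any(v$pos == pos & v$alt == alt)
    }, logical(1)))
  }, numeric(1)))
  k / (2 * length(cohort))
}

#' Idealized paralog-specific amplicon genotypes
#'
#' Reports, per sample, the two alleles carried by the requested paralog's
#' haplotypes at each candidate site -- the in-silico equivalent of genotyping
#' a gene- or pseudogene-specific long-range amplicon. Pseudogene genotypes
#' are reported at the homologous gene coordinate ("as aligned to the gene").
#'
#' @param cohort list of `SampleGenome`
#' @param model a `ParalogLocusModel`
#' @param paralog "gene" or "pseudogene"
#' @param sites data frame of candidate sites (columns `gene_pos`,
#'   `pseudo_pos`); defaults to the model's distinguishing bases
#' @return data frame with columns sample_id, site_id, allele1, allele2
#' @export
amplicon_genotypes <- function(cohort, model, paralog,
                               sites = model$distinguishing_bases) {
  sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  pos <- if (paralog == "gene") sites$gene_pos else sites$pseudo_pos
  ref_allele <- sc[pos + 1L]
  haps <- if (paralog == "gene") c("gene_h1", "gene_h2") else
    c("pseudo_h1", "pseudo_h2")
  out <- lapply(cohort, function(s) {
    al <- vapply(haps, function(h) {
      v <- s$haplotypes[[h]]
      ifelse(pos %in% v$pos, v$alt[match(pos, v$pos)], ref_allele)
    }, character(length(pos)))
    if (length(pos) == 1L) al <- matrix(al, nrow = 1L)
    data.frame(sample_id = s$sample_id,
               site_id = paste0("s", sites$gene_pos),
               allele1 = al[, 1L], allele2 = al[, 2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
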