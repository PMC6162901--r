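#' Build the distinguishing-base catalog
#'
#' A candidate site is reliable when the gene-specific amplicons are
#' homozygous for the gene (reference) allele and the pseudogene-specific
#' amplicons are homozygous for one single alternate allele, in 100% of
#' cohort samples. Any exchange of alleles between the paralogs, a third
#' allele, or a no-call genotype at the site breaks reliability.
#'
#' @param gene_amplicon_genotypes data frame (sample_id, site_id, allele1,
#'   allele2) from gene-specific amplicons; `NA` alleles are no-calls
#' @param pseudogene_amplicon_genotypes same, from pseudogene-specific
#'   amplicons, reported at the homologous gene coordinate
#' @param candidate_sites data frame with gene_pos, pseudo_pos, gene_allele,
#'   pseudo_allele and exon (e.g. a model's `distinguishing_bases`)
#' @return a `SiteCatalog` data frame: site_id, gene_pos, pseudo_pos,
#'   gene_allele, pseudo_allele, exon, reliable, gene_alt_freq,
#'   pseudogene_geneallele_freq, n_samples; per-exon reliable counts are in
#'   the `reliable_per_exon` attribute
#' @export
build_catalog <- function(gene_amplicon_genotypes,
                          pseudogene_amplicon_genotypes, candidate_sites) {
  g <- gene_amplicon_genotypes; p <- pseudogene_amplicon_genotypes
  assert_that(nrow(g) > 0 && nrow(p) > 0, "empty cohort")
  if (!setequal(unique(g$sample_id), unique(p$sample_id))) {
    stop("gene and pseudogene call sets cover different cohorts",
         call. = FALSE)
  }
  if (!setequal(unique(g$site_id), unique(p$site_id))) {
    stop("gene and pseudogene call sets cover different sites", call. = FALSE)
  }
  n_samples <- length(unique(g$sample_id))
  sites <- candidate_sites
  sites$site_id <- paste0("s", sites$gene_pos)
  assert_that(all(sites$site_id %in% g$site_id),
              "candidate sites missing from the genotype sets")

  res <- lapply(seq_len(nrow(sites)), function(i) {
    sid <- sites$site_id[i]
    ga <- c(g$allele1[g$site_id == sid], g$allele2[g$site_id == sid])
    pa <- c(p$allele1[p$site_id == sid], p$allele2[p$site_id == sid])
    nocall <- anyNA(ga) || anyNA(pa)
    gene_ok <- !nocall && all(ga == sites$gene_allele[i])
    pseudo_alleles <- unique(pa[!is.na(pa)])
    pseudo_ok <- !nocall && length(pseudo_alleles) == 1L &&
      pseudo_alleles != sites$gene_allele[i]
    data.frame(site_id = sid, gene_pos = sites$gene_pos[i],
               pseudo_pos = sites$pseudo_pos[i],
               gene_allele = sites$gene_allele[i],
               pseudo_allele = sites$pseudo_allele[i],
               exon = sites$exon[i],
               reliable = gene_ok && pseudo_ok,
               gene_alt_freq = mean(ga != sites$gene_allele[i], na.rm = TRUE),
               pseudogene_geneallele_freq =
                 mean(pa == sites$gene_allele[i], na.rm = TRUE),
               n_samples = n_samples, stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, res)
  class(catalog) <- c("SiteCatalog", "data.frame")
  attr(catalog, "reliable_per_exon") <-
    tapply(catalog$reliable, catalog$exon, sum)
  catalog
}

#' Fully reliable catalog straight from a locus model
#'
#' The catalog a cohort with no sequence exchange would produce: every
#' modelled distinguishing base reliable. Useful as truth for partitioning
#' tests and as the exon-11 site list.
#'
#' @param model a `ParalogLocusModel`
#' @return a `SiteCatalog`
#' @export
perfect_catalog <- function(model) {
  db <- model$distinguishing_bases
  catalog <- data.frame(site_id = paste0("s", db$gene_pos),
                        gene_pos = db$gene_pos, pseudo_pos = db$pseudo_pos,
                        gene_allele = db$gene_allele,
                        pseudo_allele = db$pseudo_allele, exon = db$exon,
                        reliable = TRUE, gene_alt_freq = 0,
                        pseudogene_geneallele_freq = 0, n_samples = 0L,
                        stringsAsFactors = FALSE)
  class(catalog) <- c("SiteCatalog", "data.frame")
  catalog
}

#' Allele-frequency table from amplicon genotypes
#'
#' Long-format table of per-paralog allele frequencies at the catalog sites:
#' counts over 2n haplotypes per paralog.
#'
#' @param catalog a `SiteCatalog`
#' @param gene_amplicon_genotypes,pseudogene_amplicon_genotypes genotype data
#'   frames as in [build_catalog()]
#' @return data frame: site, paralog, allele, frequency, n
#' @export
allele_frequency_table <- function(catalog, gene_amplicon_genotypes,
                                   pseudogene_amplicon_genotypes) {
  one <- function(g, paralog) {
    out <- lapply(unique(catalog$site_id), function(sid) {
      al <- c(g$allele1[g$site_id == sid], g$allele2[g$site_id == sid])
      n <- length(al) / 2
      al <- al[!is.na(al)]
      tab <- table(al)
      data.frame(site = sid, paralog = paralog, allele = names(tab),
                 frequency = as.numeric(tab) / (2 * n), n = n,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- rbind(one(gene_amplicon_genotypes, "gene"),
               one(pseudogene_amplicon_genotypes, "pseudogene"))
  rownames(res) <- NULL
  res
}

#' Write / read the allele-frequency table as TSV
#'
#' @param freqs data frame from [allele_frequency_table()]
#' @param path TSV path
#' @return the path / the data frame
#' @export
write_frequency_table <- function(freqs, path) {
  write.table(freqs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a site catalog as TSV
#'
#' @param catalog a `SiteCatalog`
#' @param path TSV path
#' @return the path / the catalog
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  catalog <- read.table(path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  class(catalog) <- c("SiteCatalog", "data.frame")
  catalog
}

#' Design capture probes avoiding variable positions
#'
#' Tiles every gene exon (plus padding) with probes of fixed length at the
#' given stride, skipping any window that overlaps a position known to differ
#' or vary between the paralogs (all catalog sites, reliable or not). Warns
#' when variable positions are so dense that part of an exon cannot be
#' tiled.
#'
#' @param model a `ParalogLocusModel`
#' @param catalog a `SiteCatalog` of variable positions
#' @param probe_len probe length in nt (40-mer capture oligos)
#' @param stride tiling stride in nt (50% overlap by default)
#' @return BED-style data frame: chrom, start, end, name
#' @export
design_probes <- function(model, catalog, probe_len = 40, stride = 20) {
  variable <- sort(unique(catalog$gene_pos))
  probes <- list()
  for (i in seq_len(nrow(model$gene_exons))) {
    ex <- model$gene_exons[i, ]
    lo <- ex$start - model$pad
    hi <- ex$end + model$pad
    starts <- seq(lo, hi - probe_len, by = stride)
    ok <- vapply(starts, function(s) {
      !any(variable >= s & variable < s + probe_len)
    }, logical(1))
    kept <- starts[ok]
    covered <- rep(FALSE, hi - lo)
    for (s in kept) covered[(s - lo + 1):(s - lo + probe_len)] <- TRUE
    if (!all(covered)) {
      gaps <- range(which(!covered)) + lo - 1L
      warning(sprintf(
        "exon %s: positions %d-%d cannot be tiled around variable sites",
        ex$label, gaps[1], gaps[2]))
    }
    if (length(kept)) {
      probes[[i]] <- data.frame(chrom = model$contig_name, start = kept,
                                end = kept + probe_len,
                                name = sprintf("probe_exon%s_%d", ex$label,
                                               seq_along(kept)),
                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, probes)
  rownames(res) <- NULL
  res
}
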