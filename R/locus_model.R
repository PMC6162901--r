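#' Generate a synthetic paralog locus
#'
#' Builds a contig containing a gene block and a near-identical pseudogene
#' block. Each block holds five exons; gene exons are labelled 11--15 and the
#' corresponding pseudogene exons 2--6 (so gene exon 12 pairs with pseudogene
#' exon 3, mirroring the PMS2 exon 12--15 / PMS2CL exon 3--6 correspondence).
#' The two blocks are byte-identical except at the requested distinguishing
#' bases, so the position homology map is a single constant-offset bijection
#' over the whole block.
#'
#' Sequence identity per exon is evaluated over the exon plus `pad` nt of
#' flanking intron on each side, the same padded window within which
#' distinguishing bases are placed.
#'
#' @param exon_lengths named integer vector of gene exon lengths
#'   (names "11".."15"); every exon must be at least `min_exon_length` nt.
#'   The default mimics the real locus shape: one large exon (the 26
#'   hg19-like differences at ~97% identity need ~900 nt) followed by four
#'   short ones.
#' @param n_distinguishing integer vector (recycled to 5) giving the number of
#'   distinguishing bases placed in each padded exon window; the default is
#'   the hg19-like configuration 26, 0, 1, 1, 0 for exons 11--15
#' @param identity_targets optional numeric vector of minimum per-exon
#'   identities in (0.9, 1]; an error is raised if a requested
#'   distinguishing-base count cannot satisfy its target
#' @param intron_length intron length between exons (nt)
#' @param pad intronic padding evaluated with each exon (nt)
#' @param flank unrelated sequence flanking the locus (nt); keep it at least
#'   half the longest sequencing fragment so fragment sampling is not clipped
#'   at the contig ends
#' @param spacer unrelated sequence between the two blocks (nt); must exceed
#'   half the longest fragment so a fragment from one paralog can never run
#'   into the other (the real paralogs are megabases apart)
#' @param min_exon_length minimum exon length accepted (reads must fit)
#' @param contig_name name of the synthetic contig
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical output
#' @return an object of class `ParalogLocusModel` with fields
#'   `contig_name`, `sequence`, `gene_exons`, `pseudogene_exons`,
#'   `homology` (gene_start, pseudo_start, length), `distinguishing_bases`,
#'   `identity_per_exon` and `pad`. All intervals are 0-based half-open.
#' @export
generate_locus <- function(exon_lengths = c(`11` = 880, `12` = 150,
                                            `13` = 150, `14` = 150,
                                            `15` = 150),
                           n_distinguishing = c(26, 0, 1, 1, 0),
                           identity_targets = NULL,
                           intron_length = 80, pad = 20,
                           flank = 650, spacer = 650,
                           min_exon_length = 115,
                           contig_name = "paralog_locus",
                           seed = 1) {
  assert_that(length(exon_lengths) == 5, "exactly five exons are modelled")
  assert_that(all(exon_lengths >= min_exon_length),
              sprintf("every exon must be >= %d nt", min_exon_length))
  assert_that(intron_length > 2 * pad,
              "introns must be longer than twice the padding")
  n_distinguishing <- rep_len(as.integer(n_distinguishing), 5L)
  assert_that(all(n_distinguishing >= 0), "n_distinguishing must be >= 0")

  span_len <- as.integer(exon_lengths) + 2L * pad
  implied_identity <- 1 - n_distinguishing / span_len
  if (!is.null(identity_targets)) {
    identity_targets <- rep_len(identity_targets, 5L)
    assert_that(all(identity_targets > 0.9 & identity_targets <= 1),
                "identity targets must lie in (0.9, 1]")
    bad <- implied_identity < identity_targets - 1e-9
    if (any(bad)) {
      stop(sprintf(
        "infeasible parameterization: exon %s cannot hold %d distinguishing bases at identity target %.3f",
        names(exon_lengths)[bad][1], n_distinguishing[bad][1],
        identity_targets[bad][1]), call. = FALSE)
    }
  }
  assert_that(all(implied_identity > 0.9),
              "infeasible parameterization: identity would fall below 0.9")

  set.seed(seed)
  gene_labels <- names(exon_lengths) %||% as.character(11:15)
  pseudo_labels <- as.character(2:6)

  # gene block: pad | exon | intron | ... | exon | pad
  block_len <- 2L * pad + sum(exon_lengths) + 4L * intron_length
  gene_start <- flank
  pseudo_start <- flank + block_len + spacer
  total_len <- 2L * flank + 2L * block_len + spacer

  block <- random_dna(block_len)
  seq_chars <- strsplit(paste0(random_dna(flank), block,
                               random_dna(spacer), block,
                               random_dna(flank)),
                        "", fixed = TRUE)[[1]]

  # exon intervals (0-based half-open, absolute contig coordinates)
  starts <- gene_start + pad +
    cumsum(c(0L, (as.integer(exon_lengths) + intron_length)[1:4]))
  gene_exons <- data.frame(label = gene_labels, start = starts,
                           end = starts + as.integer(exon_lengths),
                           stringsAsFactors = FALSE)
  offset <- pseudo_start - gene_start
  pseudogene_exons <- data.frame(label = pseudo_labels,
                                 start = gene_exons$start + offset,
                                 end = gene_exons$end + offset,
                                 stringsAsFactors = FALSE)

  # distinguishing bases inside padded exon windows; pseudogene base mutated
  db <- vector("list", 5L)
  for (i in seq_len(5L)) {
    k <- n_distinguishing[i]
    if (k == 0L) next
    win <- seq.int(gene_exons$start[i] - pad, gene_exons$end[i] + pad - 1L)
    pos <- sort(sample(win, k))
    g_allele <- seq_chars[pos + 1L]
    p_allele <- vapply(g_allele, substitute_base, character(1),
                       USE.NAMES = FALSE)
    seq_chars[pos + offset + 1L] <- p_allele
    db[[i]] <- data.frame(gene_pos = pos, pseudo_pos = pos + offset,
                          gene_allele = g_allele, pseudo_allele = p_allele,
                          exon = gene_labels[i], stringsAsFactors = FALSE)
  }
  db <- if (all(vapply(db, is.null, logical(1)))) {
    data.frame(gene_pos = integer(0), pseudo_pos = integer(0),
               gene_allele = character(0), pseudo_allele = character(0),
               exon = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, db[!vapply(db, is.null, logical(1))])
  rownames(db) <- NULL

  model <- structure(list(
    contig_name = contig_name,
    sequence = paste(seq_chars, collapse = ""),
    gene_exons = gene_exons,
    pseudogene_exons = pseudogene_exons,
    homology = list(gene_start = gene_start, pseudo_start = pseudo_start,
                    length = block_len),
    distinguishing_bases = db,
    identity_per_exon = data.frame(exon = gene_labels,
                                   identity = implied_identity,
                                   stringsAsFactors = FALSE),
    pad = pad,
    seed = seed
  ), class = "ParalogLocusModel")
  validate_locus_model(model)
  model
}

#' Validate a ParalogLocusModel
#'
#' Checks the structural invariants: exon pairs have equal length, intervals
#' are sorted and non-overlapping, every distinguishing base lies inside the
#' homology map with differing alleles that match the stored sequence, and the
#' stored per-exon identity equals the identity recomputed from the sequence
#' over the padded exon window.
#'
#' @param model a `ParalogLocusModel`
#' @return invisibly `TRUE`; stops on violation
#' @export
validate_locus_model <- function(model) {
  ge <- model$gene_exons; pe <- model$pseudogene_exons
  assert_that(all(ge$end - ge$start == pe$end - pe$start),
              "paired exons must have equal length")
  assert_that(!is.unsorted(ge$start) && all(ge$start[-1] >= head(ge$end, -1)),
              "gene exons must be sorted and non-overlapping")
  assert_that(!is.unsorted(pe$start) && all(pe$start[-1] >= head(pe$end, -1)),
              "pseudogene exons must be sorted and non-overlapping")
  h <- model$homology
  db <- model$distinguishing_bases
  if (nrow(db)) {
    assert_that(all(db$gene_pos >= h$gene_start &
                    db$gene_pos < h$gene_start + h$length),
                "distinguishing bases must lie in the homology map")
    assert_that(all(db$pseudo_pos - db$gene_pos ==
                    h$pseudo_start - h$gene_start),
                "distinguishing bases must respect the homology bijection")
    assert_that(all(db$gene_allele != db$pseudo_allele),
                "distinguishing bases must have differing alleles")
    sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
    assert_that(all(sc[db$gene_pos + 1L] == db$gene_allele) &&
                all(sc[db$pseudo_pos + 1L] == db$pseudo_allele),
                "distinguishing-base alleles must match the sequence")
  }
  # recompute identity over padded exon windows
  sc <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  off <- h$pseudo_start - h$gene_start
  for (i in seq_len(nrow(ge))) {
    win <- seq.int(ge$start[i] - model$pad, ge$end[i] + model$pad - 1L)
    ident <- mean(sc[win + 1L] == sc[win + off + 1L])
    assert_that(abs(ident - model$identity_per_exon$identity[i]) < 1e-9,
                "stored identity must equal identity recomputed from sequence")
  }
  invisible(TRUE)
}

#' Map positions between the paralogs
#'
#' Translates 0-based contig positions across the constant-offset homology
#' bijection. Positions outside the homologous span raise an error.
#'
#' @param model a `ParalogLocusModel`
#' @param pos integer vector of 0-based positions
#' @return integer vector of partner-paralog positions
#' @export
gene_to_pseudo <- function(model, pos) {
  h <- model$homology
  assert_that(all(pos >= h$gene_start & pos < h$gene_start + h$length),
              "position outside the homologous span")
  pos + (h$pseudo_start - h$gene_start)
}

#' @rdname gene_to_pseudo
#' @export
pseudo_to_gene <- function(model, pos) {
  h <- model$homology
  assert_that(all(pos >= h$pseudo_start & pos < h$pseudo_start + h$length),
              "position outside the homologous span")
  pos - (h$pseudo_start - h$gene_start)
}

#' Exon span helpers
#'
#' `gene_exon_span()` returns the 0-based half-open interval covering the
#' requested gene exon labels (plus optional padding); `region_span()` gives
#' the two paralog block spans used for read pairing.
#'
#' @param model a `ParalogLocusModel`
#' @param labels character vector of gene exon labels ("11".."15")
#' @param pad extra padding in nt
#' @return a numeric `c(start, end)` interval
#' @export
gene_exon_span <- function(model, labels, pad = 0) {
  ge <- model$gene_exons[model$gene_exons$label %in% labels, ]
  assert_that(nrow(ge) > 0, "unknown exon label")
  c(min(ge$start) - pad, max(ge$end) + pad)
}

#' @rdname gene_exon_span
#' @export
region_span <- function(model) {
  h <- model$homology
  data.frame(copy = c("gene", "pseudogene"),
             start = c(h$gene_start, h$pseudo_start),
             end = c(h$gene_start + h$length, h$pseudo_start + h$length),
             stringsAsFactors = FALSE)
}

#' @export
print.ParalogLocusModel <- function(x, ...) {
  cat("ParalogLocusModel:", x$contig_name, "--", nchar(x$sequence), "nt\n")
  cat("  gene exons:", paste(x$gene_exons$label, collapse = ", "),
      " pseudogene exons:", paste(x$pseudogene_exons$label, collapse = ", "),
      "\n")
  cat("  distinguishing bases:", nrow(x$distinguishing_bases), "\n")
  cat("  identity per exon:",
      paste(sprintf("%s=%.3f", x$identity_per_exon$exon,
                    x$identity_per_exon$identity), collapse = " "), "\n")
  invisible(x)
}

#' Write the locus reference as FASTA
#'
#' @param model a `ParalogLocusModel`
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
write_locus_fasta <- function(model, path) {
  s <- Biostrings::DNAStringSet(structure(model$sequence,
                                          names = model$contig_name))
  Biostrings::writeXStringSet(s, filepath = path)
  invisible(path)
}

#' Read a FASTA reference
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  structure(as.character(s), names = names(s))
}

#' Write exon annotations as BED
#'
#' Emits one BED line per exon of both paralogs (0-based half-open, as BED
#' requires).
#'
#' @param model a `ParalogLocusModel`
#' @param path output path
#' @return the path, invisibly
#' @export
write_exon_bed <- function(model, path) {
  bed <- rbind(
    data.frame(chrom = model$contig_name, start = model$gene_exons$start,
               end = model$gene_exons$end,
               name = paste0("gene_exon_", model$gene_exons$label)),
    data.frame(chrom = model$contig_name,
               start = model$pseudogene_exons$start,
               end = model$pseudogene_exons$end,
               name = paste0("pseudogene_exon_", model$pseudogene_exons$label)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dump / load a locus model as JSON
#'
#' @param model a `ParalogLocusModel`
#' @param path JSON path
#' @return `locus_to_json()` the path; `locus_from_json()` the model
#' @export
locus_to_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname locus_to_json
#' @export
locus_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$homology <- as.list(x$homology)
  model <- structure(x, class = "ParalogLocusModel")
  validate_locus_model(model)
  model
}
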