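#' Consensus base for one genotype
#'
#' Converts a diploid-style mitochondrial genotype to a single haploid base.
#' Homoplasmic genotypes map directly to their allele's base. Heteroplasmic
#' genotypes take the allele with the higher read depth; a REF/ALT depth tie
#' takes the ALT base (avoiding reference bias), and an ALT/ALT depth tie
#' takes the higher allele index (with a warning, since this case is not
#' covered by the REF-avoidance rationale).
#'
#' @param gt genotype string, e.g. \code{"0/1"}; must be non-missing.
#' @param allele_depths integer vector of per-allele depths (REF first).
#' @param ref REF allele (single base).
#' @param alts character vector of ALT alleles.
#' @return a single base.
#' @export
call_consensus_base <- function(gt, allele_depths, ref, alts) {
  if (is_missing_gt(gt)) stop("missing genotype cannot be consensus-called")
  a <- as.integer(strsplit(gt, "[/|]")[[1]])
  alleles <- c(ref, alts)
  if (a[1] == a[2]) return(alleles[a[1] + 1L])
  d <- allele_depths[a + 1L]
  if (any(is.na(d)))
    stop("heteroplasmic genotype without allele depths: ", gt)
  if (d[1] != d[2]) return(alleles[a[which.max(d)] + 1L])
  if (min(a) == 0) return(alleles[max(a) + 1L])  # REF/ALT tie -> ALT
  warning("ALT/ALT allele-depth tie (", gt, "); choosing higher allele index")
  alleles[max(a) + 1L]
}

#' Build per-animal variant sequences from a filtered table
#'
#' One base per retained site per animal, using the rules of
#' \code{\link{call_consensus_base}}. The input must already be free of
#' missing genotypes and INDELs (the QC contract).
#'
#' @param table a filtered \code{mito_table}.
#' @return object of class \code{variant_seqs}: list with \code{bases}
#'   (animals x sites character matrix), \code{positions}, \code{ref}
#'   (REF base per site) and \code{animals}.
#' @export
build_variant_sequences <- function(table) {
  stopifnot(inherits(table, "mito_table"))
  if (any(is_missing_gt(table$gt)))
    stop("table contains missing genotypes; run drop_indels_and_missing first")
  if (any(site_is_indel(table)))
    stop("table contains INDELs; run drop_indels_and_missing first")
  S <- n_sites(table)
  N <- n_animals(table)
  p <- parse_gt(table$gt)
  bases <- matrix("", N, S, dimnames = list(animal_ids(table), NULL))
  alt_tie <- 0L
  for (i in seq_len(S)) {
    alleles <- site_alleles(table, i)
    a1 <- p$a1[i, ]; a2 <- p$a2[i, ]
    res <- alleles[a1 + 1L]
    het <- which(a1 != a2)
    if (length(het)) {
      adv <- parse_ad(table$ad[i, het])
      for (k in seq_along(het)) {
        j <- het[k]
        d <- adv[[k]][c(a1[j], a2[j]) + 1L]
        if (any(is.na(d)))
          stop("heteroplasmic genotype without allele depths at position ",
               table$sites$pos[i], ", animal ", animal_ids(table)[j])
        if (d[1] > d[2]) res[j] <- alleles[a1[j] + 1L]
        else if (d[2] > d[1]) res[j] <- alleles[a2[j] + 1L]
        else {
          hi <- max(a1[j], a2[j])
          res[j] <- alleles[hi + 1L]
          if (min(a1[j], a2[j]) > 0) alt_tie <- alt_tie + 1L
        }
      }
    }
    bases[, i] <- res
  }
  if (alt_tie > 0)
    warning(alt_tie, " ALT/ALT allele-depth tie(s) resolved to the higher allele index")
  structure(list(bases = bases, positions = table$sites$pos,
                 ref = table$sites$ref, animals = animal_ids(table)),
            class = "variant_seqs")
}

#' @export
print.variant_seqs <- function(x, ...) {
  cat(sprintf("variant_seqs: %d animals x %d variant positions\n",
              nrow(x$bases), ncol(x$bases)))
  invisible(x)
}

#' Variant sequences as character strings
#'
#' @param x a \code{variant_seqs}.
#' @param ... unused.
#' @return named character vector, one concatenated-base string per animal.
#' @export
as.character.variant_seqs <- function(x, ...) {
  stats::setNames(apply(x$bases, 1, paste, collapse = ""), x$animals)
}

#' Expand variant sequences to full-length N-filled sequences
#'
#' Places each animal's bases at the 1-based variant positions of a
#' reference-length sequence and fills every non-variant position with N
#' (the format traditional haplogrouping tools require).
#'
#' @param vs a \code{variant_seqs} (or a character matrix with positions
#'   supplied explicitly).
#' @param reference_length full reference length (bp), default 16340.
#' @param positions 1-based variant positions; defaults to
#'   \code{vs$positions}.
#' @return \code{Biostrings::DNAStringSet}, one record per animal, each of
#'   width \code{reference_length}.
#' @export
expand_to_full_sequences <- function(vs, reference_length = 16340L,
                                     positions = NULL) {
  if (inherits(vs, "variant_seqs")) {
    bases <- vs$bases
    if (is.null(positions)) positions <- vs$positions
  } else bases <- vs
  if (is.null(positions)) stop("positions must be supplied")
  if (length(positions) != ncol(bases))
    stop("positions length must match the number of variant columns")
  if (length(positions) && max(positions) > reference_length)
    stop("variant position exceeds reference_length")
  out <- vapply(seq_len(nrow(bases)), function(i) {
    s <- rep("N", reference_length)
    s[positions] <- bases[i, ]
    paste(s, collapse = "")
  }, character(1))
  res <- Biostrings::DNAStringSet(out)
  names(res) <- rownames(bases)
  res
}

#' Write full-length N-filled FASTA
#'
#' @param vs a \code{variant_seqs}.
#' @param path output FASTA path.
#' @param reference_length full reference length (bp).
#' @return the path, invisibly.
#' @export
write_full_fasta <- function(vs, path, reference_length = 16340L) {
  seqs <- expand_to_full_sequences(vs, reference_length)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Write variant-positions FASTA and the positions file
#'
#' @param vs a \code{variant_seqs}.
#' @param fasta_path output FASTA of variant-position bases.
#' @param positions_path optional TSV (index, pos, ref) describing columns.
#' @return the fasta path, invisibly.
#' @export
write_variant_fasta <- function(vs, fasta_path, positions_path = NULL) {
  seqs <- Biostrings::DNAStringSet(as.character(vs))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60)
  if (!is.null(positions_path))
    utils::write.table(data.frame(index = seq_along(vs$positions),
                                  pos = vs$positions, ref = vs$ref),
                       positions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta_path)
}
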