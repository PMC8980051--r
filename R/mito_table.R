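#' Construct a mitochondrial variant table
#'
#' The central container of the package: per-site records (1-based position,
#' REF, ALT alleles, QUAL, MQ) together with per-animal genotypes, per-allele
#' read depths (AD) and total depth (DP) in diploid-style encoding
#' (\code{"0/1"}, \code{"./."}), as produced by joint variant calling of
#' short reads against a mitochondrial reference.
#'
#' @param sites data.frame with columns \code{pos} (1-based, strictly
#'   increasing), \code{ref}, \code{alt} (comma-separated alternate alleles),
#'   \code{qual}, \code{mq}.
#' @param gt character matrix, sites x animals, entries like \code{"0/1"} or
#'   \code{"./."}; column names are animal ids.
#' @param ad character matrix of per-allele depths (\code{"12,3"}), same
#'   shape as \code{gt}; \code{"."} where absent.
#' @param dp numeric matrix of total read depth per genotype.
#'
#' @return An object of class \code{mito_table}.
#' @export
mito_table <- function(sites, gt, ad, dp) {
  stopifnot(is.data.frame(sites),
            all(c("pos", "ref", "alt", "qual", "mq") %in% names(sites)))
  if (nrow(sites) != nrow(gt)) stop("sites and gt disagree on site count")
  if (is.null(colnames(gt))) stop("gt must carry animal ids as column names")
  if (!identical(dim(gt), dim(ad)) || !identical(dim(gt), dim(dp)))
    stop("gt, ad and dp must have identical dimensions")
  if (is.unsorted(sites$pos, strictly = TRUE))
    stop("site positions must be strictly increasing")
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, ad = ad, dp = dp),
            class = "mito_table")
}

#' @export
print.mito_table <- function(x, ...) {
  cat(sprintf("mito_table: %d sites x %d animals\n", n_sites(x), n_animals(x)))
  cat(sprintf("  positions %d..%d; %d site(s) with missing genotypes; %d INDEL site(s)\n",
              min(x$sites$pos), max(x$sites$pos),
              sum(apply(is_missing_gt(x$gt), 1, any)),
              sum(site_is_indel(x))))
  invisible(x)
}

#' @rdname mito_table
#' @param x a \code{mito_table}
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname mito_table
#' @export
n_animals <- function(x) ncol(x$gt)

#' @rdname mito_table
#' @export
animal_ids <- function(x) colnames(x$gt)

# alleles of site i as character vector c(REF, ALT1, ALT2, ...)
site_alleles <- function(x, i) {
  alt <- x$sites$alt[i]
  if (is.na(alt) || alt == "" || alt == ".") return(x$sites$ref[i])
  c(x$sites$ref[i], strsplit(alt, ",", fixed = TRUE)[[1]])
}

site_is_indel <- function(x) {
  ref_len <- nchar(x$sites$ref)
  alt_max <- vapply(strsplit(x$sites$alt, ",", fixed = TRUE),
                    function(a) if (length(a) == 0) 1L else max(nchar(a)),
                    integer(1))
  ref_len != 1L | alt_max != 1L
}

is_missing_gt <- function(gt) {
  gt == "./." | gt == ".|." | gt == "." | is.na(gt)
}

# parse a genotype matrix into two integer allele-index matrices
parse_gt <- function(gt) {
  d <- dim(gt)
  parts <- strsplit(as.vector(gt), "[/|]")
  a1 <- vapply(parts, function(p) {
    if (length(p) < 1 || p[1] == ".") NA_integer_ else as.integer(p[1])
  }, integer(1))
  a2 <- vapply(parts, function(p) {
    if (length(p) < 2 || p[2] == ".") NA_integer_ else as.integer(p[2])
  }, integer(1))
  list(a1 = matrix(a1, d[1], d[2], dimnames = dimnames(gt)),
       a2 = matrix(a2, d[1], d[2], dimnames = dimnames(gt)))
}

# heteroplasmic genotype: two differing allele indices
is_heteroplasmic <- function(gt) {
  p <- parse_gt(gt)
  h <- p$a1 != p$a2
  h[is.na(h)] <- FALSE
  h
}

# AD string matrix -> list of integer vectors
parse_ad <- function(ad) {
  lapply(strsplit(as.vector(ad), ",", fixed = TRUE), function(v) {
    if (length(v) == 1 && (v == "." || is.na(v))) return(NA_integer_)
    suppressWarnings(as.integer(v))
  })
}

subset_table <- function(x, sites = NULL, animals = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(x)) else sites
  ai <- if (is.null(animals)) seq_len(n_animals(x)) else animals
  mito_table(x$sites[si, , drop = FALSE],
             x$gt[si, ai, drop = FALSE],
             x$ad[si, ai, drop = FALSE],
             x$dp[si, ai, drop = FALSE])
}

#' Read a multi-sample mitochondrial VCF into a mito_table
#'
#' Uses \pkg{vcfR} to parse a VCFv4.x file with FORMAT fields GT, AD and DP
#' and an INFO MQ tag (falling back to a FORMAT MQ or NA when absent).
#'
#' @param path path to a .vcf or .vcf.gz file.
#' @return a \code{mito_table}.
#' @export
read_mito_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- fix[, "INFO"]
  mq <- suppressWarnings(as.numeric(sub(".*(?:^|;)MQ=([0-9.eE+-]+).*", "\\1",
                                        info)))
  mq[!grepl("(^|;)MQ=", info)] <- NA_real_
  sites <- data.frame(pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      qual = qual,
                      mq = mq,
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dpc <- vcfR::extract.gt(v, element = "DP")
  dp <- suppressWarnings(matrix(as.numeric(dpc), nrow(dpc), ncol(dpc),
                                dimnames = dimnames(dpc)))
  gt[is.na(gt)] <- "./."
  ad[is.na(ad)] <- "."
  dimnames(gt) <- list(NULL, colnames(v@gt)[-1])
  dimnames(ad) <- dimnames(dp) <- dimnames(gt)
  mito_table(sites, gt, ad, dp)
}

#' Write a mito_table as a VCFv4.2 text file
#'
#' Emits a plain-text VCF (single contig, FORMAT GT:AD:DP, INFO MQ) that
#' round-trips through \code{\link{read_mito_vcf}}. Deterministic: identical
#' tables give byte-identical files.
#'
#' @param x a \code{mito_table}.
#' @param path output path.
#' @param contig contig name written in the header and CHROM column.
#' @param contig_length contig length for the header, or NULL to omit.
#' @export
write_mito_vcf <- function(x, path, contig = "MT", contig_length = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_length))
             sprintf("##contig=<ID=%s,length=%d>", contig, contig_length)
           else sprintf("##contig=<ID=%s>", contig),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", animal_ids(x)), collapse = "\t"))
  dpc <- matrix(as.character(as.integer(round(x$dp))), nrow(x$dp), ncol(x$dp))
  dpc[is.na(dpc)] <- "."
  cells <- matrix(paste(x$gt, x$ad, dpc, sep = ":"), nrow(x$gt), ncol(x$gt))
  body <- vapply(seq_len(n_sites(x)), function(i) {
    paste(c(contig, x$sites$pos[i], ".", x$sites$ref[i], x$sites$alt[i],
            sprintf("%.2f", x$sites$qual[i]), "PASS",
            sprintf("MQ=%.2f", x$sites$mq[i]), "GT:AD:DP",
            cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the animal metadata table
#'
#' Tab-separated metadata with columns \code{animal_id, breed, country, sex,
#' tissue}. Sex is coded M/F/U and tissue is free text with
#' \code{"unknown"} for unrecorded tissue.
#'
#' @param path file path.
#' @return data.frame with the five metadata columns.
#' @export
read_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("animal_id", "breed", "country", "sex", "tissue")
  if (!all(need %in% names(m)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  m[need]
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tissue-contamination groups for heteroplasmy screening
#'
#' Splits animals into the two groups used when screening for NUMT-driven
#' heteroplasmy: the Semen group (males whose DNA came from semen or from an
#' unknown tissue, where low mitochondrial copy number makes NUMT reads hard
#' to distinguish) and the Non-semen group (females, and males sampled from a
#' known tissue other than semen).
#'
#' @param meta metadata data.frame (see \code{\link{read_metadata}}).
#' @return character vector "semen"/"non_semen" named by animal id.
#' @export
tissue_group <- function(meta) {
  sex <- toupper(meta$sex)
  tis <- tolower(meta$tissue)
  female <- sex == "F"
  known_other <- !(tis %in% c("semen", "unknown", "", NA))
  g <- ifelse(female | known_other, "non_semen", "semen")
  names(g) <- meta$animal_id
  g
}
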