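# ---- sequence containers ---------------------------------------------------

# coerce variant_seqs / character vector / matrix to animals x sites char matrix
as_base_matrix <- function(x) {
  if (inherits(x, "variant_seqs")) return(x$bases)
  if (is.matrix(x)) return(x)
  if (is.character(x)) {
    if (length(unique(nchar(x))) != 1)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    return(m)
  }
  if (inherits(x, "DNAStringSet")) return(as_base_matrix(as.character(x)))
  stop("cannot interpret input as sequences")
}

#' Pairwise nucleotide-difference matrix
#'
#' Counts mismatching positions for every pair of equal-length sequences,
#' excluding positions where either sequence has N (pairwise deletion).
#'
#' @param x a \code{variant_seqs}, character vector of sequences, DNAStringSet
#'   or animals x sites character matrix.
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_difference_matrix <- function(x) {
  m <- as_base_matrix(x)
  n <- nrow(m)
  isn <- m == "N"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    mi <- m[i, ]; ni <- isn[i, ]
    for (j in (i + 1):n) {
      cmp <- !(ni | isn[j, ])
      d[i, j] <- d[j, i] <- sum(mi[cmp] != m[j, cmp])
    }
  }
  d
}

#' Nucleotide diversity and mean pairwise difference
#'
#' k is the mean number of pairwise nucleotide differences over all unordered
#' sequence pairs; nucleotide diversity is pi = k / L.
#'
#' @param x sequences (see \code{\link{pairwise_difference_matrix}}), or a
#'   precomputed difference matrix.
#' @param L number of sites the differences refer to; defaults to the
#'   sequence length.
#' @return list with \code{k}, \code{pi}, \code{n}, \code{L} and
#'   \code{segregating_sites} (NA when only a matrix was supplied).
#' @export
nucleotide_diversity <- function(x, L = NULL) {
  if (is.matrix(x) && is.numeric(x)) {
    d <- x
    if (is.null(L)) stop("L must be given with a precomputed matrix")
    S <- NA_integer_
  } else {
    m <- as_base_matrix(x)
    if (is.null(L)) L <- ncol(m)
    d <- pairwise_difference_matrix(m)
    S <- sum(vapply(seq_len(ncol(m)), function(j) {
      b <- m[, j]; b <- b[b != "N"]
      length(unique(b)) > 1
    }, logical(1)))
  }
  n <- nrow(d)
  if (n < 2) stop("need at least two sequences")
  k <- mean(d[upper.tri(d)])
  list(k = k, pi = k / L, n = n, L = L, segregating_sites = S)
}

#' Exact-match haplotype classes
#'
#' Groups sequences into equivalence classes by exact sequence equality and
#' counts singleton classes.
#'
#' @param x sequences (see \code{\link{pairwise_difference_matrix}}).
#' @param metadata optional metadata for breed/country composition of shared
#'   classes.
#' @return list: \code{class_id} (integer per animal), \code{sizes},
#'   \code{n_haplotypes}, \code{n_singletons}, \code{composition} (data.frame
#'   per class, with breeds/countries when metadata given).
#' @export
haplotype_classes <- function(x, metadata = NULL) {
  m <- as_base_matrix(x)
  key <- apply(m, 1, paste, collapse = "")
  f <- factor(key, levels = unique(key))
  class_id <- as.integer(f)
  names(class_id) <- rownames(m)
  sizes <- as.integer(table(f))
  comp <- data.frame(class = seq_along(sizes), size = sizes)
  if (!is.null(metadata) && !is.null(rownames(m))) {
    idx <- match(rownames(m), metadata$animal_id)
    comp$breeds <- vapply(seq_along(sizes), function(k)
      paste(sort(unique(metadata$breed[idx[class_id == k]])), collapse = ","),
      character(1))
    comp$countries <- vapply(seq_along(sizes), function(k)
      paste(sort(unique(metadata$country[idx[class_id == k]])),
            collapse = ","), character(1))
  }
  list(class_id = class_id, sizes = sizes,
       n_haplotypes = length(sizes),
       n_singletons = sum(sizes == 1L),
       composition = comp)
}

#' Haplotype diversity (Hd) and its sampling SD
#'
#' Hd = n (1 - sum p_i^2) / (n - 1), the probability that two randomly drawn
#' sequences carry different haplotypes. The SD uses Nei's (1987, eq. 8.12)
#' large-sample variance:
#' V = 2/(n(n-1)) * ( 2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2 ).
#'
#' @param class_sizes integer vector of haplotype class sizes.
#' @param n total number of sequences; must equal \code{sum(class_sizes)}.
#' @return list with \code{Hd} and \code{sd}.
#' @export
haplotype_diversity <- function(class_sizes, n = sum(class_sizes)) {
  if (sum(class_sizes) != n) stop("class sizes must sum to n")
  if (n < 2) stop("need at least two sequences")
  p <- class_sizes / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, sd = sqrt(max(v, 0)))
}

#' Per-population diversity summary
#'
#' Computes, for each level of a grouping variable with at least
#' \code{min_n} sequences: number of sequences, segregating sites, mean
#' pairwise difference k, number of haplotypes, haplotype diversity (SD) and
#' nucleotide diversity.
#'
#' @param x sequences.
#' @param group grouping vector (e.g. breed), one entry per sequence.
#' @param L sites considered (defaults to sequence length).
#' @param min_n minimum group size to report.
#' @return data.frame, one row per retained group.
#' @export
diversity_by_group <- function(x, group, L = NULL, min_n = 20L) {
  m <- as_base_matrix(x)
  if (length(group) != nrow(m)) stop("group length must match sequences")
  if (is.null(L)) L <- ncol(m)
  keep <- names(which(table(group) >= min_n))
  rows <- lapply(keep, function(g) {
    mg <- m[group == g, , drop = FALSE]
    nd <- nucleotide_diversity(mg, L = L)
    hc <- haplotype_classes(mg)
    hd <- haplotype_diversity(hc$sizes)
    data.frame(group = g, n = nrow(mg),
               segregating_sites = nd$segregating_sites,
               k = nd$k, n_haplotypes = hc$n_haplotypes,
               Hd = hd$Hd, Hd_sd = hd$sd, pi = nd$pi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- clustering -------------------------------------------------------------

#' Hierarchical clusters of sequences from a distance matrix
#'
#' Average-linkage agglomerative clustering (\code{stats::hclust}) cut at a
#' given height. At cut height 0 on N-free sequences the clusters are exactly
#' the exact-match haplotype classes (and the linkage choice is irrelevant).
#'
#' @param distance_matrix symmetric nonnegative matrix (e.g. from
#'   \code{\link{pairwise_difference_matrix}}).
#' @param cut_height height at which to cut the dendrogram.
#' @param method linkage method passed to \code{hclust}.
#' @return integer vector of cluster memberships (named if the matrix has
#'   dimnames).
#' @export
hierarchical_clusters <- function(distance_matrix, cut_height = 0,
                                  method = "average") {
  n <- nrow(distance_matrix)
  if (n == 1) return(stats::setNames(1L, rownames(distance_matrix)))
  hc <- stats::hclust(stats::as.dist(distance_matrix), method = method)
  stats::cutree(hc, h = cut_height)
}

# ---- AMOVA ------------------------------------------------------------------

#' Analysis of molecular variance (one level)
#'
#' Partitions squared pairwise distances into among-group and within-group
#' variance components (Excoffier, Smouse & Quattro 1992). For
#' nucleotide-difference counts the entries of \code{distance_matrix} are
#' used directly as squared Euclidean distances (a binary encoding of sites
#' makes the count equal the squared distance).
#'
#' SSD(total) = sum_{i<j} d_ij / N; SSD(within) = sum_g sum_{i<j in g} d / n_g;
#' sigma2_within = SSD(within)/(N-k);
#' sigma2_among = (SSD(among)/(k-1) - sigma2_within)/n_bar with
#' n_bar = (N - sum n_g^2 / N)/(k-1). A negative among-group component
#' (possible under the moment estimator) is reported as-is with a warning.
#'
#' @param distance_matrix symmetric matrix of squared inter-individual
#'   distances (for sequences, the pairwise difference counts).
#' @param group_labels group membership vector, length = number of rows.
#' @param n_permutations if > 0, a permutation test of Phi_ST by label
#'   shuffling.
#' @param seed optional seed for the permutation test.
#' @return object of class \code{amova_result}: sigma2_among, sigma2_within,
#'   percent_among, percent_within, phi_st, df/SSD table, and optionally
#'   \code{p_value} and \code{perm_sigma2_among}.
#' @export
amova <- function(distance_matrix, group_labels, n_permutations = 0,
                  seed = NULL) {
  d <- as.matrix(distance_matrix)
  N <- nrow(d)
  g <- as.character(group_labels)
  if (length(g) != N) stop("group_labels length must match the matrix")
  sizes <- table(g)
  k <- length(sizes)
  if (k < 2) stop("need at least two groups")
  if (max(sizes) < 2) stop("need at least one group with two members")

  comp <- function(g) {
    sizes <- table(g)
    ssd_total <- sum(d[upper.tri(d)]) / N
    ssd_within <- sum(vapply(names(sizes), function(gr) {
      idx <- which(g == gr)
      if (length(idx) < 2) return(0)
      sum(d[idx, idx][upper.tri(d[idx, idx])]) / length(idx)
    }, numeric(1)))
    ssd_among <- ssd_total - ssd_within
    df_among <- k - 1
    df_within <- N - k
    s2w <- ssd_within / df_within
    n_bar <- (N - sum(sizes^2) / N) / (k - 1)
    s2a <- (ssd_among / df_among - s2w) / n_bar
    list(ssd_total = ssd_total, ssd_within = ssd_within,
         ssd_among = ssd_among, df_among = df_among, df_within = df_within,
         s2w = s2w, s2a = s2a, n_bar = n_bar)
  }
  z <- comp(g)
  if (z$s2a < 0)
    warning("negative among-group variance component (", signif(z$s2a, 4),
            "); reported as-is")
  total <- z$s2a + z$s2w
  phi <- z$s2a / total
  out <- list(sigma2_among = z$s2a, sigma2_within = z$s2w,
              percent_among = 100 * z$s2a / total,
              percent_within = 100 * z$s2w / total,
              phi_st = phi,
              table = data.frame(
                source = c("among_groups", "within_groups", "total"),
                df = c(z$df_among, z$df_within, N - 1),
                SSD = c(z$ssd_among, z$ssd_within, z$ssd_total),
                sigma2 = c(z$s2a, z$s2w, total)))
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_permutations), function(i) {
      zz <- comp(sample(g))
      c(zz$s2a, zz$s2a / (zz$s2a + zz$s2w))
    }, numeric(2))
    out$perm_sigma2_among <- perm[1, ]
    out$p_value <- (sum(perm[2, ] >= phi) + 1) / (n_permutations + 1)
  }
  structure(out, class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("percent among: %.2f%%  within: %.2f%%  Phi_ST: %.4f\n",
              x$percent_among, x$percent_within, x$phi_st))
  if (!is.null(x$p_value))
    cat(sprintf("permutation p-value: %.4g\n", x$p_value))
  invisible(x)
}

# ---- GRM + PCA --------------------------------------------------------------

#' Haploid genomic relationship matrix
#'
#' Encodes each polymorphic site as one 0/1 indicator per non-reference
#' allele (multi-allelic sites contribute several indicators), standardises
#' each indicator by its sample allele frequency, z = (x - p)/sqrt(p(1-p)),
#' and returns G = Z Z' / M over the M retained indicators. Monomorphic
#' indicators (p of 0 or 1) are excluded.
#'
#' @param x sequences without N (variant sequences).
#' @param ref_alleles optional per-site reference allele; defaults to the
#'   most frequent allele at each site.
#' @param collapse if TRUE, multi-allelic sites are collapsed to a single
#'   reference/non-reference indicator instead of one per allele.
#' @return symmetric matrix, animals x animals; attribute \code{"M"} is the
#'   number of indicators used.
#' @export
haploid_grm <- function(x, ref_alleles = NULL, collapse = FALSE) {
  m <- as_base_matrix(x)
  if (any(m == "N")) stop("GRM input must be N-free variant sequences")
  n <- nrow(m)
  if (n < 2) stop("need at least two animals")
  cols <- list()
  for (j in seq_len(ncol(m))) {
    b <- m[, j]
    tab <- sort(table(b), decreasing = TRUE)
    if (length(tab) < 2) next  # monomorphic
    ref <- if (is.null(ref_alleles)) names(tab)[1] else ref_alleles[j]
    alts <- setdiff(names(tab), ref)
    if (collapse) {
      cols[[length(cols) + 1L]] <- as.numeric(b != ref)
    } else {
      for (a in alts) cols[[length(cols) + 1L]] <- as.numeric(b == a)
    }
  }
  if (!length(cols)) stop("no polymorphic sites for the GRM")
  X <- do.call(cbind, cols)
  p <- colMeans(X)
  ok <- p > 0 & p < 1
  X <- X[, ok, drop = FALSE]
  p <- p[ok]
  M <- ncol(X)
  if (M == 0) stop("no polymorphic indicators after standardisation")
  Z <- sweep(sweep(X, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  G <- Z %*% t(Z) / M
  dimnames(G) <- list(rownames(m), rownames(m))
  attr(G, "M") <- M
  G
}

#' Principal components of a (haploid) GRM
#'
#' Eigendecomposition of the symmetric GRM; PC coordinates are eigenvectors
#' scaled by the square root of their (nonnegative-clipped) eigenvalues,
#' ordered by decreasing eigenvalue.
#'
#' @param grm symmetric matrix.
#' @param n_components number of PCs to return.
#' @return object of class \code{grm_pca}: \code{values} (all eigenvalues),
#'   \code{coords} (animals x n_components), \code{vectors}.
#' @export
grm_pca <- function(grm, n_components = 3L) {
  if (!isSymmetric(unname(as.matrix(grm)), tol = 1e-8))
    stop("GRM must be symmetric")
  e <- eigen(as.matrix(grm), symmetric = TRUE)
  k <- min(n_components, ncol(e$vectors))
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k, k)
  rownames(coords) <- rownames(grm)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(values = e$values, coords = coords,
                 vectors = e$vectors[, seq_len(k), drop = FALSE]),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("grm_pca: %d animals, leading eigenvalues %s\n",
              nrow(x$coords),
              paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}
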