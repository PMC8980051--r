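#' Build a masking plan for imputation cross-validation
#'
#' Splits the cohort into a study group (a random \code{floor(frac_animals *
#' N)} animals whose genotypes get masked) and a reference panel (the rest).
#' Within each study animal, a random \code{floor(frac_sites * S)} of the
#' sites are masked, drawn independently per animal.
#'
#' @param table a \code{mito_table} with no missing genotypes.
#' @param frac_animals fraction of animals masked (default 0.2).
#' @param frac_sites fraction of sites masked per animal (default 0.1).
#' @param seed seed for the draw.
#' @return object of class \code{mask_plan}: \code{animals} (masked ids),
#'   \code{panel} (reference ids), \code{sites} (named list: animal ->
#'   masked site indices), \code{seed}.
#' @export
make_mask <- function(table, frac_animals = 0.2, frac_sites = 0.1,
                      seed = 1L) {
  stopifnot(inherits(table, "mito_table"))
  if (any(is_missing_gt(table$gt)))
    stop("masking requires a table with no missing genotypes")
  if (frac_animals <= 0 || frac_animals >= 1 ||
      frac_sites <= 0 || frac_sites >= 1)
    stop("fractions must lie strictly within (0, 1)")
  set.seed(seed)
  ids <- animal_ids(table)
  n_mask <- floor(frac_animals * length(ids))
  s_mask <- floor(frac_sites * n_sites(table))
  if (n_mask < 1 || s_mask < 1) stop("fractions too small for this table")
  masked <- sort(sample(ids, n_mask))
  sites <- lapply(masked, function(a) sort(sample.int(n_sites(table), s_mask)))
  names(sites) <- masked
  structure(list(animals = masked, panel = setdiff(ids, masked),
                 sites = sites, seed = seed),
            class = "mask_plan")
}

#' Nearest-haplotype imputation of masked genotypes
#'
#' A deliberately simple imputer used to exercise the evaluation machinery:
#' for each masked animal it ranks the reference-panel consensus haplotypes
#' by Hamming distance on the animal's unmasked sites, copies the best
#' haplotype's allele as a homoplasmic phased genotype, and derives dose (DS)
#' and genotype probabilities (GP) from the normalised inverse-distance
#' weights of the k best haplotypes (ties broken by panel order).
#'
#' @param table a \code{mito_table} with no missing genotypes.
#' @param mask a \code{\link{make_mask}} plan.
#' @param k number of nearest panel haplotypes used for DS/GP.
#' @param vs optional precomputed \code{build_variant_sequences(table)}.
#' @return object of class \code{imputed_cells}: data.frame with columns
#'   animal, site (index), pos, GT, DS, GP (comma-separated, VCF genotype
#'   order).
#' @export
naive_impute <- function(table, mask, k = 5L, vs = NULL) {
  stopifnot(inherits(table, "mito_table"), inherits(mask, "mask_plan"))
  if (length(mask$panel) == 0) stop("empty reference panel")
  if (is.null(vs)) vs <- build_variant_sequences(table)
  bases <- vs$bases
  panel <- bases[mask$panel, , drop = FALSE]
  out <- vector("list", length(mask$animals))
  allele_sets <- lapply(seq_len(n_sites(table)), function(i)
    site_alleles(table, i))
  for (ai in seq_along(mask$animals)) {
    a <- mask$animals[ai]
    ms <- mask$sites[[a]]
    um <- setdiff(seq_len(n_sites(table)), ms)
    q <- bases[a, um]
    dist <- vapply(seq_len(nrow(panel)), function(h)
      sum(panel[h, um] != q), integer(1))
    ord <- order(dist)  # stable: ties -> lowest panel index
    best <- ord[seq_len(min(k, length(ord)))]
    w <- 1 / (dist[best] + 1)
    w <- w / sum(w)
    rows <- lapply(ms, function(s) {
      alleles <- allele_sets[[s]]
      hap_bases <- panel[best, s]
      hap_idx <- match(hap_bases, alleles) - 1L
      a_star <- hap_idx[1]
      ds <- 2 * sum(w[hap_idx > 0])
      n_all <- length(alleles)
      gp <- numeric(n_all * (n_all + 1) / 2)
      for (t in seq_along(best))
        gp[gt_index(hap_idx[t], hap_idx[t]) + 1L] <-
          gp[gt_index(hap_idx[t], hap_idx[t]) + 1L] + w[t]
      data.frame(animal = a, site = s, pos = table$sites$pos[s],
                 GT = paste0(a_star, "|", a_star), DS = ds,
                 GP = paste(sprintf("%.6g", gp), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out[[ai]] <- do.call(rbind, rows)
  }
  structure(do.call(rbind, out), class = c("imputed_cells", "data.frame"))
}

#' Resolve an imputed genotype to a single base
#'
#' Applies the dose/probability rules for turning an imputed (possibly
#' heteroplasmic) genotype into a haploid base: a homoplasmic genotype gives
#' its own base; a REF/ALT heteroplasmic genotype gives REF when DS < 1 and
#' the ALT allele when DS >= 1; an ALT/ALT heteroplasmic genotype with DS = 2
#' and equal summed probability mass for both alleles is set to missing
#' (\code{"N"}), otherwise the allele with the larger probability mass summed
#' across the GP entries containing it is chosen.
#'
#' @param gt genotype string (phased or unphased).
#' @param ds alternate-allele dose in [0, 2].
#' @param gp numeric vector of genotype probabilities in VCF order (or a
#'   comma-separated string).
#' @param ref REF allele.
#' @param alts character vector of ALT alleles.
#' @return a single base, or \code{"N"}.
#' @export
resolve_imputed_base <- function(gt, ds, gp, ref, alts) {
  if (is.character(gp)) gp <- as.numeric(strsplit(gp, ",", fixed = TRUE)[[1]])
  if (any(is.na(gp)) || any(gp < -1e-9)) stop("malformed GP vector")
  alleles <- c(ref, alts)
  a <- sort(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (a[1] == a[2]) return(alleles[a[1] + 1L])
  if (a[1] == 0L) {                       # REF/ALT heteroplasmy: dose rule
    if (ds < 1) return(alleles[1]) else return(alleles[a[2] + 1L])
  }
  # ALT/ALT heteroplasmy: probability-mass rule
  n_all <- length(alleles)
  mass <- function(al) {
    s <- 0
    for (b in 0:(n_all - 1)) {
      lo <- min(al, b); hi <- max(al, b)
      idx <- gt_index(lo, hi) + 1L
      if (idx <= length(gp)) s <- s + gp[idx]
    }
    s
  }
  m1 <- mass(a[1]); m2 <- mass(a[2])
  if (abs(ds - 2) < 1e-9 && abs(m1 - m2) < 1e-9) return("N")
  if (m1 == m2) return("N")
  alleles[a[which.max(c(m1, m2))] + 1L]
}

#' Concordance between imputed and original genotypes
#'
#' Scores every masked cell: a call is correct when the imputed and original
#' unordered allele pairs agree. Reports the overall rate, a confusion matrix
#' keyed by the original genotype class (0|0, 0|1, 1|1, ...), and per-class
#' percent correct.
#'
#' @param imputed an \code{imputed_cells} data.frame.
#' @param table the original (truth) \code{mito_table}.
#' @param mask the \code{mask_plan} used.
#' @return object of class \code{concordance_report}: \code{overall},
#'   \code{confusion} (original x imputed class counts), \code{per_class}
#'   (class, n, correct, rate), \code{n_cells}.
#' @export
concordance <- function(imputed, table, mask) {
  norm_class <- function(gt) {
    a <- sort(as.integer(strsplit(gt, "[/|]")[[1]]))
    paste0(a[1], "|", a[2])
  }
  want <- sum(lengths(mask$sites))
  if (nrow(imputed) != want)
    stop("imputed cells (", nrow(imputed), ") do not cover the mask (",
         want, ")")
  orig <- character(nrow(imputed))
  imp <- character(nrow(imputed))
  for (r in seq_len(nrow(imputed))) {
    orig[r] <- norm_class(table$gt[imputed$site[r], imputed$animal[r]])
    imp[r] <- norm_class(imputed$GT[r])
  }
  correct <- orig == imp
  classes <- sort(unique(c(orig, imp)))
  confusion <- base::table(factor(orig, classes), factor(imp, classes))
  names(dimnames(confusion)) <- c("original", "imputed")
  per_class <- data.frame(
    class = sort(unique(orig)),
    n = as.integer(base::table(orig)[sort(unique(orig))]))
  per_class$correct <- vapply(per_class$class, function(cl)
    sum(correct[orig == cl]), integer(1))
  per_class$rate <- per_class$correct / per_class$n
  structure(list(overall = mean(correct), confusion = confusion,
                 per_class = per_class, n_cells = length(correct)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %.4f over %d masked cells\n",
              x$overall, x$n_cells))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Haplogroup agreement after imputation
#'
#' Rebuilds each masked animal's variant sequence with imputed bases at the
#' masked cells (via \code{\link{resolve_imputed_base}}), expands to a
#' full-length sequence, re-assigns its haplogroup, and reports the fraction
#' of masked animals whose call matches their original call (tie lists
#' compared as sets).
#'
#' @param imputed an \code{imputed_cells}.
#' @param table the original \code{mito_table}.
#' @param mask the \code{mask_plan}.
#' @param definitions an \code{hg_defs}.
#' @param reference_length full reference length for sequence expansion.
#' @param vs optional precomputed \code{build_variant_sequences(table)}.
#' @return list: \code{rate}, \code{per_animal} (animal, original, imputed,
#'   agree).
#' @export
haplogroup_agreement <- function(imputed, table, mask, definitions,
                                 reference_length = definitions$reference_length,
                                 vs = NULL) {
  if (is.null(vs)) vs <- build_variant_sequences(table)
  ids <- mask$animals
  orig_seqs <- expand_to_full_sequences(
    vs$bases[ids, , drop = FALSE], reference_length, vs$positions)
  orig <- assign_haplogroups(orig_seqs, definitions)$table
  new_bases <- vs$bases[ids, , drop = FALSE]
  for (r in seq_len(nrow(imputed))) {
    s <- imputed$site[r]
    alleles <- site_alleles(table, s)
    new_bases[imputed$animal[r], s] <- resolve_imputed_base(
      imputed$GT[r], imputed$DS[r], imputed$GP[r],
      alleles[1], alleles[-1])
  }
  new_seqs <- expand_to_full_sequences(new_bases, reference_length,
                                       vs$positions)
  new <- assign_haplogroups(new_seqs, definitions)$table
  key <- function(tab) ifelse(tab$ties == "", tab$group, tab$ties)
  agree <- key(orig) == key(new)
  agree[is.na(agree)] <- orig$status[is.na(agree)] == "unassignable" &
    new$status[is.na(agree)] == "unassignable"
  list(rate = mean(agree),
       per_animal = data.frame(animal = ids, original = orig$group,
                               imputed = new$group, agree = agree,
                               stringsAsFactors = FALSE))
}

#' Replicated masking/imputation cross-validation
#'
#' Runs mask -> impute -> score (and optionally haplogroup agreement) over
#' \code{n_reps} replicates with fresh random study/panel splits (replicate
#' r uses \code{seed + r}), and aggregates mean and SD of the overall
#' concordance, the heteroplasmic/homoplasmic class rates and the agreement
#' rate.
#'
#' @param table a \code{mito_table} with no missing genotypes.
#' @param definitions optional \code{hg_defs}; when given, haplogroup
#'   agreement is scored per replicate.
#' @param n_reps number of replicates (default 50).
#' @param frac_animals,frac_sites masking fractions.
#' @param k nearest-haplotype count for the imputer.
#' @param seed master seed; replicate r uses \code{seed + r}.
#' @return object of class \code{imputation_cv}: \code{replicates}
#'   (data.frame per replicate), \code{summary} (mean/SD rows).
#' @export
run_replicates <- function(table, definitions = NULL, n_reps = 50L,
                           frac_animals = 0.2, frac_sites = 0.1, k = 5L,
                           seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  vs <- build_variant_sequences(table)
  rows <- lapply(seq_len(n_reps), function(r) {
    mask <- make_mask(table, frac_animals, frac_sites, seed = seed + r)
    imp <- naive_impute(table, mask, k = k, vs = vs)
    cc <- concordance(imp, table, mask)
    hetero <- grepl("^(\\d+)\\|(\\d+)$", cc$per_class$class) &
      vapply(strsplit(cc$per_class$class, "|", fixed = TRUE),
             function(p) p[1] != p[2], logical(1))
    het_rate <- if (any(hetero))
      sum(cc$per_class$correct[hetero]) / sum(cc$per_class$n[hetero])
    else NA_real_
    hom_rate <- sum(cc$per_class$correct[!hetero]) /
      sum(cc$per_class$n[!hetero])
    agree <- NA_real_
    if (!is.null(definitions))
      agree <- haplogroup_agreement(imp, table, mask, definitions,
                                    vs = vs)$rate
    data.frame(replicate = r, overall = cc$overall,
               het_class_rate = het_rate, hom_class_rate = hom_rate,
               haplogroup_agreement = agree)
  })
  reps <- do.call(rbind, rows)
  num <- reps[, -1, drop = FALSE]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, function(v) mean(v, na.rm = TRUE),
                                      numeric(1)),
                        sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE),
                                    numeric(1)),
                        row.names = NULL)
  structure(list(replicates = reps, summary = summary),
            class = "imputation_cv")
}

#' @export
print.imputation_cv <- function(x, ...) {
  cat(sprintf("imputation cross-validation: %d replicate(s)\n",
              nrow(x$replicates)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Ingest external imputation output (GT:DS:GP) for scoring
#'
#' Reads a VCF produced by an external imputer (Beagle-style FORMAT
#' GT:DS:GP) and extracts the cells of a mask plan as an
#' \code{imputed_cells} table, so external output can be scored with
#' \code{\link{concordance}} and \code{\link{haplogroup_agreement}}.
#'
#' @param path imputed VCF path.
#' @param table the original \code{mito_table} (defines site order).
#' @param mask the \code{mask_plan}.
#' @return an \code{imputed_cells} data.frame.
#' @export
read_imputed_vcf <- function(path, table, mask) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  pos <- as.integer(v@fix[, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  ds <- vcfR::extract.gt(v, element = "DS")
  gp <- vcfR::extract.gt(v, element = "GP")
  colnames(gt) <- colnames(ds) <- colnames(gp) <- colnames(v@gt)[-1]
  rows <- list()
  for (a in mask$animals) {
    for (s in mask$sites[[a]]) {
      i <- match(table$sites$pos[s], pos)
      if (is.na(i)) stop("imputed VCF lacks position ", table$sites$pos[s])
      rows[[length(rows) + 1L]] <- data.frame(
        animal = a, site = s, pos = pos[i], GT = gt[i, a],
        DS = as.numeric(ds[i, a]), GP = gp[i, a],
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("imputed_cells", "data.frame"))
}
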