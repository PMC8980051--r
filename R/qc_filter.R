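#' Site and animal quality-filter thresholds
#'
#' Defaults follow the standard whole-genome-sequence mitochondrial QC recipe:
#' minimum QUAL 30, minimum mapping quality 30, minimum minor allele count 2,
#' per-site mean depth capped at the grand mean + 3 SD, animals kept only with
#' mean depth >= 10 across retained sites, and semen-group animals removed
#' above 150 heteroplasmic sites.
#'
#' @param min_qual minimum phred site quality.
#' @param min_mq minimum mapping quality.
#' @param min_minor_allele_count minimum count of the least frequent allele.
#' @param dp_cap_sd number of SDs above the grand mean allowed for per-site
#'   mean depth.
#' @param min_animal_mean_dp minimum per-animal mean depth across sites.
#' @param max_semen_heteroplasmy maximum heteroplasmic sites per animal in
#'   the semen group.
#' @return object of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_qual = 30, min_mq = 30,
                              min_minor_allele_count = 2,
                              dp_cap_sd = 3,
                              min_animal_mean_dp = 10,
                              max_semen_heteroplasmy = 150) {
  v <- c(min_qual, min_mq, min_minor_allele_count, dp_cap_sd,
         min_animal_mean_dp, max_semen_heteroplasmy)
  if (any(v < 0)) stop("all thresholds must be nonnegative")
  structure(list(min_qual = min_qual, min_mq = min_mq,
                 min_minor_allele_count = min_minor_allele_count,
                 dp_cap_sd = dp_cap_sd,
                 min_animal_mean_dp = min_animal_mean_dp,
                 max_semen_heteroplasmy = max_semen_heteroplasmy),
            class = "filter_thresholds")
}

# per-site allele counts over non-missing genotypes; both alleles of every
# genotype counted (homoplasmic contributes 2, heteroplasmic 1 + 1)
site_allele_counts <- function(x) {
  p <- parse_gt(x$gt)
  lapply(seq_len(n_sites(x)), function(i) {
    n_all <- length(site_alleles(x, i))
    cnt <- integer(n_all)
    a <- c(p$a1[i, ], p$a2[i, ])
    a <- a[!is.na(a)]
    a <- a[a < n_all]  # defensive: ignore out-of-range indices
    t <- tabulate(a + 1L, nbins = n_all)
    t
  })
}

#' Apply the site-level quality filters
#'
#' Retains sites with QUAL >= \code{min_qual}, MQ >= \code{min_mq}, minor
#' allele count >= \code{min_minor_allele_count} and per-site mean depth at
#' most grand mean + \code{dp_cap_sd} SD (both statistics over per-site mean
#' depths across animals). Under the allele-count rule every alternate allele
#' must individually reach the minimum count: failing ALTs are removed, the
#' genotypes that reference them are set to missing, and a site whose
#' remaining least-frequent allele (including REF) falls short is dropped.
#'
#' @param table a \code{mito_table}.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return the filtered \code{mito_table}; attribute \code{"filter_log"}
#'   records sites removed per criterion.
#' @export
filter_sites <- function(table, thresholds = filter_thresholds()) {
  stopifnot(inherits(table, "mito_table"))
  if (n_sites(table) == 0) stop("cannot filter an empty table")
  th <- thresholds
  log <- list()

  keep_q <- !is.na(table$sites$qual) & table$sites$qual >= th$min_qual
  log$qual <- sum(!keep_q)
  keep_m <- !is.na(table$sites$mq) & table$sites$mq >= th$min_mq
  log$mq <- sum(keep_q & !keep_m)

  mean_dp <- rowMeans(table$dp, na.rm = TRUE)
  cap <- mean(mean_dp, na.rm = TRUE) +
    th$dp_cap_sd * stats::sd(mean_dp, na.rm = TRUE)
  if (is.na(cap)) cap <- Inf  # single site: SD undefined, cap vacuous
  keep_dp <- is.na(mean_dp) | mean_dp <= cap
  if (all(is.na(mean_dp))) keep_dp <- rep(TRUE, n_sites(table))
  log$dp_cap <- sum(keep_q & keep_m & !keep_dp)

  x <- subset_table(table, sites = which(keep_q & keep_m & keep_dp))

  # minor allele count: prune under-supported ALTs, then drop failing sites
  removed_ac <- 0L
  if (n_sites(x) > 0) {
    counts <- site_allele_counts(x)
    keep_site <- rep(TRUE, n_sites(x))
    for (i in seq_len(n_sites(x))) {
      alleles <- site_alleles(x, i)
      cnt <- counts[[i]]
      if (length(alleles) == 1) { keep_site[i] <- FALSE; next }
      alt_idx <- seq_along(alleles)[-1]
      bad_alt <- alt_idx[cnt[alt_idx] < th$min_minor_allele_count]
      if (length(bad_alt)) {
        keep_alleles <- setdiff(seq_along(alleles), bad_alt)
        p <- parse_gt(x$gt[i, , drop = FALSE])
        uses_bad <- (p$a1[1, ] + 1L) %in% bad_alt | (p$a2[1, ] + 1L) %in% bad_alt
        uses_bad[is.na(uses_bad)] <- FALSE
        # renumber surviving alleles and rewrite GT / AD
        new_idx <- match(seq_along(alleles), keep_alleles) - 1L
        gt_row <- x$gt[i, ]
        ad_row <- x$ad[i, ]
        for (j in which(!is_missing_gt(gt_row) & !uses_bad)) {
          a <- c(p$a1[1, j], p$a2[1, j])
          gt_row[j] <- paste(new_idx[a + 1L], collapse = "/")
          adv <- parse_ad(ad_row[j])[[1]]
          if (!all(is.na(adv)) && length(adv) == length(alleles))
            ad_row[j] <- paste(adv[keep_alleles], collapse = ",")
        }
        gt_row[uses_bad] <- "./."
        ad_row[uses_bad] <- "."
        x$gt[i, ] <- gt_row
        x$ad[i, ] <- ad_row
        x$sites$alt[i] <- paste(alleles[keep_alleles][-1], collapse = ",")
        if (length(keep_alleles) == 1) { keep_site[i] <- FALSE; next }
        cnt <- site_allele_counts(subset_table(x, sites = i))[[1]]
      }
      if (min(cnt) < th$min_minor_allele_count) keep_site[i] <- FALSE
    }
    removed_ac <- sum(!keep_site)
    x <- subset_table(x, sites = which(keep_site))
  }
  log$minor_allele_count <- removed_ac

  attr(x, "filter_log") <- data.frame(
    criterion = c("qual", "mq", "dp_cap", "minor_allele_count"),
    sites_removed = c(log$qual, log$mq, log$dp_cap, log$minor_allele_count))
  x
}

#' Remove INDEL sites and sites with missing genotypes
#'
#' Conventional mitochondrial analysis tools handle neither, so any site
#' whose REF/ALT lengths differ from 1 and any site carrying at least one
#' missing genotype is removed. The result contains SNPs only and exactly
#' zero missing genotypes.
#'
#' @param table a \code{mito_table}.
#' @return the filtered \code{mito_table}; attribute \code{"filter_log"}
#'   records removals.
#' @export
drop_indels_and_missing <- function(table) {
  stopifnot(inherits(table, "mito_table"))
  indel <- site_is_indel(table)
  missing <- apply(is_missing_gt(table$gt), 1, any)
  x <- subset_table(table, sites = which(!indel & !missing))
  attr(x, "filter_log") <- data.frame(
    criterion = c("indel", "missing_genotype"),
    sites_removed = c(sum(indel), sum(missing & !indel)))
  x
}

#' Remove animals with low mean read depth
#'
#' Drops animals whose mean DP across the retained sites is below
#' \code{min_animal_mean_dp}; the boundary value itself is retained.
#'
#' @param table a site-filtered \code{mito_table}.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return the filtered \code{mito_table}; attribute \code{"removed_animals"}
#'   lists the ids removed.
#' @export
filter_animals_by_depth <- function(table, thresholds = filter_thresholds()) {
  stopifnot(inherits(table, "mito_table"))
  mean_dp <- colMeans(table$dp, na.rm = TRUE)
  keep <- !is.na(mean_dp) & mean_dp >= thresholds$min_animal_mean_dp
  x <- subset_table(table, animals = which(keep))
  attr(x, "removed_animals") <- animal_ids(table)[!keep]
  x
}

#' Heteroplasmy profile by tissue group
#'
#' Per-animal heteroplasmic-site counts, per-site heteroplasmic-animal
#' counts, and the major:minor allele-depth ratio of every heteroplasmic
#' genotype, stratified into Semen and Non-semen groups (see
#' \code{\link{tissue_group}}). Ratios are recorded only where the minor
#' allele has at least one read.
#'
#' @param table a \code{mito_table}.
#' @param metadata metadata covering every animal in \code{table}.
#' @return list of class \code{heteroplasmy_profile}: \code{per_animal}
#'   (animal, group, n_het, mean_ratio), \code{per_site} (pos, n_het) and
#'   \code{ratios} (animal, group, pos, ratio).
#' @export
heteroplasmy_profile <- function(table, metadata) {
  stopifnot(inherits(table, "mito_table"))
  ids <- animal_ids(table)
  missing_meta <- setdiff(ids, metadata$animal_id)
  if (length(missing_meta))
    stop("animals missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  grp <- tissue_group(metadata)[ids]
  het <- is_heteroplasmic(table$gt)
  p <- parse_gt(table$gt)
  ratios <- NULL
  if (any(het)) {
    idx <- which(het, arr.ind = TRUE)
    adv <- parse_ad(table$ad[het])
    r <- vapply(seq_len(nrow(idx)), function(k) {
      a <- c(p$a1[idx[k, 1], idx[k, 2]], p$a2[idx[k, 1], idx[k, 2]])
      d <- adv[[k]][a + 1L]
      if (any(is.na(d))) stop("heteroplasmic genotype without allele depths at position ",
                              table$sites$pos[idx[k, 1]])
      if (min(d) == 0) return(NA_real_)
      max(d) / min(d)
    }, numeric(1))
    ratios <- data.frame(animal = ids[idx[, 2]],
                         group = unname(grp[idx[, 2]]),
                         pos = table$sites$pos[idx[, 1]],
                         ratio = r, stringsAsFactors = FALSE)
    ratios <- ratios[!is.na(ratios$ratio), , drop = FALSE]
  } else {
    ratios <- data.frame(animal = character(0), group = character(0),
                         pos = integer(0), ratio = numeric(0))
  }
  per_animal <- data.frame(animal = ids, group = unname(grp),
                           n_het = colSums(het), stringsAsFactors = FALSE)
  mr <- tapply(ratios$ratio, factor(ratios$animal, levels = ids), mean)
  per_animal$mean_ratio <- as.numeric(mr)
  per_site <- data.frame(pos = table$sites$pos, n_het = rowSums(het))
  structure(list(per_animal = per_animal, per_site = per_site,
                 ratios = ratios),
            class = "heteroplasmy_profile")
}

#' Remove semen-group animals with excessive heteroplasmy
#'
#' Animals in the Semen group with more than \code{max_semen_heteroplasmy}
#' heteroplasmic sites are removed (likely NUMT contamination); Non-semen
#' animals are never removed by this rule.
#'
#' @param table a \code{mito_table}.
#' @param metadata metadata covering every animal.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return the filtered \code{mito_table}; attribute \code{"removed_animals"}
#'   lists the ids removed.
#' @export
filter_semen_heteroplasmy <- function(table, metadata,
                                      thresholds = filter_thresholds()) {
  prof <- heteroplasmy_profile(table, metadata)
  pa <- prof$per_animal
  drop <- pa$group == "semen" & pa$n_het > thresholds$max_semen_heteroplasmy
  x <- subset_table(table, animals = which(!drop))
  attr(x, "removed_animals") <- pa$animal[drop]
  x
}

#' Run the full QC pipeline in the canonical order
#'
#' Site filters, then INDEL/missing removal, then the animal depth filter,
#' then the semen heteroplasmy filter. Counts depend on this order, which is
#' recorded in the returned report.
#'
#' @param table a \code{mito_table}.
#' @param metadata animal metadata.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return the filtered \code{mito_table}; attribute \code{"qc_report"} is a
#'   data.frame (step, criterion, sites_removed, animals_removed).
#' @export
qc_pipeline <- function(table, metadata, thresholds = filter_thresholds()) {
  s1 <- filter_sites(table, thresholds)
  l1 <- attr(s1, "filter_log")
  s2 <- drop_indels_and_missing(s1)
  l2 <- attr(s2, "filter_log")
  s3 <- filter_animals_by_depth(s2, thresholds)
  s4 <- filter_semen_heteroplasmy(s3, metadata, thresholds)
  rep <- rbind(
    data.frame(step = "site_filters", criterion = l1$criterion,
               sites_removed = l1$sites_removed, animals_removed = 0L),
    data.frame(step = "indel_missing", criterion = l2$criterion,
               sites_removed = l2$sites_removed, animals_removed = 0L),
    data.frame(step = "animal_depth", criterion = "min_animal_mean_dp",
               sites_removed = 0L,
               animals_removed = length(attr(s3, "removed_animals"))),
    data.frame(step = "semen_heteroplasmy", criterion = "max_semen_heteroplasmy",
               sites_removed = 0L,
               animals_removed = length(attr(s4, "removed_animals"))))
  attr(s4, "qc_report") <- rep
  s4
}
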