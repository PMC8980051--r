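#' Configuration for the synthetic mitogenome cohort generator
#'
#' The generator emulates a haploid, circular-but-linearly-processed
#' mitochondrial genome (default 16,340 bp) carrying haplogroup-structured
#' haplotypes, per-genotype read depths, heteroplasmic calls whose prevalence
#' and allelic balance differ by tissue class (semen-like samples carry few
#' mitochondria, so NUMT reads produce more balanced allele depths), sporadic
#' missing genotypes and occasional INDELs.
#'
#' @param genome_length reference length in bp.
#' @param n_haplogroups number of haplogroups to define.
#' @param defining_variants_per_group diagnostic variants per haplogroup.
#' @param n_animals cohort size.
#' @param breed_assignments named list \code{breed -> list(haplogroup, count)};
#'   counts must sum to \code{n_animals}. Default: one breed per haplogroup,
#'   equal counts.
#' @param private_mutation_rate expected Poisson number of extra (private)
#'   substitutions per animal lineage.
#' @param heteroplasmy_rate_somatic,heteroplasmy_rate_semen per-site
#'   probability that a genotype is emitted as heteroplasmic, by tissue class.
#' @param depth_mean,depth_sd read depth model (normal, truncated at 1).
#' @param numt_allele_fraction_semen,numt_allele_fraction_somatic expected
#'   fraction of reads from the contaminating allele at heteroplasmic sites;
#'   the semen value must be >= the somatic one.
#' @param missing_rate per-genotype probability of \code{"./."}.
#' @param indel_rate per-reference-position probability of a spiked INDEL site.
#' @param low_qual_rate,low_mq_rate fraction of sites emitted with QUAL (MQ)
#'   below 30, to exercise the quality filters.
#' @param prop_male probability an animal is male.
#' @param prop_semen_tissue probability a male sample is semen-derived.
#' @param prop_unknown_tissue probability tissue is unrecorded.
#' @param ratio_concentration concentration of the Beta distribution for the
#'   major-allele read fraction at heteroplasmic sites.
#' @param seed master seed; all randomness derives from it.
#'
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 16340L,
                       n_haplogroups = 4L,
                       defining_variants_per_group = 25L,
                       n_animals = 200L,
                       breed_assignments = NULL,
                       private_mutation_rate = 2,
                       heteroplasmy_rate_somatic = 0.005,
                       heteroplasmy_rate_semen = 0.05,
                       depth_mean = 12.34,
                       depth_sd = 4,
                       numt_allele_fraction_semen = 0.45,
                       numt_allele_fraction_somatic = 0.25,
                       missing_rate = 0.01,
                       indel_rate = 0.001,
                       low_qual_rate = 0.02,
                       low_mq_rate = 0.02,
                       prop_male = 0.5,
                       prop_semen_tissue = 0.7,
                       prop_unknown_tissue = 0.05,
                       ratio_concentration = 20,
                       seed = 1L) {
  rates <- c(heteroplasmy_rate_somatic, heteroplasmy_rate_semen,
             numt_allele_fraction_semen, numt_allele_fraction_somatic,
             missing_rate, indel_rate, low_qual_rate, low_mq_rate,
             prop_male, prop_semen_tissue, prop_unknown_tissue)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (genome_length <= 0) stop("genome_length must be positive")
  if (private_mutation_rate < 0) stop("private_mutation_rate must be >= 0")
  if (numt_allele_fraction_semen < numt_allele_fraction_somatic)
    stop("numt_allele_fraction_semen must be >= numt_allele_fraction_somatic")
  if (is.null(breed_assignments)) {
    cnt <- rep(n_animals %/% n_haplogroups, n_haplogroups)
    cnt[1] <- cnt[1] + n_animals - sum(cnt)
    breed_assignments <- lapply(seq_len(n_haplogroups), function(i)
      list(haplogroup = paste0("H", i), count = cnt[i]))
    names(breed_assignments) <- paste0("Breed", seq_len(n_haplogroups))
  }
  if (sum(vapply(breed_assignments, `[[`, numeric(1), "count")) != n_animals)
    stop("breed_assignments counts must sum to n_animals")
  keep <- setdiff(names(formals(sim_config)), "breed_assignments")
  cfg <- mget(keep)
  cfg$breed_assignments <- breed_assignments
  structure(cfg, class = "sim_config")
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate haplogroup definitions and founder sequences
#'
#' Draws a random reference sequence, samples disjoint defining-variant
#' positions without replacement, and builds one founder haplotype per
#' haplogroup (the reference with that group's defining alleles applied).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{definitions} (an \code{hg_defs}, see
#'   \code{\link{hg_defs}}), \code{reference} (character scalar) and
#'   \code{founders} (named character vector of founder sequences).
#' @export
simulate_haplogroup_definitions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_haplogroups < 1) stop("n_haplogroups must be >= 1")
  if (config$defining_variants_per_group < 1)
    stop("defining_variants_per_group must be >= 1")
  n_def <- config$n_haplogroups * config$defining_variants_per_group
  if (n_def > config$genome_length)
    stop("genome too short to host the requested defining variants")
  set.seed(config$seed)
  ref <- rand_base(config$genome_length)
  pos <- sort(sample.int(config$genome_length, n_def))
  pos <- split(sample(pos), rep(seq_len(config$n_haplogroups),
                                each = config$defining_variants_per_group))
  groups <- lapply(pos, function(p) {
    p <- sort(p)
    data.frame(pos = p, allele = mutate_base(ref[p]), stringsAsFactors = FALSE)
  })
  names(groups) <- paste0("H", seq_len(config$n_haplogroups))
  ref_str <- paste(ref, collapse = "")
  founders <- vapply(groups, function(g) {
    s <- ref
    s[g$pos] <- g$allele
    paste(s, collapse = "")
  }, character(1))
  list(definitions = hg_defs(groups, ref_str), reference = ref_str,
       founders = founders)
}

#' Simulate a haplogroup-structured population
#'
#' Each animal is its haplogroup founder plus a Poisson number of private
#' substitutions at random non-defining positions; metadata rows carry breed,
#' country, sex and tissue class.
#'
#' @param definitions output of \code{\link{simulate_haplogroup_definitions}}.
#' @param config a \code{\link{sim_config}}.
#' @return list (\code{truth_set}): \code{sequences} (named character vector),
#'   \code{haplogroup} (named character vector of true labels),
#'   \code{metadata} (data.frame), plus the \code{definitions} input.
#' @export
simulate_population <- function(definitions, config) {
  stopifnot(inherits(config, "sim_config"))
  defs <- definitions$definitions
  set.seed(config$seed + 1L)
  hg_of_breed <- vapply(config$breed_assignments, `[[`, character(1),
                        "haplogroup")
  if (!all(hg_of_breed %in% names(defs$groups)))
    stop("unknown haplogroup label in breed_assignments: ",
         paste(setdiff(hg_of_breed, names(defs$groups)), collapse = ", "))
  counts <- vapply(config$breed_assignments, `[[`, numeric(1), "count")
  breed <- rep(names(config$breed_assignments), counts)
  hg <- rep(hg_of_breed, counts)
  n <- config$n_animals
  ids <- sprintf("AN%04d", seq_len(n))
  def_pos <- sort(unique(unlist(lapply(defs$groups, `[[`, "pos"))))
  free_pos <- setdiff(seq_len(config$genome_length), def_pos)
  founder_chars <- lapply(definitions$founders, function(s)
    strsplit(s, "")[[1]])
  n_mut <- stats::rpois(n, config$private_mutation_rate)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- founder_chars[[hg[i]]]
    if (n_mut[i] > 0) {
      p <- sample(free_pos, min(n_mut[i], length(free_pos)))
      s[p] <- mutate_base(s[p])
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- names(hg) <- ids
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  tissue <- ifelse(sex == "M" & stats::runif(n) < config$prop_semen_tissue,
                   "semen", "blood")
  tissue[stats::runif(n) < config$prop_unknown_tissue] <- "unknown"
  country <- paste0("Country", as.integer(factor(breed)))
  meta <- data.frame(animal_id = ids, breed = breed, country = country,
                     sex = sex, tissue = tissue, stringsAsFactors = FALSE)
  list(sequences = seqs, haplogroup = hg, metadata = meta,
       definitions = definitions)
}

# VCF genotype-class index of the unordered pair (a,b), a<=b (0-based alleles)
gt_index <- function(a, b) b * (b + 1) / 2 + a

#' Simulate a multi-sample mitochondrial VCF from a truth set
#'
#' Emits every site segregating against the reference, plus spiked INDEL
#' records. Heteroplasmic genotypes are two-allele calls whose major-allele
#' read fraction is Beta-distributed per tissue class (the semen class is
#' centred nearer 0.5, mimicking NUMT interference in low-copy samples);
#' missing genotypes are \code{"./."}; a configurable fraction of sites gets
#' QUAL or MQ below 30.
#'
#' @param truth output of \code{\link{simulate_population}}.
#' @param config a \code{\link{sim_config}}.
#' @return a \code{mito_table}; attribute \code{"truth"} carries the input
#'   truth set.
#' @export
simulate_vcf <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ref <- strsplit(truth$definitions$reference, "")[[1]]
  if (any(nchar(truth$sequences) != config$genome_length))
    stop("truth sequences must all have length genome_length")
  n <- length(truth$sequences)
  ids <- names(truth$sequences)
  base_mat <- do.call(rbind, strsplit(truth$sequences, ""))  # n x L
  seg <- which(colSums(base_mat != rep(ref, each = n)) > 0)
  grp <- tissue_group(truth$metadata)[ids]
  het_rate <- ifelse(grp == "semen", config$heteroplasmy_rate_semen,
                     config$heteroplasmy_rate_somatic)
  numt_frac <- ifelse(grp == "semen", config$numt_allele_fraction_semen,
                      config$numt_allele_fraction_somatic)
  conc <- config$ratio_concentration

  S <- length(seg)
  gt <- ad <- matrix("", S, n, dimnames = list(NULL, ids))
  dp <- matrix(0, S, n, dimnames = list(NULL, ids))
  sites <- data.frame(pos = integer(S), ref = character(S), alt = character(S),
                      qual = numeric(S), mq = numeric(S),
                      stringsAsFactors = FALSE)
  for (k in seq_len(S)) {
    p <- seg[k]
    obs <- base_mat[, p]
    alts <- sort(setdiff(unique(obs), ref[p]))
    alleles <- c(ref[p], alts)
    truth_idx <- match(obs, alleles) - 1L
    n_all <- length(alleles)
    depth <- pmax(1L, as.integer(round(stats::rnorm(n, config$depth_mean,
                                                    config$depth_sd))))
    het <- stats::runif(n) < het_rate
    miss <- stats::runif(n) < config$missing_rate
    g <- a <- character(n)
    for (j in seq_len(n)) {
      if (miss[j]) { g[j] <- "./."; a[j] <- "."; next }
      adv <- integer(n_all)
      if (het[j] && n_all > 1) {
        other <- sample(setdiff(seq_len(n_all) - 1L, truth_idx[j]), 1)
        f_major <- stats::rbeta(1, conc * (1 - numt_frac[j]),
                                conc * numt_frac[j])
        d_major <- as.integer(round(f_major * depth[j]))
        d_major <- min(max(d_major, 0L), depth[j])
        adv[truth_idx[j] + 1L] <- d_major
        adv[other + 1L] <- depth[j] - d_major
        pair <- sort(c(truth_idx[j], other))
        g[j] <- paste0(pair[1], "/", pair[2])
      } else {
        adv[truth_idx[j] + 1L] <- depth[j]
        g[j] <- paste0(truth_idx[j], "/", truth_idx[j])
      }
      a[j] <- paste(adv, collapse = ",")
    }
    gt[k, ] <- g; ad[k, ] <- a; dp[k, ] <- depth
    sites$pos[k] <- p
    sites$ref[k] <- ref[p]
    sites$alt[k] <- paste(alts, collapse = ",")
  }

  # spiked INDEL records at non-segregating positions
  n_indel <- stats::rbinom(1, config$genome_length, config$indel_rate)
  if (n_indel > 0) {
    cand <- setdiff(seq_len(config$genome_length - 1L), seg)
    ipos <- sort(sample(cand, min(n_indel, length(cand))))
    igt <- iad <- matrix("0/0", length(ipos), n, dimnames = list(NULL, ids))
    idp <- matrix(pmax(1L, as.integer(round(stats::rnorm(
      length(ipos) * n, config$depth_mean, config$depth_sd)))),
      length(ipos), n, dimnames = list(NULL, ids))
    iad[] <- paste0(as.vector(idp), ",0")
    isites <- data.frame(pos = ipos, ref = ref[ipos],
                         alt = paste0(ref[ipos], rand_base(length(ipos))),
                         qual = 0, mq = 0, stringsAsFactors = FALSE)
    for (k in seq_along(ipos)) {  # two carriers so the site is variant
      carriers <- sample.int(n, 2)
      igt[k, carriers] <- "1/1"
      iad[k, carriers] <- paste0("0,", idp[k, carriers])
    }
    sites <- rbind(sites, isites)
    o <- order(sites$pos)
    sites <- sites[o, , drop = FALSE]
    gt <- rbind(gt, igt)[o, , drop = FALSE]
    ad <- rbind(ad, iad)[o, , drop = FALSE]
    dp <- rbind(dp, idp)[o, , drop = FALSE]
  }

  m <- nrow(sites)
  low_q <- stats::runif(m) < config$low_qual_rate
  low_m <- stats::runif(m) < config$low_mq_rate
  sites$qual <- ifelse(low_q, stats::runif(m, 10, 29.9),
                       stats::runif(m, 30, 60))
  sites$mq <- ifelse(low_m, stats::runif(m, 10, 29.9),
                     stats::runif(m, 30, 60))
  tab <- mito_table(sites, gt, ad, dp)
  attr(tab, "truth") <- truth
  tab
}

#' Write a full synthetic dataset to disk
#'
#' Runs the three simulation stages and writes the VCF, reference FASTA,
#' metadata TSV and haplogroup-definition file.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths plus the in-memory objects.
#' @export
write_sim_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  defs <- simulate_haplogroup_definitions(config)
  truth <- simulate_population(defs, config)
  tab <- simulate_vcf(truth, config)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                fasta = file.path(dir, "reference.fasta"),
                meta = file.path(dir, "metadata.tsv"),
                defs = file.path(dir, "haplogroup_defs.txt"))
  write_mito_vcf(tab, paths$vcf, contig = "MT",
                 contig_length = config$genome_length)
  refset <- Biostrings::DNAStringSet(defs$reference)
  names(refset) <- "MT"
  Biostrings::writeXStringSet(refset, paths$fasta, width = 60)
  write_metadata(truth$metadata, paths$meta)
  write_hg_defs(defs$definitions, paths$defs)
  invisible(c(paths, list(table = tab, truth = truth, definitions = defs)))
}
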