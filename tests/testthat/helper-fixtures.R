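# Hand-built mito_table fixtures for unit tests.

# gt: sites x animals character matrix (colnames = animal ids).
# Depths default to 20 reads on the called allele(s); heteroplasmic calls get
# an uneven 13/7 split unless ad is supplied.
mk_table <- function(gt, ad = NULL, dp = NULL, pos = NULL, ref = NULL,
                     alt = NULL, qual = 50, mq = 50) {
  S <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(S)
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("G", S)
  qual <- rep_len(qual, S)
  mq <- rep_len(mq, S)
  if (is.null(ad)) {
    ad <- gt
    for (i in seq_len(S)) {
      n_all <- 1L + length(strsplit(alt[i], ",", fixed = TRUE)[[1]])
      for (j in seq_len(ncol(gt))) {
        g <- gt[i, j]
        if (g %in% c("./.", ".")) { ad[i, j] <- "."; next }
        a <- as.integer(strsplit(g, "[/|]")[[1]])
        v <- integer(n_all)
        if (a[1] == a[2]) v[a[1] + 1L] <- 20L
        else { v[a[1] + 1L] <- 13L; v[a[2] + 1L] <- 7L }
        ad[i, j] <- paste(v, collapse = ",")
      }
    }
  }
  if (is.null(dp)) {
    dp <- matrix(20, S, ncol(gt), dimnames = dimnames(gt))
    dp[gt == "./."] <- 20
  }
  mito_table(data.frame(pos = pos, ref = ref, alt = alt, qual = qual,
                        mq = mq, stringsAsFactors = FALSE),
             gt, ad, dp)
}

mk_meta <- function(ids, breed = "B1", country = "C1", sex = "F",
                    tissue = "blood") {
  data.frame(animal_id = ids,
             breed = rep_len(breed, length(ids)),
             country = rep_len(country, length(ids)),
             sex = rep_len(sex, length(ids)),
             tissue = rep_len(tissue, length(ids)),
             stringsAsFactors = FALSE)
}

# small clean cohort reused across tests (no noise)
clean_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 3000, n_haplogroups = 3,
                        defining_variants_per_group = 10, n_animals = 24,
                        private_mutation_rate = 1,
                        heteroplasmy_rate_somatic = 0,
                        heteroplasmy_rate_semen = 0,
                        missing_rate = 0, indel_rate = 0,
                        low_qual_rate = 0, low_mq_rate = 0, seed = 11)
      defs <- simulate_haplogroup_definitions(cfg)
      truth <- simulate_population(defs, cfg)
      tab <- simulate_vcf(truth, cfg)
      cache <<- list(cfg = cfg, defs = defs, truth = truth, tab = tab)
    }
    cache
  }
})

# independent brute-force AMOVA used as oracle (plain double loops)
amova_oracle <- function(d, g) {
  N <- nrow(d)
  groups <- unique(g)
  k <- length(groups)
  ss_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d[i, j]
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (gr in groups) {
    idx <- which(g == gr)
    if (length(idx) >= 2) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]
      ss_w <- ss_w + s / length(idx)
    }
  }
  ss_a <- ss_tot - ss_w
  s2w <- ss_w / (N - k)
  nbar <- (N - sum(table(g)^2) / N) / (k - 1)
  s2a <- (ss_a / (k - 1) - s2w) / nbar
  list(s2a = s2a, s2w = s2w,
       pct_within = 100 * s2w / (s2a + s2w),
       phi = s2a / (s2a + s2w))
}

random_base_matrix <- function(n, s, n_states = 4) {
  matrix(sample(c("A", "C", "G", "T")[seq_len(n_states)], n * s,
                replace = TRUE),
         n, s, dimnames = list(paste0("a", seq_len(n)), NULL))
}
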