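test_that("mask plans realise the floor(n x fraction) arithmetic deterministically", {
  gt <- matrix("0/0", 100, 10, dimnames = list(NULL, paste0("a", 1:10)))
  gt[1, ] <- "0/1"  # keep the site polymorphic-looking
  tab <- mk_table(gt)
  m1 <- make_mask(tab, 0.2, 0.1, seed = 3)
  expect_length(m1$animals, 2L)
  expect_true(all(lengths(m1$sites) == 10L))
  expect_setequal(c(m1$animals, m1$panel), paste0("a", 1:10))
  m2 <- make_mask(tab, 0.2, 0.1, seed = 3)
  expect_identical(m1, m2)
  expect_false(identical(m1$sites, make_mask(tab, 0.2, 0.1, seed = 4)$sites))
  expect_error(make_mask(tab, 0, 0.1), "fractions")
  expect_error(make_mask(tab, 0.2, 1), "fractions")
  gt[2, 2] <- "./."
  expect_error(make_mask(mk_table(gt), 0.2, 0.1), "no missing")
})

test_that("a verbatim panel haplotype is copied perfectly", {
  cc <- clean_cohort()
  tab <- drop_indels_and_missing(cc$tab)
  mask <- make_mask(tab, 0.25, 0.2, seed = 5)
  imp <- naive_impute(tab, mask)
  # masked and imputed cell sets are identical (no leakage, no omissions)
  got <- split(imp$site, imp$animal)
  expect_identical(lapply(mask$sites, as.integer),
                   lapply(got[names(mask$sites)], as.integer))
  cc_rep <- concordance(imp, tab, mask)
  # with private_mutation_rate > 0 sequences are near-unique, yet each truth
  # haplotype's backbone exists in the panel; concordance is high but the
  # exact-1 guarantee needs duplicated haplotypes (next test)
  expect_gt(cc_rep$overall, 0.9)
})

test_that("with every truth haplotype in the panel and no heteroplasmy, concordance is exactly 1", {
  cfg <- sim_config(genome_length = 2500, n_haplogroups = 3,
                    defining_variants_per_group = 10, n_animals = 30,
                    private_mutation_rate = 0,
                    heteroplasmy_rate_somatic = 0,
                    heteroplasmy_rate_semen = 0,
                    missing_rate = 0, indel_rate = 0, seed = 19)
  tab <- simulate_vcf(simulate_population(simulate_haplogroup_definitions(cfg),
                                          cfg), cfg)
  mask <- make_mask(tab, 0.2, 0.1, seed = 2)
  imp <- naive_impute(tab, mask)
  rep <- concordance(imp, tab, mask)
  expect_identical(rep$overall, 1)
  expect_true(all(rep$per_class$rate == 1))
  agree <- haplogroup_agreement(imp, tab, mask,
                                attr(tab, "truth")$definitions$definitions,
                                cfg$genome_length)
  expect_identical(agree$rate, 1)
})

test_that("a single-haplotype panel is copied with homozygous doses", {
  gt <- cbind(a1 = c("0/0", "1/1", "0/0"), a2 = c("0/0", "1/1", "0/0"),
              a3 = c("0/0", "1/1", "1/1"), a4 = c("1/1", "0/0", "0/0"))
  tab <- mk_table(gt)
  mask <- structure(list(animals = c("a3", "a4"), panel = c("a1", "a2"),
                         sites = list(a3 = c(1L, 3L), a4 = 2L), seed = 1L),
                    class = "mask_plan")
  imp <- naive_impute(tab, mask, k = 5)
  expect_true(all(imp$GT %in% c("0|0", "1|1")))
  expect_true(all(imp$DS %in% c(0, 2)))
  # panel of identical haplotypes -> every imputation copies it
  expect_identical(imp$GT[imp$animal == "a3"], c("0|0", "0|0"))
  expect_error(naive_impute(tab, structure(list(animals = "a1",
                                                panel = character(0),
                                                sites = list(a1 = 1L)),
                                           class = "mask_plan")),
               "empty reference panel")
})

test_that("imputed genotypes resolve to bases by the dose/probability rules", {
  expect_identical(resolve_imputed_base("0|0", 0, c(1, 0, 0), "A", "G"), "A")
  expect_identical(resolve_imputed_base("1|1", 2, c(0, 0, 1), "A", "G"), "G")
  expect_identical(resolve_imputed_base("0|1", 0.4, c(0.6, 0.3, 0.1),
                                        "A", "G"), "A")
  expect_identical(resolve_imputed_base("0|1", 1.0, c(0.2, 0.5, 0.3),
                                        "A", "G"), "G")
  expect_identical(resolve_imputed_base("0|1", 1.7, c(0, 0.3, 0.7),
                                        "A", "G"), "G")
  # two-ALT heteroplasmy with DS = 2 and symmetric support is set to missing
  expect_identical(resolve_imputed_base("1|2", 2, c(0, 0, 0, 0, 1, 0),
                                        "A", c("C", "G")), "N")
  # DS < 2: the allele with more summed genotype probability wins
  expect_identical(resolve_imputed_base("1|2", 1.6, c(0, 0.1, 0.6, 0, 0.2, 0.1),
                                        "A", c("C", "G")), "C")
  expect_identical(resolve_imputed_base("1|2", 1.9, c(0, 0, 0.1, 0, 0.3, 0.6),
                                        "A", c("C", "G")), "G")
  expect_error(resolve_imputed_base("0|1", 1, c(NA, 1), "A", "G"), "malformed")
})

test_that("resolution is total over fuzzed GT/DS/GP combinations", {
  set.seed(21)
  alleles <- c("A", "C", "G", "T")
  for (r in 1:300) {
    n_alt <- sample(1:3, 1)
    alts <- alleles[2:(1 + n_alt)]
    n_all <- n_alt + 1
    a <- sort(sample(0:n_alt, 2, replace = TRUE))
    gp <- runif(n_all * (n_all + 1) / 2)
    gp <- gp / sum(gp)
    ds <- runif(1, 0, 2)
    b <- resolve_imputed_base(paste0(a[1], "|", a[2]), ds, gp, "A", alts)
    expect_true(b %in% c(alleles, "N"))
  }
})

test_that("concordance report identity and hand-counted class rates", {
  gt <- cbind(a1 = c("0/0", "1/1", "0/1"), a2 = c("0/0", "0/0", "0/0"))
  tab <- mk_table(gt)
  mask <- structure(list(animals = "a1", panel = "a2",
                         sites = list(a1 = 1:3), seed = 1L),
                    class = "mask_plan")
  # a2's haplotype is all-REF, so imputation copies REF everywhere
  imp <- naive_impute(tab, mask)
  rep <- concordance(imp, tab, mask)
  expect_equal(rep$overall, 1 / 3)
  pc <- rep$per_class
  expect_equal(pc$rate[pc$class == "0|0"], 1)
  expect_equal(pc$rate[pc$class == "1|1"], 0)
  expect_equal(pc$rate[pc$class == "0|1"], 0)
  expect_equal(unname(rep$confusion["1|1", "0|0"]), 1)
  # perfect imputation scores 1 with a diagonal confusion matrix
  imp2 <- imp
  imp2$GT <- c("0|0", "1|1", "0|1")[imp2$site]
  rep2 <- concordance(imp2, tab, mask)
  expect_equal(rep2$overall, 1)
  expect_true(all(rep2$confusion[upper.tri(rep2$confusion)] == 0))
  expect_error(concordance(imp[-1, ], tab, mask), "cover the mask")
})

test_that("replicated cross-validation aggregates and is reproducible", {
  cfg <- sim_config(genome_length = 2500, n_haplogroups = 2,
                    defining_variants_per_group = 8, n_animals = 24,
                    private_mutation_rate = 1,
                    heteroplasmy_rate_somatic = 0.02,
                    heteroplasmy_rate_semen = 0.05,
                    missing_rate = 0, indel_rate = 0, seed = 29)
  tab <- simulate_vcf(simulate_population(simulate_haplogroup_definitions(cfg),
                                          cfg), cfg)
  defs <- attr(tab, "truth")$definitions$definitions
  cv1 <- run_replicates(tab, defs, n_reps = 3, seed = 100)
  cv2 <- run_replicates(tab, defs, n_reps = 3, seed = 100)
  expect_identical(cv1$replicates, cv2$replicates)
  expect_equal(nrow(cv1$replicates), 3L)
  one <- run_replicates(tab, defs, n_reps = 1, seed = 100)
  expect_equal(one$summary$mean[one$summary$metric == "overall"],
               one$replicates$overall[1])
  expect_true(all(cv1$replicates$overall >= 0 & cv1$replicates$overall <= 1))
})

test_that("external GT:DS:GP output can be ingested for scoring", {
  gt <- cbind(a1 = c("0/0", "1/1"), a2 = c("0/1", "0/0"))
  tab <- mk_table(gt)
  mask <- structure(list(animals = "a1", panel = "a2",
                         sites = list(a1 = 1:2), seed = 1L),
                    class = "mask_plan")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"p\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a1", "a2"), collapse = "\t"),
    paste(c("MT", "1", ".", "A", "G", "50", "PASS", ".", "GT:DS:GP",
            "0|1:0.4:0.6,0.3,0.1", "0|0:0:1,0,0"), collapse = "\t"),
    paste(c("MT", "2", ".", "A", "G", "50", "PASS", ".", "GT:DS:GP",
            "1|1:2:0,0,1", "0|0:0:1,0,0"), collapse = "\t")), vcf)
  imp <- read_imputed_vcf(vcf, tab, mask)
  expect_equal(nrow(imp), 2L)
  expect_identical(imp$GT, c("0|1", "1|1"))
  expect_equal(imp$DS, c(0.4, 2))
  expect_identical(resolve_imputed_base(imp$GT[1], imp$DS[1], imp$GP[1],
                                        "A", "G"), "A")
  rep <- concordance(imp, tab, mask)
  expect_equal(rep$overall, 0.5)  # 0|1 != 0|0 truth at site 1; 1|1 correct
})
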