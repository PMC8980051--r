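test_that("pairwise differences match hand counts and a brute-force recount", {
  expect_equal(pairwise_difference_matrix(c(a = "AAA", b = "ATT"))[1, 2], 2)
  m <- rbind(a = c("A", "A", "A"), b = c("A", "A", "A"))
  expect_true(all(pairwise_difference_matrix(m) == 0))
  # N positions are excluded pairwise
  expect_equal(pairwise_difference_matrix(c(a = "ANA", b = "TTT"))[1, 2], 2)
  set.seed(7)
  x <- random_base_matrix(12, 40)
  x[sample(length(x), 30)] <- "N"
  d <- pairwise_difference_matrix(x)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:11) for (j in (i + 1):12) {
    cnt <- 0
    for (s in 1:40)
      if (x[i, s] != "N" && x[j, s] != "N" && x[i, s] != x[j, s])
        cnt <- cnt + 1
    expect_equal(d[i, j], cnt)
  }
  expect_error(pairwise_difference_matrix(c("AA", "AAA")), "equal length")
})

test_that("pairwise differences agree with ape's raw distance counts", {
  skip_if_not_installed("ape")
  set.seed(8)
  x <- random_base_matrix(10, 60)
  d <- pairwise_difference_matrix(x)
  bin <- ape::as.DNAbin(tolower(x))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "N"))
  expect_equal(unname(d), unname(d_ape))
})

test_that("nucleotide diversity matches manual enumeration and the matrix oracle", {
  nd <- nucleotide_diversity(c("AAA", "AAT", "ATT"))
  expect_equal(nd$k, 4 / 3)
  expect_equal(nd$pi, 4 / 9)
  expect_equal(nd$segregating_sites, 2L)
  expect_equal(nucleotide_diversity(c("AAA", "AAA"))$pi, 0)
  expect_error(nucleotide_diversity("AAA"), "at least two")
  set.seed(9)
  x <- random_base_matrix(15, 30)
  nd2 <- nucleotide_diversity(x)
  d <- pairwise_difference_matrix(x)
  expect_equal(nd2$pi, mean(d[upper.tri(d)]) / 30)
})

test_that("haplotype classes and diversity follow the textbook formulas", {
  hc <- haplotype_classes(c(a = "AAT", b = "AAT", c = "GGT"))
  expect_equal(hc$n_haplotypes, 2L)
  expect_equal(hc$n_singletons, 1L)
  x <- random_base_matrix(8, 20)
  hc2 <- haplotype_classes(x)
  expect_equal(hc2$n_haplotypes, 8L)  # random sequences: all distinct
  expect_equal(hc2$n_singletons, 8L)
  expect_equal(haplotype_diversity(c(1, 1), 2)$Hd, 1)
  expect_equal(haplotype_diversity(c(2, 2), 4)$Hd, 2 / 3)
  expect_equal(haplotype_diversity(5, 5)$Hd, 0)
  expect_equal(haplotype_diversity(5, 5)$sd, 0)
  expect_error(haplotype_diversity(c(2, 2), 5), "sum to n")
  # Hd stays in [0, 1] on random class-size vectors
  set.seed(10)
  for (r in 1:50) {
    sizes <- rmultinom(1, 40, rexp(sample(2:10, 1)))[, 1]
    sizes <- sizes[sizes > 0]
    if (length(sizes) < 1) next
    hd <- haplotype_diversity(sizes, sum(sizes))$Hd
    expect_gte(hd, 0); expect_lte(hd, 1)
  }
})

test_that("diversity statistics are invariant to animal order", {
  set.seed(11)
  x <- random_base_matrix(10, 25)
  perm <- sample(10)
  nd1 <- nucleotide_diversity(x); nd2 <- nucleotide_diversity(x[perm, ])
  expect_equal(nd1$pi, nd2$pi)
  expect_equal(sort(haplotype_classes(x)$sizes),
               sort(haplotype_classes(x[perm, ])$sizes))
  d <- pairwise_difference_matrix(x)
  expect_equal(unname(pairwise_difference_matrix(x[perm, ])),
               unname(d[perm, perm]))
})

test_that("zero-height clusters equal exact haplotype classes", {
  set.seed(12)
  for (r in 1:10) {
    base <- random_base_matrix(5, 12, n_states = 2)
    x <- base[sample(5, 18, replace = TRUE), , drop = FALSE]
    rownames(x) <- paste0("a", 1:18)
    cl <- hierarchical_clusters(pairwise_difference_matrix(x), 0)
    hc <- haplotype_classes(x)$class_id
    expect_equal(length(unique(cl)), length(unique(hc)))
    # same partition: co-membership matrices agree
    expect_identical(outer(cl, cl, "=="), outer(hc, hc, "=="))
  }
  expect_equal(length(unique(hierarchical_clusters(matrix(0, 4, 4), 0))), 1L)
  d <- pairwise_difference_matrix(random_base_matrix(6, 10))
  expect_equal(length(unique(hierarchical_clusters(d, max(d) + 1))), 1L)
})

test_that("the linkage choice is irrelevant at cut height zero", {
  set.seed(13)
  base <- random_base_matrix(4, 15)
  x <- base[sample(4, 12, replace = TRUE), , drop = FALSE]
  rownames(x) <- paste0("a", 1:12)
  d <- pairwise_difference_matrix(x)
  cl_a <- hierarchical_clusters(d, 0, method = "average")
  cl_s <- hierarchical_clusters(d, 0, method = "single")
  cl_c <- hierarchical_clusters(d, 0, method = "complete")
  expect_identical(outer(cl_a, cl_a, "=="), outer(cl_s, cl_s, "=="))
  expect_identical(outer(cl_a, cl_a, "=="), outer(cl_c, cl_c, "=="))
})

test_that("AMOVA matches the independent brute-force formulas", {
  set.seed(14)
  for (groups in list(rep(c("g1", "g2"), c(6, 9)),
                      rep(paste0("g", 1:5), c(4, 7, 5, 3, 6)))) {
    n <- length(groups)
    x <- random_base_matrix(n, 30)
    d <- pairwise_difference_matrix(x)
    # random labels: the moment estimator may go slightly negative, by design
    res <- suppressWarnings(amova(d, groups))
    oracle <- amova_oracle(d, groups)
    expect_equal(res$sigma2_among, oracle$s2a, tolerance = 1e-9)
    expect_equal(res$sigma2_within, oracle$s2w, tolerance = 1e-9)
    expect_equal(res$percent_within, oracle$pct_within, tolerance = 1e-9)
    expect_equal(res$phi_st, oracle$phi, tolerance = 1e-9)
    expect_equal(res$percent_among + res$percent_within, 100,
                 tolerance = 1e-9)
  }
})

test_that("AMOVA extremes behave as forced", {
  # identical within groups, different between: all variance among
  x <- rbind(matrix("A", 4, 10), matrix("G", 4, 10))
  rownames(x) <- paste0("a", 1:8)
  res <- suppressWarnings(amova(pairwise_difference_matrix(x),
                                rep(c("g1", "g2"), each = 4)))
  expect_equal(res$percent_within, 0)
  expect_equal(res$phi_st, 1)
  expect_error(amova(matrix(0, 3, 3), c("a", "a", "a")), "two groups")
})

test_that("random labels on a panmictic pool give a centred permutation null", {
  set.seed(15)
  x <- random_base_matrix(24, 40)
  d <- pairwise_difference_matrix(x)
  labels <- rep(c("g1", "g2", "g3"), each = 8)
  res <- suppressWarnings(amova(d, labels, n_permutations = 500, seed = 99))
  perm <- res$perm_sigma2_among
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm)), 2 * se + 1e-12)
})

test_that("the haploid GRM matches a naive double-loop computation", {
  set.seed(16)
  x <- random_base_matrix(8, 25, n_states = 2)
  G <- haploid_grm(x)
  # naive oracle: same encoding, explicit loops
  cols <- list()
  for (j in 1:25) {
    b <- x[, j]
    tab <- sort(table(b), decreasing = TRUE)
    if (length(tab) < 2) next
    for (a in setdiff(names(tab), names(tab)[1]))
      cols[[length(cols) + 1]] <- as.numeric(b == a)
  }
  X <- do.call(cbind, cols)
  p <- colMeans(X)
  Z <- sweep(sweep(X, 2, p), 2, sqrt(p * (1 - p)), "/")
  G0 <- matrix(0, 8, 8)
  for (i in 1:8) for (k in 1:8) G0[i, k] <- sum(Z[i, ] * Z[k, ]) / ncol(X)
  expect_equal(unname(G), G0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(unname(G)))
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)  # standardisation property
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)  # PSD up to numerical tolerance
  # duplicate animals give identical GRM rows
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2) <- paste0("a", 1:9)
  G2 <- haploid_grm(x2)
  expect_equal(unname(G2[1, ]), unname(G2[9, ]), tolerance = 1e-12)
  expect_error(haploid_grm(matrix("A", 3, 4,
                                  dimnames = list(letters[1:3], NULL))),
               "polymorphic")
})

test_that("PCA of the GRM has the analytic spectra and separates groups", {
  p_id <- grm_pca(diag(4), n_components = 4)
  expect_equal(p_id$values, rep(1, 4))
  expect_equal(t(p_id$vectors) %*% p_id$vectors, diag(4), tolerance = 1e-12)
  v <- c(2, 1, -1, 0.5)
  r1 <- outer(v, v)
  p_r1 <- grm_pca(r1, n_components = 4)
  expect_equal(sum(abs(p_r1$values) > 1e-8), 1L)
  expect_error(grm_pca(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  # two well-separated clades: PC1 splits them with no overlap
  cc <- clean_cohort()
  vs <- build_variant_sequences(drop_indels_and_missing(cc$tab))
  G <- haploid_grm(vs)
  pc1 <- grm_pca(G, 2)$coords[, 1]
  hg <- cc$truth$haplogroup[vs$animals]
  ranges <- tapply(pc1, hg, range)
  disjoint <- function(r1, r2) r1[2] < r2[1] || r2[2] < r1[1]
  pairs <- combn(names(ranges), 2)
  n_disjoint <- sum(apply(pairs, 2, function(p)
    disjoint(ranges[[p[1]]], ranges[[p[2]]])))
  expect_gte(n_disjoint, 1L)
  expect_true(all(diff(grm_pca(G, 3)$values) <= 1e-9))
})

test_that("per-breed diversity summaries line up with the single-group stats", {
  set.seed(17)
  x <- random_base_matrix(30, 20)
  breed <- rep(c("B1", "B2", "B3"), each = 10)
  tab <- diversity_by_group(x, breed, min_n = 10)
  expect_equal(nrow(tab), 3L)
  ref <- nucleotide_diversity(x[breed == "B2", , drop = FALSE])
  expect_equal(tab$pi[tab$group == "B2"], ref$pi)
  expect_equal(tab$k[tab$group == "B2"], ref$k)
  hd <- haplotype_diversity(haplotype_classes(x[breed == "B2", ])$sizes)
  expect_equal(tab$Hd[tab$group == "B2"], hd$Hd)
  expect_null(diversity_by_group(x, breed, min_n = 11))
})
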