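# Variome: summary counting against hand counts, the multiset distance
# against a brute-force oracle, MDS geometry, and neighbor joining against
# additive-tree theory and an independent implementation.

toy_gm <- function() {
  sites <- data.frame(seq = "chr1", pos = c(10L, 20L, 30L),
                      ref = c("A", "C", "T"),
                      alt = c("G", "A", "del:2"),
                      type = c("SNP", "SNP", "InDel"),
                      stringsAsFactors = FALSE)
  a1 <- rbind(s1 = c("G", "C", "T"), s2 = c("A", "C", "T"))
  a2 <- rbind(s1 = c("G", "A", "del:2"), s2 = c("A", "C", "T"))
  genotype_matrix(c("s1", "s2"), sites, a1, a2)
}

test_that("variome summary matches hand counts on the toy matrix", {
  s <- summarize_variome(toy_gm())
  s1 <- s[s$sample == "s1", ]
  # A->G hom alt (2 transition copies), C->A het (1 transversion copy)
  expect_equal(s1$het_snps, 1)
  expect_equal(s1$hom_snps, 1)
  expect_equal(s1$indels, 1)
  expect_equal(s1$snps_plus_indels, 3)
  expect_equal(s1$ti, 2)
  expect_equal(s1$tv, 1)
  expect_equal(s1$titv_ratio, 2.0)
  # s2 is identical to the reference everywhere
  s2 <- s[s$sample == "s2", ]
  expect_equal(unlist(s2[c("het_snps", "hom_snps", "indels",
                           "snps_plus_indels", "ti", "tv")],
                      use.names = FALSE), rep(0, 6))
  expect_true(is.na(s2$titv_ratio))
})

test_that("het plus hom equals the number of variant SNP sites per sample", {
  cfg <- small_config()
  pop <- sim_population(cfg)
  gm <- sim_genotype_matrix(pop$genomes)
  s <- summarize_variome(gm)
  snp <- gm$sites$type == "SNP"
  for (i in seq_along(gm$samples)) {
    variant_sites <- sum(snp & !is.na(gm$a1[i, ]) & !is.na(gm$a2[i, ]) &
                           (gm$a1[i, ] != gm$sites$ref |
                              gm$a2[i, ] != gm$sites$ref))
    expect_equal(s$het_snps[i] + s$hom_snps[i], variant_sites)
  }
})

test_that("allele symbols outside the site's ref/alt set are rejected", {
  sites <- data.frame(seq = "chr1", pos = 1L, ref = "A", alt = "G",
                      type = "SNP")
  expect_error(genotype_matrix("s1", sites, rbind(s1 = "T"), rbind(s1 = "G")),
               "not in ref/alt")
})

test_that("allele distances follow the worked examples", {
  sites <- data.frame(seq = "chr1", pos = c(1L, 2L), ref = c("A", "C"),
                      alt = c("G", "T"), type = "SNP")
  a1 <- rbind(x = c("A", "C"), y = c("A", "T"))
  a2 <- rbind(x = c("A", "T"), y = c("G", "T"))
  gm <- genotype_matrix(c("x", "y"), sites, a1, a2)
  # site1 A/A vs A/G -> 1; site2 C/T vs T/T -> 1
  d <- allele_distance(gm)
  expect_equal(d$d["x", "y"], 2)
  expect_equal(d$denom["x", "y"], 2)
  # identical samples
  gm2 <- genotype_matrix(c("x", "y"), sites, rbind(x = c("A", "C"),
                                                   y = c("A", "C")),
                         rbind(x = c("G", "T"), y = c("G", "T")))
  expect_equal(allele_distance(gm2)$d["x", "y"], 0)
  # n sites of opposite homozygotes hit the maximum 2n
  n <- 7
  sites_n <- data.frame(seq = "chr1", pos = seq_len(n), ref = "A",
                        alt = "G", type = "SNP")
  hom <- genotype_matrix(c("x", "y"), sites_n,
                         rbind(x = rep("A", n), y = rep("G", n)),
                         rbind(x = rep("A", n), y = rep("G", n)))
  expect_equal(allele_distance(hom)$d["x", "y"], 2 * n)
})

test_that("distances equal the brute-force multiset oracle with missingness", {
  set.seed(77)
  n_s <- 5; n_v <- 200
  sites <- data.frame(seq = "chr1", pos = seq_len(n_v), ref = "A",
                      alt = "C,G,T", type = "SNP", stringsAsFactors = FALSE)
  draw <- function() matrix(sample(c("A", "C", "G", "T"), n_s * n_v, TRUE),
                            n_s, n_v, dimnames = list(paste0("s", 1:n_s)))
  a1 <- draw(); a2 <- draw()
  miss <- matrix(runif(n_s * n_v) < 0.10, n_s, n_v)
  a1[miss] <- NA; a2[miss] <- NA
  gm <- genotype_matrix(paste0("s", 1:n_s), sites, a1, a2)
  d <- allele_distance(gm)
  for (i in 1:(n_s - 1)) {
    for (j in (i + 1):n_s) {
      want <- naive_pair_distance(a1[i, ], a2[i, ], a1[j, ], a2[j, ])
      expect_identical(unname(d$d[i, j]), as.numeric(want$d))
      expect_identical(unname(d$denom[i, j]), as.integer(want$denom))
    }
  }
  # axioms on the same output
  expect_true(isSymmetric(d$d))
  expect_true(all(diag(d$d) == 0))
  expect_true(all(d$d <= 2 * d$denom))
  # normalization divides by the pairwise denominator
  dn <- allele_distance(gm, normalize = TRUE)
  expect_equal(dn$d[1, 2], d$d[1, 2] / d$denom[1, 2])
})

test_that("a pair with no jointly called sites is an error naming the pair", {
  sites <- data.frame(seq = "chr1", pos = 1:2, ref = "A", alt = "G",
                      type = "SNP")
  a1 <- rbind(x = c("A", NA), y = c(NA, "G"))
  gm <- genotype_matrix(c("x", "y"), sites, a1, a1)
  expect_error(allele_distance(gm), "x / y")
})

test_that("permuting samples permutes every derived result consistently", {
  cfg <- small_config()
  pop <- sim_population(cfg)
  gm <- sim_genotype_matrix(pop$genomes)
  perm <- c(4, 1, 6, 2, 5, 3)
  gmp <- genotype_matrix(gm$samples[perm], gm$sites,
                         gm$a1[perm, , drop = FALSE],
                         gm$a2[perm, , drop = FALSE])
  d <- allele_distance(gm); dp <- allele_distance(gmp)
  expect_equal(dp$d, d$d[perm, perm])
  s <- summarize_variome(gm); sp <- summarize_variome(gmp)
  expect_equal(sp$het_snps, s$het_snps[perm])
  t1 <- nj_tree(d); t2 <- nj_tree(dp)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("classical MDS reproduces known geometries", {
  # equilateral triangle, side 1
  D3 <- matrix(1, 3, 3) - diag(3)
  rownames(D3) <- colnames(D3) <- c("a", "b", "c")
  co <- classical_mds(D3, dims = 2)
  expect_equal(as.numeric(dist(co)), rep(1, 3), tolerance = 1e-9)
  # two samples at distance 4: +-2 on axis 1, axis 2 identically zero
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  co2 <- classical_mds(D2, dims = 2)
  expect_equal(sort(co2[, 1]), c(-2, 2), ignore_attr = TRUE)
  expect_equal(co2[, 2], c(a = 0, b = 0))
  # all-zero distances embed at the origin without an error
  co0 <- classical_mds(matrix(0, 3, 3), dims = 2)
  expect_true(all(co0 == 0))
})

test_that("full-dimensional MDS reconstructs Euclidean distances to 1e-6", {
  set.seed(5)
  X <- matrix(rnorm(6 * 4), 6, 4)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("s", 1:6)
  co <- classical_mds(D, dims = 5)
  expect_lt(max(abs(as.matrix(dist(co)) - D) / max(D)), 1e-6)
})

test_that("the MDS sign convention makes the first nonzero loading positive", {
  set.seed(6)
  X <- matrix(rnorm(5 * 2), 5, 2)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("s", 1:5)
  co <- classical_mds(D, dims = 2)
  for (k in 1:2) {
    nz <- which(abs(co[, k]) > 1e-12)
    expect_gt(co[nz[1], k], 0)
  }
})

test_that("neighbor joining recovers a four-taxon additive tree exactly", {
  # tree ((A:1,B:2):3,(C:4,D:5)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 1 + 2
  D["A", "C"] <- D["C", "A"] <- 1 + 3 + 4
  D["A", "D"] <- D["D", "A"] <- 1 + 3 + 5
  D["B", "C"] <- D["C", "B"] <- 2 + 3 + 4
  D["B", "D"] <- D["D", "B"] <- 2 + 3 + 5
  D["C", "D"] <- D["D", "C"] <- 4 + 5
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # additive tree: cophenetic distances reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # and the cherry structure matches ((A,B),(C,D))
  ref <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("a star phylogeny yields zero-length internal branches", {
  D <- matrix(2, 4, 4) - 2 * diag(4)
  rownames(D) <- colnames(D) <- c("A", "B", "C", "D")
  tr <- nj_tree(D)
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
})

test_that("neighbor joining agrees with the reference implementation", {
  set.seed(12)
  for (rep in 1:3) {
    tr0 <- ape::rtree(7)
    D <- ape::cophenetic.phylo(tr0)
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("the simulated panel shows the hybrid signature in MDS and tree", {
  cfg <- sim_config(genome_length = 60000, n_genes = 20, rng_seed = 3)
  pop <- sim_population(cfg, n_maternal = 2, n_paternal = 2, n_f1 = 2)
  gm <- sim_genotype_matrix(pop$genomes)
  d <- allele_distance(gm)
  grp <- pop$groups[gm$samples]
  # F1 distances to the two parental groups are balanced and both smaller
  # than the parental-parental distance
  f1 <- names(grp)[grp == "f1"]
  mm <- names(grp)[grp == "maternal"]
  pp <- names(grp)[grp == "paternal"]
  d_fm <- mean(d$d[f1, mm]); d_fp <- mean(d$d[f1, pp])
  d_mp <- mean(d$d[mm, pp])
  expect_lt(abs(d_fm - d_fp) / max(d_fm, d_fp), 0.10)
  expect_lt(d_fm, d_mp)
  expect_lt(d_fp, d_mp)
  # F1 coordinates sit between the parental cluster centers on axis 1
  co <- suppressWarnings(classical_mds(d, dims = 2))
  m_ctr <- mean(co[mm, 1]); p_ctr <- mean(co[pp, 1])
  expect_true(all((co[f1, 1] - m_ctr) * (co[f1, 1] - p_ctr) < 0))
  # maternal accessions form a clade away from the paternal side
  tr <- ape::root(nj_tree(d), outgroup = pp[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(tr, mm))
})

test_that("genotype matrices survive a VCF round trip", {
  cfg <- small_config()
  pop <- sim_population(cfg)
  gm <- sim_genotype_matrix(pop$genomes)
  f <- tempfile(fileext = ".vcf")
  write_vcf_genotypes(gm, f)
  back <- read_vcf_genotypes(f)
  expect_identical(back$samples, gm$samples)
  expect_equal(back$sites, gm$sites, ignore_attr = TRUE)
  # genotypes are unordered pairs; compare sorted pairs
  sort_pair <- function(g) {
    p1 <- pmin(g$a1, g$a2); p2 <- pmax(g$a1, g$a2)
    list(p1, p2)
  }
  expect_identical(sort_pair(back), sort_pair(gm))
})
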