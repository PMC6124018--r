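# Generator contracts: rate calibration, determinism, inheritance structure,
# coverage accounting, output well-formedness.

test_that("zero mutation rates give identical parents equal to the ancestor", {
  cfg <- sim_config(genome_length = 5000, n_genes = 2,
                    interspecies_divergence = 0,
                    intraspecies_heterozygosity = 0, rng_seed = 2)
  p <- simulate_parents(cfg)
  expect_identical(p$maternal$seq$a, p$ancestral)
  expect_identical(p$maternal$seq$b, p$ancestral)
  expect_identical(p$paternal$seq$a, p$ancestral)
  expect_identical(p$paternal$seq$b, p$ancestral)
  expect_equal(nrow(p$maternal$variants$a), 0)
  expect_equal(nrow(p$paternal$variants$b), 0)
})

test_that("interspecies variant counts track the binomial expectation", {
  L <- 1e5; d <- 0.01
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(genome_length = L, n_genes = 10,
                      interspecies_divergence = d, indel_fraction = 0,
                      intraspecies_heterozygosity = 0, rng_seed = s)
    p <- simulate_parents(cfg)
    nrow(p$maternal$species_variants) + nrow(p$paternal$species_variants)
  }, numeric(1))
  sigma <- sqrt(L * d * (1 - d))
  expect_lt(abs(mean(counts) - L * d), 3 * sigma / sqrt(length(counts)))
})

test_that("identical configuration reproduces byte-identical outputs", {
  cfg <- small_config()
  p1 <- simulate_parents(cfg)
  p2 <- simulate_parents(cfg)
  expect_identical(p1, p2)
  r1 <- simulate_reads(p1$maternal, cfg)
  r2 <- simulate_reads(p2$maternal, cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(p1$maternal, f1)
  write_genome_fasta(p2$maternal, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  q1 <- tempfile(fileext = ".fastq"); q2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, q1); write_fastq(r2, q2)
  expect_identical(unname(tools::md5sum(q1)), unname(tools::md5sum(q2)))
})

test_that("haplotypes reconstruct from ancestral plus their variant table", {
  p <- small_parents()
  for (g in list(p$maternal, p$paternal)) {
    for (h in c("a", "b")) {
      re <- apply_variants(g$ancestral, g$variants[[h]])
      expect_identical(re$seq, g$seq[[h]])
      expect_identical(re$map, g$map[[h]])
    }
  }
})

test_that("unidentifiable rate combinations are rejected", {
  cfg <- sim_config(genome_length = 2000, n_genes = 1,
                    interspecies_divergence = 0.3,
                    intraspecies_heterozygosity = 0.25)
  expect_error(simulate_parents(cfg), "no longer identifiable")
  expect_error(sim_config(genome_length = 100, n_genes = 10,
                          gene_length_mean = 100), "genome_length")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(error_rate = 1), "rates")
})

test_that("an F1 carries one maternal and one paternal donor at every gene", {
  cfg <- small_config()
  p <- simulate_parents(cfg)
  genes <- emit_gene_annotation(cfg)
  off <- simulate_offspring(p$maternal, p$paternal, cfg, genes = genes)
  go <- off$truth$gene_origin
  expect_equal(nrow(go), length(genes))
  expect_true(all(go$donor_hapA == "maternal"))
  expect_true(all(go$donor_hapB == "paternal"))
  expect_setequal(go$gene_id, genes$gene_id)
  expect_false(anyDuplicated(go$gene_id) > 0)
})

test_that("offspring simulation rejects parents on different coordinates", {
  cfg <- small_config()
  p <- simulate_parents(cfg)
  other <- simulate_parents(small_config(rng_seed = 43L))
  expect_error(simulate_offspring(p$maternal, other$paternal, cfg),
               "coordinate system")
})

test_that("a BC1 without recombination inherits whole-haplotype blocks", {
  cfg <- small_config(offspring_type = "BC1", bc_recomb_rate = 0)
  p <- simulate_parents(cfg)
  genes <- emit_gene_annotation(cfg)
  off <- simulate_offspring(p$maternal, p$paternal, cfg, genes = genes)
  go <- off$truth$gene_origin
  expect_length(unique(go$donor_hapA), 1)
  expect_true(all(go$donor_hapB == "maternal"))
  expect_equal(nrow(off$truth$donor_segments), 1)
})

test_that("BC1 donor switches along the gene track follow the Poisson rate", {
  sw <- vapply(1:50, function(s) {
    cfg <- sim_config(genome_length = 50000, n_genes = 50,
                      gene_length_mean = 800, offspring_type = "BC1",
                      bc_recomb_rate = 2, coverage = 5, rng_seed = s)
    p <- simulate_parents(cfg)
    genes <- emit_gene_annotation(cfg)
    off <- simulate_offspring(p$maternal, p$paternal, cfg, genes = genes)
    d <- off$truth$gene_origin$donor_hapA
    sum(d[-1] != d[-length(d)])
  }, numeric(1))
  # SE of the mean of 50 Poisson(2) draws is 0.2; allow 3 SE
  expect_lt(abs(mean(sw) - 2), 0.6)
})

test_that("emitted bases realize the configured per-haplotype coverage", {
  cfg <- small_config(coverage = 17)
  p <- simulate_parents(cfg)
  rs <- simulate_reads(p$paternal, cfg)
  hap_total <- nchar(p$paternal$seq$a) + nchar(p$paternal$seq$b)
  expect_lt(abs(rs$total_bases / hap_total - 17) / 17, 0.02)
})

test_that("error-free reads are exact substrings of their source haplotype", {
  cfg <- small_config(error_rate = 0)
  p <- simulate_parents(cfg)
  rs <- simulate_reads(p$maternal, cfg)
  idx <- seq(1, length(rs$reads), by = 37)
  for (i in idx) {
    h <- rs$sidecar$haplotype[i]
    s <- rs$sidecar$start[i]
    expect_identical(rs$reads[i],
                     substr(p$maternal$seq[[h]], s, s + rs$read_length - 1))
  }
})

test_that("read simulation rejects reads longer than the genome", {
  cfg <- small_config()
  p <- simulate_parents(cfg)
  cfg_long <- small_config(genome_length = 30000L)
  cfg_long$read_length <- 40000L
  expect_error(simulate_reads(p$maternal, cfg_long), "read_length")
})

test_that("FASTQ records are well-formed with matching quality lengths", {
  cfg <- small_config(coverage = 2)
  p <- simulate_parents(cfg)
  rs <- simulate_reads(p$maternal, cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  lines <- readLines(fq)
  expect_equal(length(lines) %% 4, 0)
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  expect_identical(nchar(seqs), nchar(quals))
  expect_true(all(startsWith(lines[seq(1, length(lines), by = 4)], "@")))
  back <- read_fastq(fq)
  expect_identical(unname(as.character(back)), rs$reads)
})

test_that("gene annotation is sorted, non-overlapping, with calibrated lengths", {
  cfg <- sim_config(genome_length = 400000, n_genes = 250,
                    gene_length_mean = 1000, rng_seed = 7)
  genes <- emit_gene_annotation(cfg)
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  expect_true(all(diff(st) > 0))
  expect_true(all(st[-1] > en[-length(en)]))
  expect_lt(abs(mean(en - st + 1) - 1000) / 1000, 0.10)
  # empty annotation
  empty <- emit_gene_annotation(sim_config(genome_length = 1000, n_genes = 0))
  expect_length(empty, 0)
})

test_that("S-locus accessions are heterozygous and trios obey GSI", {
  ped <- data.frame(child = "kid", mother = "acc01", father = "acc02")
  sim <- simulate_s_locus(c(sprintf("acc%02d", 1:4), "kid"), pool_size = 6,
                          pedigree = ped, rng_seed = 5)
  expect_true(all(sim$truth$class1 != sim$truth$class2))
  kid <- sim$truth["kid", ]
  mo <- unlist(sim$truth["acc01", c("class1", "class2")])
  fa <- unlist(sim$truth["acc02", c("class1", "class2")])
  kid_pair <- c(kid$class1, kid$class2)
  expect_length(intersect(kid_pair, mo), 1)
  pat <- setdiff(kid_pair, intersect(kid_pair, mo))
  expect_true(pat %in% fa)
  expect_false(pat %in% mo)
})

test_that("a GSI-incompatible pedigree (selfing) is rejected", {
  ped <- data.frame(child = "kid", mother = "acc01", father = "acc01")
  expect_error(simulate_s_locus(c("acc01", "kid"), pool_size = 4,
                                pedigree = ped, rng_seed = 1),
               "unsatisfiable under GSI")
})
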