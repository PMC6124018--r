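# S-locus: clustering recovery against simulator truth, GSI laws, trio
# consistency, cross prediction and the sharing network.

shared_sim <- function() cached("slocus12", {
  sim <- simulate_s_locus(12, pool_size = 8, rng_seed = 6)
  list(sim = sim, sh = cluster_s_alleles(sim$alleles))
})

test_that("alignment identity behaves across the divergence spectrum", {
  withr::with_seed(3, {
    a <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  })
  expect_equal(align_identity(a, a), 1)
  near <- paste0(substr(a, 1, 590), "ACGTACGTAC")  # ~98% identical
  expect_gt(align_identity(a, near), 0.95)
  # modest length difference with identical overlap stays high
  expect_gt(align_identity(a, substr(a, 1, 570)), 0.94)
  # unrelated sequences must not reach the class threshold through a
  # chance short overlap
  expect_lt(align_identity(a, b), 0.9)
})

test_that("clustering recovers the simulated classes as an exact partition", {
  x <- shared_sim()
  units <- x$sh$units
  tt <- x$sim$truth
  units$truth <- vapply(seq_len(nrow(units)), function(i)
    tt[units$accession[i], paste0("class", units$copy[i])], "")
  tab <- table(units$truth, units$class)
  # bijection between truth classes and called classes
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # partition law: every unit in exactly one class
  expect_equal(sum(lengths(x$sh$classes)), nrow(units))
  # GSI law: every simulated accession heterozygous, no homozygote flags
  expect_true(all(x$sh$assignment$flags == ""))
  expect_true(all(x$sh$assignment$class1 != x$sh$assignment$class2))
})

test_that("class labels are stable under input reordering", {
  x <- shared_sim()
  withr::with_seed(99, {
    shuffled <- x$sim$alleles[sample(nrow(x$sim$alleles)), ]
  })
  sh2 <- cluster_s_alleles(shuffled)
  a1 <- x$sh$assignment[order(x$sh$assignment$accession), ]
  a2 <- sh2$assignment[order(sh2$assignment$accession), ]
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("identical duplicated copies collapse to one flagged class", {
  base <- paste(rep("ACGT", 150), collapse = "")
  al <- data.frame(accession = "acc", gene = rep(c("S-RNase", "SFB"), 2),
                   copy = c(1L, 1L, 2L, 2L),
                   sequence = rep(c(base, paste0(base, "AA")), 2),
                   stringsAsFactors = FALSE)
  sh <- expect_silent(cluster_s_alleles(al))
  expect_equal(length(sh$classes), 1)
  expect_equal(sh$assignment$flags, "putative_homozygote")
})

test_that("mutually dissimilar alleles become singleton classes", {
  withr::with_seed(14, {
    al <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(accession = paste0("a", i),
                 gene = rep(c("S-RNase", "SFB"), 2),
                 copy = c(1L, 1L, 2L, 2L),
                 sequence = replicate(4, paste(
                   sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")),
                 stringsAsFactors = FALSE)
    }))
  })
  sh <- cluster_s_alleles(al)
  expect_equal(length(sh$classes), 6)
  expect_true(all(lengths(sh$classes) == 1))
})

test_that("trio checks enumerate donor assignments under pollen rejection", {
  a <- data.frame(accession = c("mo", "fa", "ch"),
                  class1 = c("S1", "S3", "S2"),
                  class2 = c("S2", "S4", "S3"),
                  stringsAsFactors = FALSE)
  r <- check_trio("ch", "mo", "fa", a)
  expect_true(r$consistent)
  expect_equal(r$donors, c(maternal = "S2", paternal = "S3"))
  # child carrying both paternal classes is impossible
  a2 <- a; a2$class1[3] <- "S3"; a2$class2[3] <- "S4"
  expect_false(check_trio("ch", "mo", "fa", a2)$consistent)
  # shared class S2: S2 cannot be the paternal donation (rejected pollen)
  # but works maternally with S3 donated by the father
  a3 <- data.frame(accession = c("mo", "fa", "ch"),
                   class1 = c("S1", "S2", "S2"),
                   class2 = c("S2", "S3", "S3"),
                   stringsAsFactors = FALSE)
  r3 <- check_trio("ch", "mo", "fa", a3)
  expect_true(r3$consistent)
  expect_equal(r3$donors, c(maternal = "S2", paternal = "S3"))
})

test_that("simulated trios are consistent; shuffled parents are rejected", {
  ped <- data.frame(child = c("kid1", "kid2"),
                    mother = c("acc01", "acc02"),
                    father = c("acc03", "acc04"))
  sim <- simulate_s_locus(c(sprintf("acc%02d", 1:4), "kid1", "kid2"),
                          pool_size = 8, pedigree = ped, rng_seed = 20)
  sh <- cluster_s_alleles(sim$alleles)
  # map truth labels to called labels through any accession
  expect_true(check_trio("kid1", "acc01", "acc03", sh)$consistent)
  expect_true(check_trio("kid2", "acc02", "acc04", sh)$consistent)
  # wrong parents that share no S class with the child are always rejected
  asg <- sh$assignment
  kid_pair <- assignment_classes(asg, "kid1")
  unrelated <- vapply(sprintf("acc%02d", 1:4), function(a)
    length(intersect(kid_pair, assignment_classes(asg, a))) == 0, logical(1))
  for (a in names(unrelated)[unrelated]) {
    expect_false(check_trio("kid1", a, "acc03", sh)$consistent &&
                   check_trio("kid1", "acc01", a, sh)$consistent)
  }
  # and shuffled pairings are mostly rejected as the pool grows
  shuffles <- rbind(c("kid1", "acc02", "acc04"), c("kid1", "acc04", "acc02"),
                    c("kid2", "acc01", "acc03"), c("kid2", "acc03", "acc01"))
  ok <- vapply(seq_len(nrow(shuffles)), function(i)
    check_trio(shuffles[i, 1], shuffles[i, 2], shuffles[i, 3],
               sh)$consistent, logical(1))
  expect_lt(mean(ok), 1)
})

test_that("cross compatibility counts escaping pollen classes", {
  expect_equal(predict_cross(c("S1", "S2"), c("S1", "S2")), "incompatible")
  expect_equal(predict_cross(c("S1", "S2"), c("S2", "S3")), "semi_compatible")
  expect_equal(predict_cross(c("S1", "S2"), c("S3", "S4")), "fully_compatible")
})

test_that("the sharing network equals the planted truth edge set", {
  x <- shared_sim()
  net <- build_s_network(x$sh)
  # independent edge construction from the truth labels
  tt <- x$sim$truth
  want <- list()
  accs <- sort(tt$accession)
  for (i in seq_along(accs)) for (j in seq_along(accs)) {
    if (j <= i) next
    shared <- intersect(unlist(tt[accs[i], c("class1", "class2")]),
                        unlist(tt[accs[j], c("class1", "class2")]))
    for (cl in shared)
      want[[length(want) + 1L]] <- paste(accs[i], accs[j])
  }
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, unlist(want))
  # network law: edge iff class sets intersect, checked exhaustively
  asg <- x$sh$assignment
  for (i in seq_along(accs)) for (j in seq_along(accs)) {
    if (j <= i) next
    inter <- length(intersect(
      unlist(asg[asg$accession == accs[i], c("class1", "class2")]),
      unlist(asg[asg$accession == accs[j], c("class1", "class2")]))) > 0
    has_edge <- any(net$edges$from == accs[i] & net$edges$to == accs[j])
    expect_equal(has_edge, inter)
  }
})

test_that("degenerate networks: no sharing and full sharing", {
  none <- data.frame(accession = c("a", "b"), class1 = c("S1", "S3"),
                     class2 = c("S2", "S4"))
  expect_equal(nrow(build_s_network(none)$edges), 0)
  tri <- data.frame(accession = c("a", "b", "c"),
                    class1 = c("S1", "S1", "S1"),
                    class2 = c("S2", "S3", "S4"))
  net <- build_s_network(tri)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$class == "S1"))
})

test_that("alleles and networks round-trip through their file formats", {
  x <- shared_sim()
  f <- tempfile(fileext = ".fasta")
  write_s_alleles(x$sim$alleles, f)
  back <- read_s_alleles(f)
  expect_equal(back, x$sim$alleles, ignore_attr = TRUE)
  net <- build_s_network(x$sh,
                         metadata = data.frame(
                           accession = x$sim$truth$accession,
                           taxon = "synthetic"))
  e <- tempfile(fileext = ".tsv"); g <- tempfile(fileext = ".graphml")
  write_s_network(net, e, g)
  expect_equal(read_tsv(e), net$edges, ignore_attr = TRUE)
  expect_true(file.size(g) > 0)
  bad <- Biostrings::DNAStringSet("ACGT")
  names(bad) <- "no_grammar"
  fb <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(bad, fb)
  expect_error(read_s_alleles(fb), "accession\\|gene\\|copy")
})
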