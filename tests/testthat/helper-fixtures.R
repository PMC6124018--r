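# Shared small fixtures, built in code. Caches live for the test run.

.fix_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_env[[key]])) .fix_env[[key]] <- force(expr)
  .fix_env[[key]]
}

small_config <- function(...) {
  args <- modifyList(list(genome_length = 30000L, n_genes = 15L,
                          gene_length_mean = 800L, coverage = 10,
                          error_rate = 0, rng_seed = 42L), list(...))
  do.call(sim_config, args)
}

small_parents <- function() cached("parents", simulate_parents(small_config()))

assignment_classes <- function(asg, acc) {
  unlist(asg[asg$accession == acc, c("class1", "class2")], use.names = FALSE)
}

tempfile_with <- function(content) {
  f <- tempfile(fileext = ".tsv")
  writeLines(content, f, sep = "")
  f
}

# Naive canonical k-mer recount used as the independent oracle.
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

naive_kmer_histogram <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character())
    substring(r, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  canon <- pmin(kmers, revcomp_chr(kmers))
  tab <- table(table(canon))
  data.frame(multiplicity = as.integer(names(tab)),
             count = as.numeric(tab))
}

# Brute-force multiset allele-difference oracle.
naive_pair_distance <- function(a1i, a2i, a1j, a2j) {
  d <- 0; denom <- 0
  for (s in seq_along(a1i)) {
    g1 <- c(a1i[s], a2i[s]); g2 <- c(a1j[s], a2j[s])
    if (anyNA(g1) || anyNA(g2)) next
    denom <- denom + 1
    shared <- 0
    pool <- g2
    for (al in g1) {
      hit <- match(al, pool)
      if (!is.na(hit)) { shared <- shared + 1; pool <- pool[-hit] }
    }
    d <- d + (2 - shared)
  }
  list(d = d, denom = denom)
}

# Literal restatement of the published decision ladder, used as the
# exhaustive classification oracle.
oracle_classify <- function(cov_m, cov_p, s_m, s_p, fold = 2,
                            min_support = 1, min_breadth = 0.5) {
  if (cov_m == 0 && cov_p == 0) return("NO_DATA")
  if (cov_p == 0 && cov_m >= min_breadth) return("UNIQUE_MATERNAL")
  if (cov_m == 0 && cov_p >= min_breadth) return("UNIQUE_PATERNAL")
  m_ok <- (s_m >= fold * s_p) && (s_m >= min_support)
  p_ok <- (s_p >= fold * s_m) && (s_p >= min_support)
  if (m_ok && p_ok) return("COMMON")
  if (m_ok) return("PHASED_MATERNAL")
  if (p_ok) return("PHASED_PATERNAL")
  "COMMON"
}

make_grid_evidence <- function(cov_m, cov_p, s_m, s_p) {
  data.frame(gene_id = sprintf("g%d", seq_along(cov_m)), seq = "chr1",
             start = 1L, end = 1000L, cov_m = cov_m, cov_p = cov_p,
             support_m = s_m, support_p = s_p,
             sites_considered = s_m + s_p, stringsAsFactors = FALSE)
}

make_evidence <- function(cov_m, cov_p, s_m, s_p) {
  data.frame(gene_id = "g", seq = "chr1", start = 1L, end = 1000L,
             cov_m = cov_m, cov_p = cov_p,
             support_m = s_m, support_p = s_p,
             sites_considered = s_m + s_p,
             stringsAsFactors = FALSE)
}
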