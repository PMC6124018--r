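# S-locus simulation: a pool of S-haplotype classes (linked S-RNase/SFB
# sequence pairs), heterozygous accessions, and pedigrees constrained by
# gametophytic self-incompatibility (GSI): a pollen S class present in the
# seed parent is rejected, so offspring are always heterozygous and the
# paternal donation never matches either maternal class.

#' Simulate S-locus alleles for a set of accessions
#'
#' Builds a pool of `pool_size` S-haplotype classes. Class sequences for the
#' two linked genes (S-RNase ~ 700 bp, SFB ~ 1000 bp) are derived from one
#' base sequence per gene mutated independently at 8% per class, so classes
#' differ pairwise by well over 5%; each accession's allele copy adds private
#' noise at 0.1%, keeping within-class divergence comfortably under 0.5%. Accessions
#' without pedigree get a random pair of distinct classes; trio offspring
#' receive one maternal class and one GSI-compatible paternal class.
#'
#' @param accessions Character vector of accession names, or a count (names
#'   are then generated).
#' @param pool_size Number of S-haplotype classes in the population pool
#'   (>= 2).
#' @param pedigree Optional data.frame with columns `child, mother, father`
#'   (accession names; parents must appear in `accessions`).
#' @param rng_seed Integer seed.
#' @return A list with `alleles` (data.frame `accession, gene, copy,
#'   sequence`), `truth` (data.frame `accession, class1, class2`) and
#'   `class_sequences` (list per class per gene).
#' @examples
#' sim <- simulate_s_locus(4, pool_size = 5, rng_seed = 2)
#' sim$truth
#' @export
simulate_s_locus <- function(accessions, pool_size, pedigree = NULL,
                             rng_seed = 1L) {
  if (pool_size < 2) stop("pool_size must be >= 2")
  if (is.numeric(accessions))
    accessions <- sprintf("acc%02d", seq_len(accessions))
  withr::with_seed(stage_seed(rng_seed, "slocus"), {
    gene_len <- c("S-RNase" = 700L, "SFB" = 1000L)
    base <- lapply(gene_len, random_dna)
    classes <- lapply(seq_len(pool_size), function(i) {
      lapply(base, function(s) mutate_sequence(s, 0.08))
    })
    names(classes) <- sprintf("truthS%02d", seq_len(pool_size))

    truth <- data.frame(accession = accessions,
                        class1 = NA_character_, class2 = NA_character_,
                        stringsAsFactors = FALSE)
    rownames(truth) <- accessions
    ped_children <- if (is.null(pedigree)) character() else pedigree$child
    for (acc in setdiff(accessions, ped_children)) {
      pair <- sample(names(classes), 2L)
      truth[acc, c("class1", "class2")] <- sort(pair)
    }
    if (!is.null(pedigree)) {
      for (i in seq_len(nrow(pedigree))) {
        mo <- unlist(truth[pedigree$mother[i], c("class1", "class2")])
        fa <- unlist(truth[pedigree$father[i], c("class1", "class2")])
        if (any(is.na(mo)) || any(is.na(fa)))
          stop("pedigree parents must precede children")
        pollen_ok <- setdiff(fa, mo)
        if (length(pollen_ok) == 0)
          stop("pedigree unsatisfiable under GSI: both pollen classes of '",
               pedigree$father[i], "' are present in seed parent '",
               pedigree$mother[i], "'")
        maternal_don <- sample(mo, 1L)
        paternal_don <- if (length(pollen_ok) == 1) pollen_ok else
          sample(pollen_ok, 1L)
        truth[pedigree$child[i], c("class1", "class2")] <-
          sort(c(maternal_don, paternal_don))
      }
    }

    rows <- list()
    for (acc in accessions) {
      for (copy in 1:2) {
        cls <- truth[acc, paste0("class", copy)]
        for (g in names(gene_len)) {
          rows[[length(rows) + 1L]] <- data.frame(
            accession = acc, gene = g, copy = copy,
            sequence = mutate_sequence(classes[[cls]][[g]], 0.001),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(alleles = do.call(rbind, rows), truth = truth,
         class_sequences = classes)
  })
}

# Point-mutate a sequence at the given per-base rate (substitutions only).
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) chars[hit] <- other_base(chars[hit])
  paste(chars, collapse = "")
}
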