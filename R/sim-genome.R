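# Diploid genome simulation: ancestral sequence, species divergence,
# within-species heterozygosity, and haplotype materialization.
#
# Variant tables are data.frames with columns
#   pos  : 1-based position on the ancestral coordinate system
#   type : "sub", "ins" or "del"
#   ref  : ancestral bases replaced ("" for insertions)
#   alt  : replacement bases ("" for deletions; insertions go AFTER pos)
# Every haplotype is ancestral + its own variant table, so all haplotypes of
# all individuals share one coordinate system.

empty_variants <- function() {
  data.frame(pos = integer(), type = character(),
             ref = character(), alt = character(),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(.dna_bases, n, replace = TRUE), collapse = "")
}

other_base <- function(base) {
  idx <- match(base, .dna_bases)
  .dna_bases[((idx - 1L + sample.int(3L, length(base), replace = TRUE)) %% 4L) + 1L]
}

# Substitution with transition bias: a transition (A<->G, C<->T) is drawn
# with probability ti_prob, otherwise one of the two transversions.
# ti_prob = 0.608 puts the expected Ti/Tv ratio at ~1.55, the regime
# observed in Prunus resequencing panels.
.transition_of <- c(A = "G", C = "T", G = "A", T = "C")
.transversions_of <- list(A = c("C", "T"), C = c("A", "G"),
                          G = c("C", "T"), T = c("A", "G"))

substitute_base <- function(base, ti_prob = 0.608) {
  n <- length(base)
  is_ti <- runif(n) < ti_prob
  out <- character(n)
  out[is_ti] <- .transition_of[base[is_ti]]
  if (any(!is_ti)) {
    pick <- sample.int(2L, sum(!is_ti), replace = TRUE)
    out[!is_ti] <- vapply(seq_len(sum(!is_ti)), function(i) {
      .transversions_of[[base[!is_ti][i]]][pick[i]]
    }, "")
  }
  out
}

# Draw variant records at i.i.d. uniform positions. `exclude` positions are
# never used (avoids stacking a heterozygous variant on a species site).
draw_variants <- function(anc_chars, rate, indel_fraction, exclude = integer()) {
  L <- length(anc_chars)
  if (rate <= 0) return(empty_variants())
  pos <- which(runif(L) < rate)
  pos <- setdiff(pos, exclude)
  n <- length(pos)
  if (n == 0) return(empty_variants())
  is_indel <- runif(n) < indel_fraction
  type <- ifelse(is_indel, ifelse(runif(n) < 0.5, "ins", "del"), "sub")
  len <- ifelse(type == "sub", 1L, sample(10L, n, replace = TRUE))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]
    if (type[i] == "sub") {
      ref[i] <- anc_chars[p]
      alt[i] <- substitute_base(anc_chars[p])
    } else if (type[i] == "ins") {
      ref[i] <- ""
      alt[i] <- paste(sample(.dna_bases, len[i], replace = TRUE), collapse = "")
    } else {
      end <- min(L, p + len[i] - 1L)
      ref[i] <- paste(anc_chars[p:end], collapse = "")
      alt[i] <- ""
    }
  }
  data.frame(pos = pos, type = type, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Materialize a haplotype from the ancestral sequence and a variant table
#'
#' @param ancestral Ancestral sequence (single character string).
#' @param variants Variant table: columns `pos`, `type` (`"sub"`, `"ins"`,
#'   `"del"`), `ref`, `alt` on ancestral coordinates; insertions are placed
#'   after `pos`, deletions remove `nchar(ref)` bases starting at `pos`.
#' @return A list with `seq` (the haplotype string) and `map`, an integer
#'   vector giving, for every haplotype base, its ancestral coordinate
#'   (`NA` for inserted bases).
#' @export
apply_variants <- function(ancestral, variants) {
  anc <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  L <- length(anc)
  if (nrow(variants) == 0)
    return(list(seq = ancestral, map = seq_len(L)))
  v <- variants[order(variants$pos), , drop = FALSE]
  seq_parts <- vector("list", 2L * nrow(v) + 1L)
  map_parts <- vector("list", 2L * nrow(v) + 1L)
  np <- 0L
  push <- function(chars, map) {
    np <<- np + 1L
    seq_parts[[np]] <<- chars
    map_parts[[np]] <<- map
  }
  cur <- 1L
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    if (p < cur) next  # swallowed by an earlier deletion
    if (v$type[i] == "sub") {
      if (p > cur) push(anc[cur:(p - 1L)], cur:(p - 1L))
      push(v$alt[i], p)
      cur <- p + 1L
    } else if (v$type[i] == "ins") {
      push(anc[cur:p], cur:p)
      ins <- strsplit(v$alt[i], "", fixed = TRUE)[[1]]
      push(ins, rep(NA_integer_, length(ins)))
      cur <- p + 1L
    } else {  # del
      if (p > cur) push(anc[cur:(p - 1L)], cur:(p - 1L))
      cur <- p + nchar(v$ref[i])
    }
  }
  if (cur <= L) push(anc[cur:L], cur:L)
  list(seq = paste(unlist(seq_parts[seq_len(np)]), collapse = ""),
       map = as.integer(unlist(map_parts[seq_len(np)])))
}

new_diploid_genome <- function(label, ancestral, seq_a, seq_b,
                               map_a, map_b, var_a, var_b,
                               species_variants = empty_variants()) {
  structure(list(label = label,
                 ancestral = ancestral,
                 ancestral_length = nchar(ancestral),
                 seq = list(a = seq_a, b = seq_b),
                 map = list(a = map_a, b = map_b),
                 variants = list(a = var_a, b = var_b),
                 species_variants = species_variants),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("diploid_genome '%s': haplotypes %d / %d bp (ancestral %d bp), %d + %d variants\n",
              x$label, nchar(x$seq$a), nchar(x$seq$b), x$ancestral_length,
              nrow(x$variants$a), nrow(x$variants$b)))
  invisible(x)
}

#' Simulate two diverged diploid parental genomes
#'
#' Draws a random ancestral chromosome, splits it into a maternal and a
#' paternal species (differing sites at rate `interspecies_divergence`, each
#' assigned to one species relative to the shared ancestor), then gives each
#' parent within-species heterozygosity at rate
#' `intraspecies_heterozygosity`. A fraction `indel_fraction` of all variant
#' sites become 1--10 bp InDels.
#'
#' @param config A [sim_config()].
#' @return A list with `maternal` and `paternal` (`diploid_genome` objects)
#'   and `ancestral` (character string).
#' @examples
#' p <- simulate_parents(sim_config(genome_length = 20000, n_genes = 5,
#'                                  rng_seed = 1))
#' p$maternal
#' @export
simulate_parents <- function(config) {
  validate_sim_config(config)
  if (config$interspecies_divergence + config$intraspecies_heterozygosity >= 0.5)
    stop("divergence + heterozygosity >= 0.5: alleles no longer identifiable")
  withr::with_seed(stage_seed(config$rng_seed, "parents"), {
    L <- config$genome_length
    ancestral <- random_dna(L)
    anc <- strsplit(ancestral, "", fixed = TRUE)[[1]]
    sp_var <- draw_variants(anc, config$interspecies_divergence,
                            config$indel_fraction)
    to_m <- runif(nrow(sp_var)) < 0.5
    founders <- list(maternal = sp_var[to_m, , drop = FALSE],
                     paternal = sp_var[!to_m, , drop = FALSE])
    genomes <- lapply(names(founders), function(lab) {
      founder <- founders[[lab]]
      het <- draw_variants(anc, config$intraspecies_heterozygosity,
                           config$indel_fraction, exclude = sp_var$pos)
      on_a <- runif(nrow(het)) < 0.5
      var_a <- rbind(founder, het[on_a, , drop = FALSE])
      var_b <- rbind(founder, het[!on_a, , drop = FALSE])
      var_a <- var_a[order(var_a$pos), , drop = FALSE]
      var_b <- var_b[order(var_b$pos), , drop = FALSE]
      hap_a <- apply_variants(ancestral, var_a)
      hap_b <- apply_variants(ancestral, var_b)
      new_diploid_genome(lab, ancestral, hap_a$seq, hap_b$seq,
                         hap_a$map, hap_b$map, var_a, var_b,
                         species_variants = founder)
    })
    names(genomes) <- names(founders)
    list(maternal = genomes$maternal, paternal = genomes$paternal,
         ancestral = ancestral)
  })
}

#' Haplotype alleles at ancestral coordinates
#'
#' Looks up the base a haplotype carries at given ancestral positions:
#' the ancestral base unless overridden by a substitution, `NA` where the
#' position falls inside a deletion.
#'
#' @param genome A `diploid_genome`.
#' @param hap `"a"` or `"b"`.
#' @param pos Integer vector of ancestral positions.
#' @return Character vector of alleles (`NA` for deleted positions).
#' @export
allele_at <- function(genome, hap, pos) {
  out <- substring(genome$ancestral, pos, pos)
  v <- genome$variants[[hap]]
  subs <- v[v$type == "sub", , drop = FALSE]
  hit <- match(pos, subs$pos)
  out[!is.na(hit)] <- subs$alt[hit[!is.na(hit)]]
  dels <- v[v$type == "del", , drop = FALSE]
  for (i in seq_len(nrow(dels))) {
    inside <- pos >= dels$pos[i] & pos < dels$pos[i] + nchar(dels$ref[i])
    out[inside] <- NA_character_
  }
  out
}

#' Simulate an F1 or BC1 offspring with ground truth
#'
#' F1: one randomly chosen haplotype from each parent becomes the child's
#' `a` (maternal) and `b` (paternal) haplotype, so every gene carries exactly
#' one maternal-donated and one paternal-donated copy. BC1: a recombined F1
#' gamete (crossovers Poisson-distributed at `bc_recomb_rate`) plus one
#' haplotype of the recurrent (maternal) parent. The truth records the donor
#' of each child haplotype per gene and the number of species-diagnostic
#' substitution sites per gene.
#'
#' @param maternal,paternal `diploid_genome` parents sharing one ancestral
#'   coordinate system.
#' @param config A [sim_config()]; `offspring_type` selects F1 or BC1.
#' @param genes Optional [GenomicRanges::GRanges] of gene models (from
#'   [emit_gene_annotation()]) used to fill the per-gene truth.
#' @return A list with `child` (`diploid_genome`) and `truth` (list with
#'   `gene_origin` data.frame, `true_haploid_size`, `donor_segments`,
#'   `picks`).
#' @export
simulate_offspring <- function(maternal, paternal, config, genes = NULL) {
  stopifnot(is(maternal, "diploid_genome"), is(paternal, "diploid_genome"))
  if (maternal$ancestral_length != paternal$ancestral_length ||
      !identical(maternal$ancestral, paternal$ancestral))
    stop("parents do not share a coordinate system")
  validate_sim_config(config)
  L <- maternal$ancestral_length
  withr::with_seed(stage_seed(config$rng_seed, "offspring"), {
    pick_m <- sample(c("a", "b"), 1L)
    pick_p <- sample(c("a", "b"), 1L)
    if (config$offspring_type == "F1") {
      child <- new_diploid_genome(
        "offspring_F1", maternal$ancestral,
        maternal$seq[[pick_m]], paternal$seq[[pick_p]],
        maternal$map[[pick_m]], paternal$map[[pick_p]],
        maternal$variants[[pick_m]], paternal$variants[[pick_p]])
      segments <- data.frame(start = 1L, end = L, donor = "maternal",
                             stringsAsFactors = FALSE)
      donor_b <- "paternal"
    } else {
      # F1 gamete: alternate between the transmitted maternal and paternal
      # haplotypes at Poisson-distributed crossover breakpoints.
      n_x <- rpois(1L, config$bc_recomb_rate)
      breaks <- sort(sample.int(L - 1L, min(n_x, L - 1L)))
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, L)
      first <- sample(c("maternal", "paternal"), 1L)
      donors <- rep(c(first, setdiff(c("maternal", "paternal"), first)),
                    length.out = length(starts))
      segments <- data.frame(start = starts, end = ends, donor = donors,
                             stringsAsFactors = FALSE)
      gam_var <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
        src <- if (segments$donor[i] == "maternal")
          maternal$variants[[pick_m]] else paternal$variants[[pick_p]]
        src[src$pos >= segments$start[i] & src$pos <= segments$end[i], ,
            drop = FALSE]
      }))
      gam_var <- gam_var[order(gam_var$pos), , drop = FALSE]
      gam <- apply_variants(maternal$ancestral, gam_var)
      recurrent <- sample(c("a", "b"), 1L)
      child <- new_diploid_genome(
        "offspring_BC1", maternal$ancestral,
        gam$seq, maternal$seq[[recurrent]],
        gam$map, maternal$map[[recurrent]],
        gam_var, maternal$variants[[recurrent]])
      donor_b <- "maternal"
    }
    truth <- list(true_haploid_size =
                    round((nchar(child$seq$a) + nchar(child$seq$b)) / 2),
                  donor_segments = segments,
                  picks = c(maternal = pick_m, paternal = pick_p))
    if (!is.null(genes)) {
      mid <- floor((GenomicRanges::start(genes) + GenomicRanges::end(genes)) / 2)
      seg_idx <- findInterval(mid, segments$start)
      diag_pos <- species_diagnostic_positions(maternal, paternal)
      counts <- vapply(seq_along(genes), function(i) {
        sum(diag_pos >= GenomicRanges::start(genes)[i] &
              diag_pos <= GenomicRanges::end(genes)[i])
      }, integer(1))
      truth$gene_origin <- data.frame(
        gene_id = genes$gene_id,
        donor_hapA = segments$donor[seg_idx],
        donor_hapB = donor_b,
        diagnostic_snps = counts,
        stringsAsFactors = FALSE)
    }
    list(child = child, truth = truth)
  })
}

# Ancestral positions where the two species carry different substitution
# alleles (the diagnostic SNPs of the glossary).
species_diagnostic_positions <- function(maternal, paternal) {
  m <- maternal$species_variants
  p <- paternal$species_variants
  sort(c(m$pos[m$type == "sub"], p$pos[p$type == "sub"]))
}
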