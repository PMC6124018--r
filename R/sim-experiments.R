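# End-to-end synthetic experiments: tie the generator to the analysis
# stages and carry the truth alongside.

#' Run a full synthetic phasing experiment
#'
#' Simulates two diverged parents, an offspring, gene models and parental
#' read sets; emulates the haplotype-fused draft assembly by picking, for
#' every gene, one of the child's two haplotypes as the represented
#' (reference) haplotype; builds parental pileups at candidate variant
#' positions through the read-origin sidecar; and runs the evidence /
#' classification / summary chain. The truth donor of a gene is the donor
#' of its picked haplotype (in an F1 every gene carries both parental
#' haplotypes, so the phase classes describe the haplotype the assembly
#' shows).
#'
#' @param config A [sim_config()].
#' @param min_depth Minimum allele depth at a site (default 2).
#' @param fold Twofold support rule parameter (default 2).
#' @param min_support Minimum winning supports (default 1).
#' @return List with `calls` ([classify_phase()] output), `summary`,
#'   `truth` (data.frame `gene_id, assembly_hap, true_donor,
#'   diagnostic_snps`), `genes`, `sites` (diagnostic site table), `parents`,
#'   `child`.
#' @export
sim_phase_experiment <- function(config, min_depth = 2L, fold = 2,
                                 min_support = 1L) {
  par <- simulate_parents(config)
  genes <- emit_gene_annotation(config)
  off <- simulate_offspring(par$maternal, par$paternal, config, genes = genes)
  rs_m <- simulate_reads(par$maternal, config)
  rs_p <- simulate_reads(par$paternal, config)

  cand <- sort(unique(c(
    sub_positions(par$maternal), sub_positions(par$paternal))))
  pm <- pileup_readset(rs_m, par$maternal, cand)
  pp <- pileup_readset(rs_p, par$paternal, cand)
  ds <- diagnostic_sites(pm, pp, cand, min_depth = min_depth)

  g <- as_gene_frame(genes)
  picks <- withr::with_seed(stage_seed(config$rng_seed, "assembly"),
                            sample(c("a", "b"), nrow(g), replace = TRUE))
  gene_of_site <- site_gene_index(ds$pos, g)
  ref <- rep(NA_character_, nrow(ds))
  in_gene <- which(!is.na(gene_of_site))
  for (h in c("a", "b")) {
    sel <- in_gene[picks[gene_of_site[in_gene]] == h]
    if (length(sel))
      ref[sel] <- allele_at(off$child, h, ds$pos[sel])
  }
  keep <- !is.na(ref)
  ps <- parent_sites_from_pileup(ds[keep, , drop = FALSE], ref[keep])

  cb_m <- coverage_breadth(rs_m, par$maternal, genes)
  cb_p <- coverage_breadth(rs_p, par$paternal, genes)
  cov <- data.frame(gene_id = cb_m$gene_id, cov_m = cb_m$breadth,
                    cov_p = cb_p$breadth[match(cb_m$gene_id, cb_p$gene_id)])
  ev <- collect_evidence(genes, ps$maternal, ps$paternal,
                         min_depth = min_depth, cov = cov)
  calls <- classify_phase(ev, fold = fold, min_support = min_support)

  go <- off$truth$gene_origin
  truth <- data.frame(
    gene_id = g$gene_id,
    assembly_hap = picks,
    true_donor = ifelse(picks == "a", go$donor_hapA, go$donor_hapB),
    diagnostic_snps = go$diagnostic_snps,
    stringsAsFactors = FALSE)

  list(calls = calls, summary = summarize_phase(calls), truth = truth,
       genes = genes, sites = ds, parents = par, child = off$child)
}

sub_positions <- function(genome) {
  c(genome$variants$a$pos[genome$variants$a$type == "sub"],
    genome$variants$b$pos[genome$variants$b$type == "sub"])
}

site_gene_index <- function(pos, gene_frame) {
  idx <- findInterval(pos, gene_frame$start)
  idx[idx == 0L] <- NA_integer_
  inside <- !is.na(idx) & pos <= gene_frame$end[idx]
  idx[!inside] <- NA_integer_
  idx
}

#' Simulate a multi-accession panel of two species and their F1 hybrids
#'
#' Builds the two species founders once, then derives each accession by
#' drawing private heterozygosity on top of its species founder; F1
#' accessions take one random haplotype from a maternal-species and one from
#' a paternal-species accession. Suitable input for the variome stage
#' (distances, MDS, trees) with known group structure.
#'
#' @param config A [sim_config()].
#' @param n_maternal,n_paternal,n_f1 Accession counts per group.
#' @return List with `genomes` (named list of `diploid_genome`), `groups`
#'   (named character vector: maternal/paternal/f1), and `ancestral`.
#' @export
sim_population <- function(config, n_maternal = 2L, n_paternal = 2L,
                           n_f1 = 2L) {
  par <- simulate_parents(config)
  anc <- par$maternal$ancestral
  anc_chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  founders <- list(maternal = par$maternal$species_variants,
                   paternal = par$paternal$species_variants)
  genomes <- list()
  groups <- character()
  mk_acc <- function(group, i) {
    withr::with_seed(stage_seed(config$rng_seed, paste0("panel_", group), i), {
      founder <- founders[[group]]
      het <- draw_variants(anc_chars, config$intraspecies_heterozygosity,
                           config$indel_fraction, exclude = founder$pos)
      on_a <- runif(nrow(het)) < 0.5
      var_a <- rbind(founder, het[on_a, , drop = FALSE])
      var_b <- rbind(founder, het[!on_a, , drop = FALSE])
      var_a <- var_a[order(var_a$pos), , drop = FALSE]
      var_b <- var_b[order(var_b$pos), , drop = FALSE]
      ha <- apply_variants(anc, var_a)
      hb <- apply_variants(anc, var_b)
      new_diploid_genome(sprintf("%s%d", toupper(substr(group, 1, 1)), i),
                         anc, ha$seq, hb$seq, ha$map, hb$map, var_a, var_b,
                         species_variants = founder)
    })
  }
  for (i in seq_len(n_maternal)) {
    g <- mk_acc("maternal", i)
    genomes[[g$label]] <- g
    groups[g$label] <- "maternal"
  }
  for (i in seq_len(n_paternal)) {
    g <- mk_acc("paternal", i)
    genomes[[g$label]] <- g
    groups[g$label] <- "paternal"
  }
  mats <- names(groups)[groups == "maternal"]
  pats <- names(groups)[groups == "paternal"]
  for (i in seq_len(n_f1)) {
    lab <- sprintf("F1_%d", i)
    genomes[[lab]] <- withr::with_seed(
      stage_seed(config$rng_seed, "panel_f1", i), {
        mo <- genomes[[mats[((i - 1L) %% length(mats)) + 1L]]]
        fa <- genomes[[pats[((i - 1L) %% length(pats)) + 1L]]]
        pm <- sample(c("a", "b"), 1L)
        pp <- sample(c("a", "b"), 1L)
        new_diploid_genome(lab, anc,
                           mo$seq[[pm]], fa$seq[[pp]],
                           mo$map[[pm]], fa$map[[pp]],
                           mo$variants[[pm]], fa$variants[[pp]])
      })
    groups[lab] <- "f1"
  }
  list(genomes = genomes, groups = groups, ancestral = anc)
}

#' Build a genotype matrix from simulated diploid genomes
#'
#' Collects every distinct variant across the genomes' haplotypes into a
#' site list (multiple alternate alleles at one position form a multiallelic
#' site) and records each sample's unordered diploid genotype against the
#' ancestral reference.
#'
#' @param genomes Named list of `diploid_genome` objects sharing one
#'   ancestral sequence.
#' @param seqname Sequence name for the sites.
#' @return A [genotype_matrix()] object.
#' @export
sim_genotype_matrix <- function(genomes, seqname = "chr1") {
  stopifnot(length(genomes) >= 1)
  all_var <- unique(do.call(rbind, unlist(lapply(genomes, function(g)
    list(g$variants$a, g$variants$b)), recursive = FALSE)))
  all_var <- all_var[order(all_var$pos, all_var$type, all_var$alt), ,
                     drop = FALSE]
  vkey <- with(all_var, paste(pos, type, ref, alt))
  anc <- genomes[[1]]$ancestral
  # one site per position; allele symbols: ref base / sub alt base /
  # ins:SEQ / del:N
  sym <- with(all_var, ifelse(type == "sub", alt,
                              ifelse(type == "ins", paste0("ins:", alt),
                                     paste0("del:", nchar(ref)))))
  pos_levels <- sort(unique(all_var$pos))
  ref_sym <- substring(anc, pos_levels, pos_levels)
  alt_by_pos <- split(sym, factor(all_var$pos, levels = pos_levels))
  sites <- data.frame(
    seq = seqname,
    pos = pos_levels,
    ref = ref_sym,
    alt = vapply(alt_by_pos, paste, "", collapse = ","),
    type = vapply(split(all_var$type, factor(all_var$pos, levels = pos_levels)),
                  function(tt) if (all(tt == "sub")) "SNP" else "InDel",
                  ""),
    stringsAsFactors = FALSE)
  n_sites <- nrow(sites)
  samples <- names(genomes)
  a1 <- a2 <- matrix(NA_character_, length(samples), n_sites,
                     dimnames = list(samples, NULL))
  site_of_variant <- match(all_var$pos, pos_levels)
  for (s in samples) {
    g <- genomes[[s]]
    for (hap_i in 1:2) {
      h <- c("a", "b")[hap_i]
      v <- g$variants[[h]]
      alleles <- sites$ref
      if (nrow(v)) {
        hkey <- with(v, paste(pos, type, ref, alt))
        hit <- match(hkey, vkey)
        alleles[site_of_variant[hit]] <- sym[hit]
      }
      if (hap_i == 1) a1[s, ] <- alleles else a2[s, ] <- alleles
    }
  }
  genotype_matrix(samples, sites, a1, a2)
}
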