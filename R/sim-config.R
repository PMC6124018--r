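#' Simulation configuration for a two-species hybrid cross
#'
#' Bundles every tunable of the synthetic data generator: a shared ancestral
#' chromosome is mutated into two diverged parental species, each parent is a
#' heterozygous diploid, and an offspring (F1 or first backcross) inherits one
#' haplotype per parent. All downstream stages (k-mer spectrum, phasing,
#' variome, S-locus) can be exercised against the recorded truth.
#'
#' @param genome_length Ancestral chromosome length in bases.
#' @param n_genes Number of non-overlapping gene models to annotate.
#' @param gene_length_mean Mean gene length in bases.
#' @param interspecies_divergence Expected substitutions/base separating the
#'   two parental species. Differing sites are drawn at this rate and each is
#'   assigned to one species relative to the shared ancestor, so the two
#'   species differ pairwise by this rate.
#' @param intraspecies_heterozygosity Expected variants/base between the two
#'   haplotypes of one parent.
#' @param indel_fraction Fraction of variant sites realized as short InDels
#'   (lengths uniform on 1--10) instead of substitutions.
#' @param read_length Read length in bases (single-end).
#' @param coverage Fold coverage per haplotype copy: emitted bases equal
#'   `coverage * (length(hap_a) + length(hap_b))`.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param offspring_type `"F1"` (one intact haplotype per parent) or `"BC1"`
#'   (one recombined F1 gamete plus one recurrent-parent haplotype).
#' @param bc_recomb_rate Expected crossovers per chromosome in the BC1 gamete
#'   (Poisson).
#' @param rng_seed Integer seed; identical configurations yield byte-identical
#'   outputs.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(genome_length = 50000, n_genes = 20, rng_seed = 7)
#' cfg$interspecies_divergence
#' @export
sim_config <- function(genome_length = 1e6,
                       n_genes = 500,
                       gene_length_mean = 1000,
                       interspecies_divergence = 0.01,
                       intraspecies_heterozygosity = 0.002,
                       indel_fraction = 0.1,
                       read_length = 100,
                       coverage = 30,
                       error_rate = 0.005,
                       offspring_type = c("F1", "BC1"),
                       bc_recomb_rate = 1,
                       rng_seed = 1L) {
  offspring_type <- match.arg(offspring_type)
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    gene_length_mean = as.integer(gene_length_mean),
    interspecies_divergence = interspecies_divergence,
    intraspecies_heterozygosity = intraspecies_heterozygosity,
    indel_fraction = indel_fraction,
    read_length = as.integer(read_length),
    coverage = coverage,
    error_rate = error_rate,
    offspring_type = offspring_type,
    bc_recomb_rate = bc_recomb_rate,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length >= 1L, cfg$n_genes >= 0L, cfg$read_length >= 1L)
  if (cfg$n_genes > 0 && cfg$genome_length < cfg$n_genes * cfg$gene_length_mean)
    stop("genome_length must be >= n_genes * gene_length_mean")
  rates <- c(interspecies_divergence = cfg$interspecies_divergence,
             intraspecies_heterozygosity = cfg$intraspecies_heterozygosity,
             indel_fraction = cfg$indel_fraction,
             error_rate = cfg$error_rate)
  bad <- rates < 0 | rates >= 1
  if (any(bad))
    stop("rates must lie in [0, 1): ", paste(names(rates)[bad], collapse = ", "))
  if (cfg$coverage <= 0) stop("coverage must be > 0")
  if (cfg$bc_recomb_rate < 0) stop("bc_recomb_rate must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
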