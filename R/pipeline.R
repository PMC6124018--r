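# Pipeline orchestration: validated configuration, stage execution in
# dependency order, resolved-config copy and a run manifest with file
# checksums next to the outputs.

pipeline_defaults <- function() {
  list(
    global = list(rng_seed = 1L, log_level = "info"),
    # demonstration scale: small enough to run in seconds, large enough for
    # every stage to produce non-trivial output
    simulate = list(genome_length = 60000L, n_genes = 30L,
                    gene_length_mean = 800L,
                    interspecies_divergence = 0.01,
                    intraspecies_heterozygosity = 0.002,
                    indel_fraction = 0.1, read_length = 100L,
                    coverage = 20, error_rate = 0.002,
                    offspring_type = "F1", bc_recomb_rate = 1),
    kmer = list(k = 17L, max_mult = 10000L),
    phase = list(min_depth = 2L, fold = 2, min_support = 1L),
    variome = list(n_maternal = 2L, n_paternal = 2L, n_f1 = 2L,
                   normalize = FALSE, snps_only = FALSE),
    slocus = list(accessions = 8L, pool_size = 6L,
                  identity_threshold = 0.99)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' A configuration is a nested list (or YAML file) with blocks `global`,
#' `simulate`, `kmer`, `phase`, `variome`, `slocus`; unknown blocks or keys
#' are rejected before any stage runs, and missing keys take the
#' documented defaults.
#'
#' @param config A nested list, a YAML file path, or `NULL` for pure
#'   defaults.
#' @return The resolved configuration list.
#' @export
resolve_pipeline_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  if (is.null(config)) return(defaults)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  bad_blocks <- setdiff(names(config), names(defaults))
  if (length(bad_blocks))
    stop("unknown configuration block(s): ", paste(bad_blocks, collapse = ", "))
  for (blk in names(config)) {
    bad_keys <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(bad_keys))
      stop("unknown key(s) in '", blk, "': ", paste(bad_keys, collapse = ", "))
    defaults[[blk]] <- modifyList(defaults[[blk]], config[[blk]])
  }
  defaults
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes the stages in dependency order (simulate feeds everything
#' else), writing each stage's outputs, a resolved copy of the
#' configuration, and a manifest of produced files with MD5 checksums and
#' wall times. Deterministic stages reproduce identical checksums when
#' re-run with the same configuration. A stage failure stops the run with
#' the manifest of completed stages attached to the error.
#'
#' @param config Configuration (list, YAML path or `NULL`); see
#'   [resolve_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "kmer", "phase", "variome",
#'   "slocus")` to run; `simulate` is implied by the others.
#' @return The run manifest: data.frame `stage, file, md5, seconds`.
#' @export
run_pipeline <- function(config = NULL, out_dir,
                         stages = c("simulate", "kmer", "phase", "variome",
                                    "slocus")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- resolve_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  sim_cfg <- do.call(sim_config, c(cfg$simulate,
                                   list(rng_seed = cfg$global$rng_seed)))
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), seconds = numeric(),
                         stringsAsFactors = FALSE)
  note <- function(stage, files, secs) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), seconds = secs,
      stringsAsFactors = FALSE))
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      err <- simpleError(sprintf("stage '%s' failed: %s", stage,
                                 conditionMessage(e)))
      err$manifest <- manifest
      stop(err)
    })
    note(stage, files, proc.time()[["elapsed"]] - t0)
  }
  path <- function(...) file.path(out_dir, ...)

  run_stage("simulate", function() {
    par <- simulate_parents(sim_cfg)
    genes <- emit_gene_annotation(sim_cfg)
    off <- simulate_offspring(par$maternal, par$paternal, sim_cfg,
                              genes = genes)
    reads <- simulate_reads(off$child, sim_cfg)
    write_genome_fasta(par$maternal, path("maternal.fasta"))
    write_genome_fasta(par$paternal, path("paternal.fasta"))
    write_genome_fasta(off$child, path("offspring.fasta"))
    write_gff3(genes, path("genes.gff3"))
    write_fastq(reads, path("offspring_reads.fastq"),
                path("offspring_read_origin.tsv"))
    write_tsv(off$truth$gene_origin, path("truth_genes.tsv"),
              comment = "simulator truth: per-gene haplotype donors")
    path(c("maternal.fasta", "paternal.fasta", "offspring.fasta",
           "genes.gff3", "offspring_reads.fastq",
           "offspring_read_origin.tsv", "truth_genes.tsv"))
  })

  if ("kmer" %in% stages) run_stage("kmer", function() {
    par <- simulate_parents(sim_cfg)
    off <- simulate_offspring(par$maternal, par$paternal, sim_cfg)
    reads <- simulate_reads(off$child, sim_cfg)
    sp <- count_kmers(reads, k = cfg$kmer$k, max_mult = cfg$kmer$max_mult)
    write_kmer_histogram(sp, path("kmer_histogram.tsv"))
    report <- tryCatch({
      pk <- fit_peaks(sp)
      sz <- estimate_genome_size(sp, pk)
      data.frame(k = sp$k, error_trough = pk$error_trough,
                 het_peak_depth = pk$het_peak_depth,
                 hom_peak_depth = pk$hom_peak_depth,
                 het_volume_fraction = pk$het_volume_fraction,
                 haploid_size = sz$haploid_size,
                 diploid_size = sz$diploid_size)
    }, error = function(e) data.frame(k = sp$k, error = conditionMessage(e)))
    write_tsv(report, path("kmer_report.tsv"),
              comment = "k-mer peak fit and genome-size estimates")
    path(c("kmer_histogram.tsv", "kmer_report.tsv"))
  })

  if ("phase" %in% stages) run_stage("phase", function() {
    exp <- sim_phase_experiment(sim_cfg, min_depth = cfg$phase$min_depth,
                                fold = cfg$phase$fold,
                                min_support = cfg$phase$min_support)
    write_tsv(as.data.frame(exp$calls), path("phase_calls.tsv"),
              comment = sprintf("fold=%s min_depth=%d min_support=%d",
                                cfg$phase$fold, cfg$phase$min_depth,
                                cfg$phase$min_support))
    write_tsv(as.data.frame(exp$summary), path("phase_summary.tsv"),
              comment = "phase class counts and percentages")
    write_bed(paint_chromosomes(exp$calls), path("phase_track.bed"))
    path(c("phase_calls.tsv", "phase_summary.tsv", "phase_track.bed"))
  })

  if ("variome" %in% stages) run_stage("variome", function() {
    pop <- sim_population(sim_cfg, n_maternal = cfg$variome$n_maternal,
                          n_paternal = cfg$variome$n_paternal,
                          n_f1 = cfg$variome$n_f1)
    gm <- sim_genotype_matrix(pop$genomes)
    write_vcf_genotypes(gm, path("variome.vcf"))
    write_tsv(as.data.frame(summarize_variome(gm)),
              path("variome_summary.tsv"),
              comment = "per-sample het/hom SNP, InDel and Ti/Tv summary")
    d <- allele_distance(gm, normalize = cfg$variome$normalize,
                         snps_only = cfg$variome$snps_only)
    write_distance_tsv(d, path("distances.tsv"))
    coords <- classical_mds(d, dims = 2)
    write_tsv(data.frame(sample = rownames(coords),
                         dim1 = coords[, 1], dim2 = coords[, 2]),
              path("mds_coordinates.tsv"), comment = "classical MDS, 2 axes")
    write_newick(nj_tree(d), path("nj_tree.nwk"))
    path(c("variome.vcf", "variome_summary.tsv", "distances.tsv",
           "mds_coordinates.tsv", "nj_tree.nwk"))
  })

  if ("slocus" %in% stages) run_stage("slocus", function() {
    sim <- simulate_s_locus(cfg$slocus$accessions, cfg$slocus$pool_size,
                            rng_seed = cfg$global$rng_seed)
    write_s_alleles(sim$alleles, path("s_alleles.fasta"))
    sh <- cluster_s_alleles(sim$alleles,
                            identity_threshold = cfg$slocus$identity_threshold)
    write_tsv(sh$assignment, path("s_assignment.tsv"),
              comment = sprintf("identity_threshold=%s",
                                cfg$slocus$identity_threshold))
    net <- build_s_network(sh)
    write_s_network(net, path("s_network_edges.tsv"),
                    path("s_network.graphml"))
    path(c("s_alleles.fasta", "s_assignment.tsv", "s_network_edges.tsv",
           "s_network.graphml"))
  })

  write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"),
            comment = sprintf("hybridseer %s",
                              as.character(utils::packageVersion("hybridseer"))))
  manifest
}
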