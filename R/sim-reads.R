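#' Simulate uniform-coverage single-end reads from a diploid genome
#'
#' Reads are drawn uniformly from both haplotypes (so emitted bases equal
#' `coverage` times the summed haplotype lengths), with i.i.d. per-base
#' substitution errors at `error_rate`. A sidecar table records, for every
#' read, its true haplotype of origin and 1-based start coordinate on that
#' haplotype; it stands in for an aligner on the synthetic path.
#'
#' @param genome A `diploid_genome`.
#' @param config A [sim_config()] supplying `read_length`, `coverage`,
#'   `error_rate`.
#' @return An object of class `read_set`: list with `reads` (character
#'   vector), `sidecar` (data.frame `read_id, haplotype, start`),
#'   `read_length`, `genome_label`, `total_bases`.
#' @examples
#' p <- simulate_parents(sim_config(genome_length = 5000, n_genes = 2,
#'                                  coverage = 5, rng_seed = 3))
#' rs <- simulate_reads(p$maternal, sim_config(genome_length = 5000,
#'                                             n_genes = 2, coverage = 5,
#'                                             rng_seed = 3))
#' length(rs$reads)
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(is(genome, "diploid_genome"))
  validate_sim_config(config)
  rl <- config$read_length
  if (rl > min(nchar(genome$seq$a), nchar(genome$seq$b)))
    stop("read_length exceeds haplotype length")
  seed <- stage_seed(config$rng_seed, "reads",
                     extra = sum(utf8ToInt(genome$label)))
  withr::with_seed(seed, {
    per_hap <- lapply(c(a = "a", b = "b"), function(h) {
      hl <- nchar(genome$seq[[h]])
      n_reads <- round(config$coverage * hl / rl)
      starts <- sample.int(hl - rl + 1L, n_reads, replace = TRUE)
      reads <- substring(genome$seq[[h]], starts, starts + rl - 1L)
      list(reads = reads, starts = starts)
    })
    reads <- c(per_hap$a$reads, per_hap$b$reads)
    hap <- rep(c("a", "b"), c(length(per_hap$a$reads), length(per_hap$b$reads)))
    starts <- c(per_hap$a$starts, per_hap$b$starts)
    if (config$error_rate > 0 && length(reads) > 0) {
      n_err <- rbinom(1L, length(reads) * rl, config$error_rate)
      if (n_err > 0) {
        ri <- sample.int(length(reads), n_err, replace = TRUE)
        pp <- sample.int(rl, n_err, replace = TRUE)
        cur <- substr(reads[ri], pp, pp)
        reads <- mutate_bases_cpp(reads, ri, pp, other_base(cur))
      }
    }
    structure(list(
      reads = reads,
      sidecar = data.frame(
        read_id = sprintf("%s_%s_%06d", genome$label, hap,
                          seq_along(reads)),
        haplotype = hap,
        start = starts,
        stringsAsFactors = FALSE),
      read_length = rl,
      genome_label = genome$label,
      total_bases = length(reads) * rl), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set from '%s': %d reads x %d bp (%.2f Mb)\n",
              x$genome_label, length(x$reads), x$read_length,
              x$total_bases / 1e6))
  invisible(x)
}

#' Annotate non-overlapping gene models on the ancestral chromosome
#'
#' Places `n_genes` non-overlapping intervals with approximately normal
#' lengths (mean `gene_length_mean`, sd 15% of the mean, floored at 50 bp)
#' separated by randomly sized gaps; deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param seqname Chromosome name used in the annotation.
#' @return A [GenomicRanges::GRanges] with metadata column `gene_id`,
#'   1-based inclusive coordinates, sorted and non-overlapping.
#' @export
emit_gene_annotation <- function(config, seqname = "chr1") {
  validate_sim_config(config)
  n <- config$n_genes
  L <- config$genome_length
  if (n == 0)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(seqname, L)))
  withr::with_seed(stage_seed(config$rng_seed, "genes"), {
    len <- pmax(50L, as.integer(round(
      rnorm(n, config$gene_length_mean, 0.15 * config$gene_length_mean))))
    if (sum(len) > L)
      stop("cannot place ", n, " non-overlapping genes in ", L, " bases")
    slack <- L - sum(len)
    cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
    starts <- cuts + cumsum(c(0L, len[-n])) + 1L
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = starts, width = len),
      gene_id = sprintf("gene%05d", seq_len(n)),
      seqinfo = GenomeInfoDb::Seqinfo(seqname, L))
    gr
  })
}
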