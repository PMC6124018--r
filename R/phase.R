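# Parent-of-origin phase classification of genes from parental read support.
#
# A gene is phased to one parent if it is covered only by that parent's reads
# (unique mapping) or if it has at least `fold` times as many diagnostic-SNP
# supports from that parent (phased by SNP); genes with balanced support are
# common; genes with no coverage from either parent carry no data.
#
# Evidence is assembled from per-parent allele support at candidate sites:
# a site is *diagnostic* when the depth-filtered allele sets of the two
# parents are non-empty and disjoint, and it votes for the parent whose
# supported allele matches the reference (assembly) allele at that site.

.phase_levels <- c("UNIQUE_MATERNAL", "PHASED_MATERNAL",
                   "UNIQUE_PATERNAL", "PHASED_PATERNAL",
                   "COMMON", "NO_DATA")

#' Pile up read alleles from a simulated read set at ancestral positions
#'
#' Uses the read-origin sidecar (true haplotype and start coordinate) plus
#' the haplotype-to-ancestral coordinate maps to count, per target position,
#' how many reads of the set carry each base. This replaces an aligner on
#' the synthetic path.
#'
#' @param read_set A `read_set` from [simulate_reads()].
#' @param genome The `diploid_genome` the reads were simulated from.
#' @param positions Ancestral positions (1-based) to pile up.
#' @return Integer matrix `length(positions)` x 4 (columns A, C, G, T).
#' @export
pileup_readset <- function(read_set, genome, positions) {
  stopifnot(is(read_set, "read_set"), is(genome, "diploid_genome"))
  positions <- as.integer(positions)
  counts <- matrix(0L, length(positions), 4,
                   dimnames = list(NULL, .dna_bases))
  for (h in c("a", "b")) {
    sel <- read_set$sidecar$haplotype == h
    if (!any(sel)) next
    map <- genome$map[[h]]
    inv <- integer(genome$ancestral_length)
    keep <- !is.na(map)
    inv[map[keep]] <- which(keep)
    hap_pos <- ifelse(positions >= 1 & positions <= genome$ancestral_length,
                      inv[pmax(positions, 1L)], 0L)
    present <- which(hap_pos > 0L)
    if (!length(present)) next
    ord_r <- order(read_set$sidecar$start[sel])
    reads <- read_set$reads[sel][ord_r]
    starts <- read_set$sidecar$start[sel][ord_r]
    ord_s <- order(hap_pos[present])
    m <- pileup_alleles_cpp(reads, starts, hap_pos[present][ord_s])
    back <- present[ord_s]
    counts[back, ] <- counts[back, , drop = FALSE] + m[, 1:4, drop = FALSE]
  }
  counts
}

#' Identify species-diagnostic sites from two parental pileups
#'
#' A candidate site is diagnostic when, after depth filtering, the maternal
#' and paternal supported-allele sets are both non-empty and disjoint: the
#' parents demonstrably carry different alleles there, so read support at
#' the site can assign parental origin. Sites where a parent is heterozygous
#' (supports both alleles) are shared and never diagnostic.
#'
#' @param pileup_m,pileup_p Count matrices (positions x A,C,G,T) from
#'   [pileup_readset()] or equivalent, over the same `positions`.
#' @param positions Ancestral positions of the rows.
#' @param min_depth Minimum reads supporting an allele for it to count
#'   (default 2, the minimum depth rule).
#' @param seqname Sequence name for the output.
#' @return data.frame `seq, pos, allele_m, allele_p, depth_m, depth_p`
#'   with one row per diagnostic site (alleles are each parent's
#'   best-supported allele).
#' @export
diagnostic_sites <- function(pileup_m, pileup_p, positions, min_depth = 2L,
                             seqname = "chr1") {
  stopifnot(nrow(pileup_m) == length(positions),
            nrow(pileup_p) == length(positions))
  pass_m <- pileup_m >= min_depth
  pass_p <- pileup_p >= min_depth
  disjoint <- rowSums(pass_m & pass_p) == 0
  ok <- rowSums(pass_m) > 0 & rowSums(pass_p) > 0 & disjoint
  idx <- which(ok)
  best <- function(mat, rows) .dna_bases[max.col(mat[rows, , drop = FALSE],
                                                 ties.method = "first")]
  am <- best(pileup_m, idx)
  ap <- best(pileup_p, idx)
  data.frame(seq = rep(seqname, length(idx)),
             pos = positions[idx],
             allele_m = am,
             allele_p = ap,
             depth_m = pileup_m[cbind(idx, match(am, .dna_bases))],
             depth_p = pileup_p[cbind(idx, match(ap, .dna_bases))],
             stringsAsFactors = FALSE)
}

#' Collect per-gene phasing evidence
#'
#' Joins per-parent allele support tables over gene intervals. At each site
#' the depth-filtered supported-allele sets of the two parents are formed;
#' sites failing `min_depth` in both parents are excluded from
#' `sites_considered`; a site with non-empty, disjoint sets votes for the
#' parent whose supported allele matches the reference (assembly) allele.
#'
#' @param genes [GenomicRanges::GRanges] with `gene_id` (1-based inclusive)
#'   or a data.frame with `gene_id, seq, start, end`.
#' @param maternal_sites,paternal_sites data.frames
#'   `seq, pos, ref, allele, depth`: allele observations of each parent's
#'   reads with the reference (assembly) allele at the site. Build them with
#'   [parent_sites_from_pileup()] on the synthetic path or
#'   [read_parent_sites_vcf()] for real data.
#' @param min_depth Minimum depth for an allele observation to count
#'   (default 2).
#' @param cov Optional data.frame `gene_id, cov_m, cov_p` of aligned-read
#'   breadth fractions (from [coverage_breadth()]). When absent, breadth
#'   falls back to 1 if the gene has any depth-passing site for that parent
#'   and 0 otherwise (documented coarse fallback for site-only input).
#' @return data.frame of class `gene_evidence`:
#'   `gene_id, seq, start, end, cov_m, cov_p, support_m, support_p,
#'   sites_considered`.
#' @export
collect_evidence <- function(genes, maternal_sites, paternal_sites,
                             min_depth = 2L, cov = NULL) {
  g <- as_gene_frame(genes)
  for (df in list(maternal_sites, paternal_sites))
    stopifnot(all(c("seq", "pos", "ref", "allele", "depth") %in% names(df)))
  key <- function(df) paste(df$seq, df$pos)
  m <- maternal_sites[maternal_sites$depth >= min_depth, , drop = FALSE]
  p <- paternal_sites[paternal_sites$depth >= min_depth, , drop = FALSE]
  all_keys <- union(key(m), key(p))
  site <- data.frame(key = all_keys, stringsAsFactors = FALSE)
  parts <- strsplit(all_keys, " ", fixed = TRUE)
  site$seq <- vapply(parts, `[`, "", 1)
  site$pos <- as.integer(vapply(parts, `[`, "", 2))
  refs <- rbind(maternal_sites[c("seq", "pos", "ref")],
                paternal_sites[c("seq", "pos", "ref")])
  site$ref <- refs$ref[match(site$key, key(refs))]
  # per-site supported allele sets
  set_m <- split(m$allele, key(m))
  set_p <- split(p$allele, key(p))
  sm <- set_m[site$key]
  sp <- set_p[site$key]
  n_m <- lengths(sm)
  n_p <- lengths(sp)
  lmap <- function(f, a, b) {
    if (nrow(site) == 0) return(logical(0))
    mapply(f, a, b, USE.NAMES = FALSE)
  }
  disjoint <- lmap(function(a, b) length(intersect(a, b)) == 0, sm, sp)
  diag <- n_m > 0 & n_p > 0 & disjoint
  vote_m <- diag & lmap(function(a, r) r %in% a, sm, site$ref)
  vote_p <- diag & lmap(function(a, r) r %in% a, sp, site$ref)

  overlaps <- function(i) {
    which(site$seq == g$seq[i] & site$pos >= g$start[i] & site$pos <= g$end[i])
  }
  ev <- g
  ev$cov_m <- 0
  ev$cov_p <- 0
  ev$support_m <- 0L
  ev$support_p <- 0L
  ev$sites_considered <- 0L
  for (i in seq_len(nrow(g))) {
    idx <- overlaps(i)
    ev$sites_considered[i] <- length(idx)
    ev$support_m[i] <- sum(vote_m[idx])
    ev$support_p[i] <- sum(vote_p[idx])
    ev$cov_m[i] <- as.numeric(any(n_m[idx] > 0))
    ev$cov_p[i] <- as.numeric(any(n_p[idx] > 0))
  }
  if (!is.null(cov)) {
    j <- match(ev$gene_id, cov$gene_id)
    ev$cov_m <- ifelse(is.na(j), ev$cov_m, cov$cov_m[j])
    ev$cov_p <- ifelse(is.na(j), ev$cov_p, cov$cov_p[j])
  }
  stopifnot(all(ev$cov_m >= 0 & ev$cov_m <= 1),
            all(ev$cov_p >= 0 & ev$cov_p <= 1),
            all(ev$support_m + ev$support_p <= ev$sites_considered))
  class(ev) <- c("gene_evidence", "data.frame")
  ev
}

as_gene_frame <- function(genes) {
  if (is(genes, "GRanges")) {
    data.frame(gene_id = genes$gene_id,
               seq = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "seq", "start", "end") %in% names(genes)))
    as.data.frame(genes)[c("gene_id", "seq", "start", "end")]
  }
}

#' Build per-parent site support tables from diagnostic-site pileups
#'
#' Converts the output of [diagnostic_sites()] plus the reference (assembly)
#' alleles into the two `seq, pos, ref, allele, depth` tables consumed by
#' [collect_evidence()].
#'
#' @param sites Output of [diagnostic_sites()].
#' @param ref Character vector of reference alleles at `sites$pos` (the
#'   allele the haplotype-fused assembly shows).
#' @return List with `maternal` and `paternal` data.frames.
#' @export
parent_sites_from_pileup <- function(sites, ref) {
  stopifnot(length(ref) == nrow(sites))
  list(
    maternal = data.frame(seq = sites$seq, pos = sites$pos, ref = ref,
                          allele = sites$allele_m, depth = sites$depth_m,
                          stringsAsFactors = FALSE),
    paternal = data.frame(seq = sites$seq, pos = sites$pos, ref = ref,
                          allele = sites$allele_p, depth = sites$depth_p,
                          stringsAsFactors = FALSE))
}

#' Per-gene aligned-read breadth of coverage
#'
#' Fraction of each gene interval covered by at least one read of the set,
#' computed on ancestral coordinates through the sidecar.
#'
#' @inheritParams pileup_readset
#' @param genes Gene intervals ([GenomicRanges::GRanges] with `gene_id` or
#'   equivalent data.frame).
#' @return data.frame `gene_id, breadth`.
#' @export
coverage_breadth <- function(read_set, genome, genes) {
  g <- as_gene_frame(genes)
  L <- genome$ancestral_length
  delta <- integer(L + 1L)
  for (h in c("a", "b")) {
    sel <- read_set$sidecar$haplotype == h
    if (!any(sel)) next
    map <- genome$map[[h]]
    filled <- map
    na <- is.na(filled)
    filled[na] <- 0L
    filled <- cummax(filled)   # maps are nondecreasing; carry last coordinate
    filled[filled == 0L] <- 1L
    s <- read_set$sidecar$start[sel]
    e <- pmin(s + read_set$read_length - 1L, length(map))
    lo <- filled[s]
    hi <- filled[e]
    delta_add <- tabulate(lo, nbins = L)
    delta_sub <- tabulate(pmin(hi + 1L, L + 1L), nbins = L + 1L)
    delta[seq_len(L)] <- delta[seq_len(L)] + delta_add
    delta <- delta - delta_sub
  }
  covered <- cumsum(delta[seq_len(L)]) > 0
  g$breadth <- vapply(seq_len(nrow(g)), function(i) {
    mean(covered[g$start[i]:min(g$end[i], L)])
  }, numeric(1))
  g[c("gene_id", "breadth")]
}

#' Classify genes into parental phase classes
#'
#' Decision ladder, applied per gene: (1) no coverage from either parent:
#' `NO_DATA`; (2) coverage breadth at least `min_breadth` from one parent
#' and zero from the other: `UNIQUE_*` (aligned only by one parent's reads);
#' (3) at least `fold` times as many diagnostic-SNP supports from one parent
#' (and at least `min_support` of them): `PHASED_*`; (4) otherwise `COMMON`.
#' A tie in rule 3 (possible only at zero supports with `min_support = 0`)
#' is `COMMON`.
#'
#' @param evidence A `gene_evidence` data.frame from [collect_evidence()]
#'   (any data.frame with the same columns works).
#' @param fold Support ratio required to phase (default 2: the twofold
#'   rule).
#' @param min_support Minimum winning-side supports to phase (default 1;
#'   prevents phasing on zero evidence).
#' @param min_breadth Minimum breadth for a `UNIQUE_*` call (default 0.5).
#' @return data.frame of class `phase_calls`: evidence columns plus `call`
#'   (factor with levels UNIQUE_MATERNAL, PHASED_MATERNAL, UNIQUE_PATERNAL,
#'   PHASED_PATERNAL, COMMON, NO_DATA).
#' @examples
#' ev <- data.frame(gene_id = "g1", seq = "chr1", start = 1, end = 100,
#'                  cov_m = 0.9, cov_p = 0.8, support_m = 4, support_p = 2,
#'                  sites_considered = 6)
#' classify_phase(ev)$call  # 4 >= 2 * 2: phased maternal at the boundary
#' @export
classify_phase <- function(evidence, fold = 2, min_support = 1L,
                           min_breadth = 0.5) {
  ev <- as.data.frame(evidence)
  n <- nrow(ev)
  call <- character(n)
  m_ok <- ev$support_m >= fold * ev$support_p & ev$support_m >= min_support
  p_ok <- ev$support_p >= fold * ev$support_m & ev$support_p >= min_support
  for (i in seq_len(n)) {
    call[i] <- if (ev$cov_m[i] == 0 && ev$cov_p[i] == 0) {
      "NO_DATA"
    } else if (ev$cov_p[i] == 0 && ev$cov_m[i] >= min_breadth) {
      "UNIQUE_MATERNAL"
    } else if (ev$cov_m[i] == 0 && ev$cov_p[i] >= min_breadth) {
      "UNIQUE_PATERNAL"
    } else if (m_ok[i] && !p_ok[i]) {
      "PHASED_MATERNAL"
    } else if (p_ok[i] && !m_ok[i]) {
      "PHASED_PATERNAL"
    } else {
      "COMMON"
    }
  }
  ev$call <- factor(call, levels = .phase_levels)
  class(ev) <- c("phase_calls", "data.frame")
  ev
}

#' Summarize phase calls as counts and percentages
#'
#' Per-class counts in the order unique maternal, phased maternal, unique
#' paternal, phased paternal, common; percentages are taken over genes with
#' data (`NO_DATA` is reported separately and excluded from the
#' denominator).
#'
#' @param calls A `phase_calls` data.frame from [classify_phase()].
#' @return data.frame of class `phase_summary`: `call, count, ratio_pct`
#'   (`ratio_pct` is `NA` for `NO_DATA`), with attribute `total`.
#' @export
summarize_phase <- function(calls) {
  if (nrow(calls) == 0) stop("no calls to summarize")
  counts <- table(factor(calls$call, levels = .phase_levels))
  with_data <- sum(counts[setdiff(.phase_levels, "NO_DATA")])
  out <- data.frame(call = .phase_levels,
                    count = as.integer(counts),
                    ratio_pct = ifelse(.phase_levels == "NO_DATA", NA_real_,
                                       100 * as.integer(counts) / with_data),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(calls)
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("phase_summary (", attr(x, "total"), " genes):\n", sep = "")
  print.data.frame(cbind(x["call"], count = x$count,
                         ratio_pct = round(x$ratio_pct, 1)), row.names = FALSE)
  invisible(x)
}

#' Paint phase calls along chromosomes as a BED track
#'
#' One record per gene, 0-based half-open coordinates, class in the last
#' column, stably sorted by sequence then start.
#'
#' @param calls A `phase_calls` data.frame.
#' @param genes Optional gene intervals to take coordinates from when
#'   `calls` lacks them.
#' @return data.frame `chrom, start, end, name, score, strand, call`
#'   (BED6 + class column).
#' @export
paint_chromosomes <- function(calls, genes = NULL) {
  src <- if (!is.null(genes)) {
    g <- as_gene_frame(genes)
    merge(as.data.frame(calls)[c("gene_id", "call")], g, by = "gene_id")
  } else as.data.frame(calls)
  if (nrow(src) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character(),
                      call = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = src$seq,
                    start = src$start - 1L,   # BED is 0-based half-open
                    end = src$end,
                    name = src$gene_id,
                    score = 0L,
                    strand = ".",
                    call = as.character(src$call),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
}
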