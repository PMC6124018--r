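# Variome analysis: per-sample variant summaries, allele-sharing distances,
# classical MDS, neighbor-joining trees.

#' Construct a samples-by-sites diploid genotype matrix
#'
#' The container behind all variome operations: an ordered sample list, a
#' site table (`seq, pos, ref, alt, type`, with `alt` a comma-separated
#' allele list and `type` either `"SNP"` or `"InDel"`), and two allele
#' matrices giving each sample's unordered genotype (`NA` = missing call).
#'
#' @param samples Character vector of sample names.
#' @param sites data.frame with columns `seq, pos, ref, alt, type`.
#' @param a1,a2 Character matrices (samples x sites) of allele symbols; each
#'   non-missing symbol must be the site's `ref` or one of its `alt`
#'   alleles.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, a1, a2) {
  stopifnot(all(c("seq", "pos", "ref", "alt", "type") %in% names(sites)),
            nrow(a1) == length(samples), nrow(a2) == length(samples),
            ncol(a1) == nrow(sites), ncol(a2) == nrow(sites))
  allowed <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                    sites$ref, sites$alt, SIMPLIFY = FALSE)
  for (j in seq_len(nrow(sites))) {
    vals <- c(a1[, j], a2[, j])
    bad <- !is.na(vals) & !(vals %in% allowed[[j]])
    if (any(bad))
      stop("allele symbol not in ref/alt set at site ", sites$pos[j])
  }
  structure(list(samples = samples, sites = sites, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d SNP, %d InDel)\n",
              length(x$samples), nrow(x$sites),
              sum(x$sites$type == "SNP"), sum(x$sites$type == "InDel")))
  invisible(x)
}

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Per-sample variome summary
#'
#' For every sample: heterozygous SNPs (two distinct alleles), homozygous
#' non-reference SNPs, InDel calls (any non-reference allele at an InDel
#' site), their total, and transitions/transversions counted per
#' non-reference allele copy at biallelic SNPs (a homozygous alternate
#' contributes two copies). Sites with more than one alternate allele are
#' counted in the het/hom totals but excluded from Ti/Tv; their number is
#' attached as attribute `n_multiallelic_excluded`.
#'
#' @param gm A [genotype_matrix()].
#' @return data.frame of class `variome_summary`: `sample, het_snps,
#'   hom_snps, indels, snps_plus_indels, ti, tv, titv_ratio` (`titv_ratio`
#'   is `NA` when `tv` is 0).
#' @export
summarize_variome <- function(gm) {
  stopifnot(is(gm, "genotype_matrix"), length(gm$samples) >= 1)
  st <- gm$sites
  snp <- st$type == "SNP"
  indel <- st$type == "InDel"
  biallelic <- snp & !grepl(",", st$alt, fixed = TRUE)
  rows <- lapply(seq_along(gm$samples), function(i) {
    g1 <- gm$a1[i, ]
    g2 <- gm$a2[i, ]
    called <- !is.na(g1) & !is.na(g2)
    het <- called & g1 != g2
    hom_alt <- called & g1 == g2 & g1 != st$ref
    copies <- (!is.na(g1) & g1 != st$ref) + (!is.na(g2) & g2 != st$ref)
    ti_site <- biallelic & is_transition(st$ref, st$alt)
    tv_site <- biallelic & !is_transition(st$ref, st$alt)
    ti <- sum(copies[ti_site])
    tv <- sum(copies[tv_site])
    data.frame(sample = gm$samples[i],
               het_snps = sum(het & snp),
               hom_snps = sum(hom_alt & snp),
               indels = sum((het | hom_alt) & indel),
               snps_plus_indels = sum((het | hom_alt) & (snp | indel)),
               ti = ti, tv = tv,
               titv_ratio = if (tv == 0) NA_real_ else ti / tv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_multiallelic_excluded") <- sum(snp & !biallelic)
  class(out) <- c("variome_summary", "data.frame")
  out
}

#' Allele-sharing distance matrix between genotypes
#'
#' The distance between two samples is the total number of allele
#' differences across jointly called sites: per site the contribution is
#' `2 - |multiset intersection of the two genotypes|` (0 for identical
#' genotypes, 1 for one shared allele, 2 for none). Sites missing in either
#' sample are skipped pairwise; `normalize` divides each pair by its number
#' of jointly called sites.
#'
#' @param gm A [genotype_matrix()] with at least two samples.
#' @param normalize Divide by the pairwise jointly-called site count.
#' @param snps_only Restrict to SNP sites (InDels included by default).
#' @return Object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal), `denom` (jointly called site counts), and
#'   `samples`.
#' @export
allele_distance <- function(gm, normalize = FALSE, snps_only = FALSE) {
  stopifnot(is(gm, "genotype_matrix"))
  n <- length(gm$samples)
  if (n < 2) stop("need at least 2 samples")
  keep <- if (snps_only) gm$sites$type == "SNP" else rep(TRUE, nrow(gm$sites))
  a1 <- gm$a1[, keep, drop = FALSE]
  a2 <- gm$a2[, keep, drop = FALSE]
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  denom <- matrix(0L, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      called <- !is.na(a1[i, ]) & !is.na(a2[i, ]) &
        !is.na(a1[j, ]) & !is.na(a2[j, ])
      if (!any(called)) stop("no jointly called sites for pair ",
                             gm$samples[i], " / ", gm$samples[j])
      shared <- pmax((a1[i, called] == a1[j, called]) +
                       (a2[i, called] == a2[j, called]),
                     (a1[i, called] == a2[j, called]) +
                       (a2[i, called] == a1[j, called]))
      d[i, j] <- d[j, i] <- sum(2 - shared)
      denom[i, j] <- denom[j, i] <- sum(called)
    }
  }
  if (normalize) {
    off <- row(d) != col(d)
    d[off] <- d[off] / denom[off]
  }
  stopifnot(isSymmetric(d), all(diag(d) == 0), all(d >= 0))
  structure(list(d = d, denom = denom, samples = gm$samples,
                 normalized = normalize),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix over %d samples%s:\n", length(x$samples),
              if (x$normalized) " (normalized)" else ""))
  print(round(x$d, 4))
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (is(d, "distance_matrix")) d$d
  else if (inherits(d, "dist")) as.matrix(d)
  else as.matrix(d)
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances and embeds the samples on the top
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues beyond the requested dimensions (non-Euclidean residue) are
#' reported with a warning. For reproducibility across runs and BLAS
#' backends, each axis is oriented so its first nonzero loading is
#' positive.
#'
#' @param d A `distance_matrix`, `dist`, or symmetric matrix.
#' @param dims Number of dimensions (default 2; at most samples - 1).
#' @return Numeric matrix samples x dims of coordinates (class
#'   `mds_coordinates`), with the eigenvalues as attribute `eig`.
#' @export
classical_mds <- function(d, dims = 2L) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  k_eff <- min(dims, n - 1L)  # extra axes beyond n-1 are identically zero
  if (all(D == 0)) {
    coords <- matrix(0, n, dims, dimnames = list(rownames(D), NULL))
    attr(coords, "eig") <- rep(0, n)
    class(coords) <- c("mds_coordinates", class(coords))
    return(coords)
  }
  fit <- cmdscale(D, k = k_eff, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("distance matrix is not Euclidean-embeddable; negative ",
            "eigenvalues ignored beyond the requested dimensions")
  coords <- fit$points
  if (ncol(coords) < dims)  # degenerate geometry: pad trailing zero axes
    coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(D)
  attr(coords, "eig") <- fit$eig
  class(coords) <- c("mds_coordinates", class(coords))
  coords
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, with deterministic lexicographic tie-breaking on cluster
#' labels. Negative branch lengths are clamped to zero with the excess
#' moved to the sister branch, so every output branch length is
#' non-negative while path lengths between leaves are preserved. Exactly
#' recovers additive trees.
#'
#' @param d A `distance_matrix`, `dist`, or symmetric matrix with at least
#'   3 samples.
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 samples")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nwk <- labels          # growing newick fragment per active cluster
  key <- labels          # lexicographic tie-break key per cluster
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.12g", x)
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * Dm[i, j] - r[i] - r[j]
        pair_key <- sort(c(key[active[i]], key[active[j]]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best <- list(q = q, i = i, j = j, key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    ci <- active[i]; cj <- active[j]
    new_d <- (Dm[i, -c(i, j)] + Dm[j, -c(i, j)] - dij) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    others <- active[-c(i, j)]
    D[u, others] <- D[others, u] <- new_d
    nwk[u] <- sprintf("(%s:%s,%s:%s)", nwk[ci], fmt(bi), nwk[cj], fmt(bj))
    key[u] <- min(key[ci], key[cj])
    active <- c(others, u)
  }
  a <- active
  Dm <- D[a, a]
  b1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  b2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  b3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[a[1]], fmt(b[1]), nwk[a[2]], fmt(b[2]),
                 nwk[a[3]], fmt(b[3]))
  ape::read.tree(text = txt)
}
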