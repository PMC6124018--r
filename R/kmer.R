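# K-mer spectrum analysis: canonical k-mer histogram, het/hom peak fitting,
# genome-size estimation. A heterozygous diploid shows two coverage peaks:
# k-mers private to one haplotype pile up at roughly half the depth of
# k-mers shared by both, so the spectrum separates the heterozygous from the
# homozygous sequence fraction.

#' Count canonical k-mers from reads
#'
#' Counts every k-long window of every read after collapsing each k-mer with
#' its reverse complement onto the lexicographically smaller of the pair.
#' Windows containing a non-ACGT base are skipped; reads shorter than `k`
#' are skipped and tallied. Multiplicities above `max_mult` are pooled into
#' an overflow bin (repeats contribute volume there, not peaks).
#'
#' @param reads A `read_set`, character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTQ file (optionally
#'   gzipped).
#' @param k Odd k-mer length, 11--31 (default 17).
#' @param max_mult Overflow bin (default 10000).
#' @return An object of class `kmer_spectrum`: list with `k`, `histogram`
#'   (data.frame `multiplicity, count`), `total_kmer_instances`,
#'   `total_read_bases`, `n_too_short`.
#' @examples
#' sp <- count_kmers(c("ACGT"), k = 3)
#' sp$histogram  # canonical ACG seen twice (CGT reverse-complements to ACG)
#' @export
count_kmers <- function(reads, k = 17L, max_mult = 10000L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (palindromic k-mers otherwise pair with themselves)")
  if (k > 31L) stop("k must be <= 31")
  reads <- as_read_characters(reads)
  res <- count_kmers_cpp(reads, k, as.integer(max_mult))
  new_kmer_spectrum(k,
                    data.frame(multiplicity = res$multiplicity,
                               count = res$count),
                    total_instances = res$total_instances,
                    total_bases = res$total_bases,
                    n_too_short = res$n_too_short)
}

as_read_characters <- function(reads) {
  if (is(reads, "read_set")) return(reads$reads)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    return(as.character(Biostrings::readDNAStringSet(reads, format = "fastq")))
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads)) return(reads)
  stop("unsupported read input")
}

new_kmer_spectrum <- function(k, histogram, total_instances, total_bases,
                              n_too_short = 0) {
  histogram <- histogram[order(histogram$multiplicity), , drop = FALSE]
  rownames(histogram) <- NULL
  stopifnot(all(histogram$count >= 0))
  structure(list(k = k, histogram = histogram,
                 total_kmer_instances = total_instances,
                 total_read_bases = total_bases,
                 n_too_short = n_too_short),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum (k = %d): %d occupied multiplicities, %.3g k-mer instances, %.3g read bases\n",
              x$k, nrow(x$histogram), x$total_kmer_instances,
              x$total_read_bases))
  invisible(x)
}

#' Write / read a k-mer histogram as two-column TSV
#'
#' The format (`multiplicity<TAB>count`, no header) is compatible with the
#' histogram output of standalone k-mer counters, so precomputed histograms
#' can be analyzed. Metadata (`k`, total read bases) travels in `#` comment
#' lines and is recovered by the reader when present.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path Output/input file path.
#' @return `write_kmer_histogram` returns `path` invisibly;
#'   `read_kmer_histogram` returns a `kmer_spectrum` (with
#'   `total_read_bases = NA` if the comment header is absent).
#' @export
write_kmer_histogram <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k=%d", spectrum$k),
               sprintf("# total_read_bases=%.0f", spectrum$total_read_bases)),
             con)
  write.table(spectrum$histogram, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_histogram
#' @param k K-mer length to assume when the file carries no `# k=` header.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  km <- sub("^# k=", "", grep("^# k=", meta, value = TRUE))
  if (length(km)) k <- as.integer(km[1])
  tb <- sub("^# total_read_bases=", "",
            grep("^# total_read_bases=", meta, value = TRUE))
  total_bases <- if (length(tb)) as.numeric(tb[1]) else NA_real_
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "[\t ]+")
  hist <- data.frame(multiplicity = as.integer(vapply(parts, `[`, "", 1)),
                     count = as.numeric(vapply(parts, `[`, "", 2)))
  new_kmer_spectrum(k, hist,
                    total_instances = sum(hist$multiplicity * hist$count),
                    total_bases = total_bases)
}

#' Fit heterozygous and homozygous coverage peaks in a k-mer spectrum
#'
#' The histogram is smoothed with a centered moving average, the error trough
#' is located as the first local minimum (multiplicity 0 when the spectrum
#' rises from the start, i.e. no error component), and local maxima beyond
#' the trough become peak candidates. The homozygous peak is the candidate
#' with the greater multiplicity among the top two by height; the
#' heterozygous peak is the remaining candidate closest to half the
#' homozygous depth, accepted only inside the window
#' `het_window * hom depth` and above `min_het_height` of the homozygous
#' peak height (a floor that keeps sampling noise from minting a spurious
#' half-depth peak).
#'
#' @param spectrum A `kmer_spectrum`.
#' @param smooth_window Moving-average window in bins (odd; default 3).
#' @param het_window Acceptance window for the het/hom depth ratio
#'   (default `c(0.35, 0.65)`; the theoretical ratio is 0.5).
#' @param min_het_height Minimum het candidate height as a fraction of the
#'   homozygous peak height (default 0.1).
#' @param peak_floor Candidates below this fraction of the tallest
#'   candidate are dropped before peak selection (default 0.05): genomic
#'   repeats put a small bump at integer multiples of the main depth that
#'   must not masquerade as the homozygous peak.
#' @return An object of class `peak_model`: `error_trough`,
#'   `het_peak_depth` (`NA` when absent), `hom_peak_depth`,
#'   `het_peak_height`, `hom_peak_height`, `error_volume`, `het_volume`,
#'   `hom_volume`, `het_volume_fraction`.
#' @export
fit_peaks <- function(spectrum, smooth_window = 3L,
                      het_window = c(0.35, 0.65), min_het_height = 0.1,
                      peak_floor = 0.05) {
  h <- spectrum$histogram
  if (nrow(h) == 0)
    stop("insufficient coverage: empty k-mer histogram")
  max_m <- max(h$multiplicity)
  dense <- numeric(max_m)
  dense[h$multiplicity] <- h$count
  s <- smooth_ma(dense, smooth_window)

  trough <- 0L
  if (max_m >= 2 && s[1] > s[2]) {
    for (m in 2:(max_m - 1L)) {
      if (s[m] <= s[m - 1L] && s[m] <= s[m + 1L]) { trough <- m; break }
    }
  }
  beyond <- which(seq_len(max_m) > trough)
  cand <- beyond[vapply(beyond, function(m) {
    left <- if (m > 1) s[m - 1L] else -Inf
    right <- if (m < max_m) s[m + 1L] else -Inf
    s[m] > 0 && s[m] >= left && s[m] > right
  }, logical(1))]
  if (length(cand) == 0)
    stop("insufficient coverage: no k-mer peak beyond the error trough")
  cand <- cand[s[cand] >= peak_floor * max(s[cand])]

  top2 <- cand[order(s[cand], decreasing = TRUE)][seq_len(min(2L, length(cand)))]
  hom <- max(top2)
  het <- NA_integer_
  window <- het_window * hom
  others <- setdiff(cand, hom)
  ok <- others[others >= window[1] & others <= window[2] &
                 s[others] >= min_het_height * s[hom]]
  if (length(ok)) het <- ok[which.min(abs(ok - hom / 2))]

  inst <- h$multiplicity * h$count
  error_volume <- sum(inst[h$multiplicity < trough])
  if (!is.na(het)) {
    # split het and hom mass at the smoothed valley between the two peaks
    valley_range <- (het + 1L):(hom - 1L)
    split <- if (length(valley_range))
      valley_range[which.min(s[valley_range])] else het
    het_volume <- sum(inst[h$multiplicity >= trough & h$multiplicity <= split])
    hom_volume <- sum(inst[h$multiplicity > split])
  } else {
    het_volume <- 0
    hom_volume <- sum(inst[h$multiplicity >= trough])
  }
  structure(list(error_trough = trough,
                 het_peak_depth = het,
                 hom_peak_depth = hom,
                 het_peak_height = if (is.na(het)) NA_real_ else dense[het],
                 hom_peak_height = dense[hom],
                 error_volume = error_volume,
                 het_volume = het_volume,
                 hom_volume = hom_volume,
                 het_volume_fraction = het_volume / (het_volume + hom_volume)),
            class = "peak_model")
}

smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("peak_model: trough %d | het peak %s | hom peak %d | het volume fraction %.3f\n",
              x$error_trough,
              if (is.na(x$het_peak_depth)) "absent" else x$het_peak_depth,
              x$hom_peak_depth, x$het_volume_fraction))
  invisible(x)
}

#' Estimate haploid and diploid genome size from a fitted k-mer spectrum
#'
#' Haploid size: signal k-mer volume (total instances minus the error mass
#' below the trough) divided by the homozygous peak depth; or, under
#' `basis = "read_length"`, total read bases divided by the homozygous peak
#' depth converted from k-mer to base coverage by
#' `read_length / (read_length - k + 1)`. Diploid size: the same volume
#' divided by the heterozygous peak depth (every diploid position is covered
#' at the per-haplotype depth, so the het-peak depth is the per-copy
#' coverage); it equals the haploid size when no het peak exists.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param peaks A `peak_model` from [fit_peaks()].
#' @param basis `"kmers"` (default; uses k-mer volume) or `"read_length"`
#'   (uses total read bases, no error subtraction).
#' @param read_length Read length, required for `basis = "read_length"`.
#' @return List with `haploid_size` and `diploid_size` (bases).
#' @export
estimate_genome_size <- function(spectrum, peaks,
                                 basis = c("kmers", "read_length"),
                                 read_length = NULL) {
  basis <- match.arg(basis)
  if (is.null(peaks$hom_peak_depth) || is.na(peaks$hom_peak_depth))
    stop("homozygous peak absent; cannot estimate genome size")
  c_hom <- peaks$hom_peak_depth
  c_het <- peaks$het_peak_depth
  if (basis == "kmers") {
    signal <- spectrum$total_kmer_instances - peaks$error_volume
    haploid <- signal / c_hom
    diploid <- if (!is.na(c_het)) signal / c_het else haploid
  } else {
    if (is.null(read_length)) stop("read_length required for basis='read_length'")
    conv <- read_length / (read_length - spectrum$k + 1)
    haploid <- spectrum$total_read_bases / (c_hom * conv)
    diploid <- if (!is.na(c_het))
      spectrum$total_read_bases / (c_het * conv) else haploid
  }
  list(haploid_size = haploid, diploid_size = diploid)
}
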