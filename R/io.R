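# Shared readers/writers. Coordinate contract: GFF3 and the internal gene
# tables are 1-based inclusive; BED output is 0-based half-open; conversion
# happens exactly once, at the emit/parse boundary.

#' Write a TSV with `#` comment header lines
#' @param df data.frame to write.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with
#'   a leading `# `).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (skips `#` comments)
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a diploid genome's haplotypes to FASTA
#' @param genome A `diploid_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(c(genome$seq$a, genome$seq$b))
  names(seqs) <- paste0(genome$label, c("_hapA", "_hapB"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a read set to FASTQ (Phred+33) and its origin sidecar to TSV
#'
#' Every record's quality line has the same length as its sequence line
#' (constant Q40). The sidecar (`read_id, haplotype, start`) records the
#' true origin of every read.
#'
#' @param read_set A `read_set`.
#' @param fastq_path FASTQ output path.
#' @param sidecar_path Optional TSV path for the read-origin sidecar.
#' @return `fastq_path`, invisibly.
#' @export
write_fastq <- function(read_set, fastq_path, sidecar_path = NULL) {
  n <- length(read_set$reads)
  lines <- character(4L * n)
  lines[seq(1, by = 4, length.out = n)] <- paste0("@", read_set$sidecar$read_id)
  lines[seq(2, by = 4, length.out = n)] <- read_set$reads
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <-
    vapply(nchar(read_set$reads), function(w) strrep("I", w), "")
  writeLines(lines, fastq_path)
  if (!is.null(sidecar_path))
    write_tsv(read_set$sidecar, sidecar_path,
              comment = paste("read-origin sidecar for", read_set$genome_label))
  invisible(fastq_path)
}

#' Read a FASTQ file
#' @param path FASTQ path (optionally gzipped).
#' @return A [Biostrings::DNAStringSet] of read sequences.
#' @export
read_fastq <- function(path) Biostrings::readDNAStringSet(path, format = "fastq")

#' Write gene models to GFF3 (1-based inclusive)
#' @param genes [GenomicRanges::GRanges] with `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- genes
  if (length(gr)) {
    gr$type <- "gene"
    gr$source <- "hybridseer"
    gr$ID <- gr$gene_id
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 coordinates are 1-based inclusive and imported as such; BED input
#' is 0-based half-open and converted at this boundary.
#'
#' @param path GFF3 (`.gff/.gff3`) or BED path.
#' @return [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  ids <- if (!is.null(gr$gene_id)) gr$gene_id
  else if (!is.null(gr$ID)) gr$ID
  else if (!is.null(gr$name)) gr$name
  else sprintf("gene%05d", seq_along(gr))
  mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
  gr
}

#' Write a phase-painted (or any) BED-like track
#'
#' Emits 0-based half-open records; [paint_chromosomes()] output goes in
#' directly.
#'
#' @param bed data.frame whose first three columns are `chrom, start, end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like track written by [write_bed()]
#' @param path Input path.
#' @param col_names Column names to assign (default matches
#'   [paint_chromosomes()] output).
#' @return data.frame.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end", "name",
                                         "score", "strand", "call")) {
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(), integer(), integer(), character(), integer(),
                 character(), character(), stringsAsFactors = FALSE),
      col_names))
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- col_names[seq_len(ncol(df))]
  df
}

#' Write the 6-column pileup TSV of per-parent allele support
#'
#' Long format: one row per (site, allele) with the reference (assembly)
#' allele and the supporting depths of the maternal and paternal read sets
#' (`seq, pos, ref, allele, depth_m, depth_p`).
#'
#' @param maternal_sites,paternal_sites data.frames
#'   `seq, pos, ref, allele, depth` (see [collect_evidence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(maternal_sites, paternal_sites, path) {
  m <- maternal_sites
  p <- paternal_sites
  m$depth_m <- m$depth; m$depth <- NULL
  p$depth_p <- p$depth; p$depth <- NULL
  all <- merge(m, p, by = c("seq", "pos", "ref", "allele"), all = TRUE)
  all$depth_m[is.na(all$depth_m)] <- 0L
  all$depth_p[is.na(all$depth_p)] <- 0L
  all <- all[order(all$seq, all$pos, all$allele), , drop = FALSE]
  write_tsv(all, path, comment = "per-parent allele support at candidate sites")
}

#' Read the 6-column pileup TSV back into per-parent site tables
#' @param path Input path.
#' @return List with `maternal` and `paternal` data.frames
#'   (`seq, pos, ref, allele, depth`).
#' @export
read_pileup_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("seq", "pos", "ref", "allele", "depth_m", "depth_p")
  if (!all(need %in% names(df)))
    stop("pileup TSV must have columns ", paste(need, collapse = ", "))
  list(maternal = data.frame(df[c("seq", "pos", "ref", "allele")],
                             depth = df$depth_m),
       paternal = data.frame(df[c("seq", "pos", "ref", "allele")],
                             depth = df$depth_p))
}

#' Write a genotype matrix as a minimal multi-sample VCF 4.2
#'
#' SNP alleles are written as standard REF/ALT bases; simulator InDel
#' symbols (`ins:SEQ`, `del:N`) are written as the symbolic alternates
#' `<INS:SEQ>` / `<DEL:N>` and recovered by [read_vcf_genotypes()].
#' Genotypes are unphased `GT` fields; missing calls are `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path) {
  st <- gm$sites
  alt_lists <- strsplit(st$alt, ",", fixed = TRUE)
  enc <- function(a) {
    ifelse(grepl("^ins:", a), paste0("<INS:", sub("^ins:", "", a), ">"),
           ifelse(grepl("^del:", a), paste0("<DEL:", sub("^del:", "", a), ">"),
                  a))
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=hybridseer",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(st)), function(j) {
    alleles <- c(st$ref[j], alt_lists[[j]])
    gt <- vapply(seq_along(gm$samples), function(i) {
      x1 <- gm$a1[i, j]; x2 <- gm$a2[i, j]
      if (is.na(x1) || is.na(x2)) return("./.")
      idx <- sort(c(match(x1, alleles), match(x2, alleles))) - 1L
      paste(idx, collapse = "/")
    }, "")
    paste(c(st$seq[j], st$pos[j], ".", st$ref[j],
            paste(enc(alt_lists[[j]]), collapse = ","),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Consumes CHROM/POS/REF/ALT and the GT subfield (unphased or phased,
#' `./.` missing); everything else is ignored. Sites are typed `"SNP"` when
#' every allele is a single A/C/G/T base and `"InDel"` otherwise; symbolic
#' `<INS:SEQ>`/`<DEL:N>` alternates map back to the simulator's `ins:`/
#' `del:` allele symbols.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dec <- function(a) {
    a <- sub("^<INS:(.*)>$", "ins:\\1", a)
    sub("^<DEL:(.*)>$", "del:\\1", a)
  }
  alt_lists <- lapply(strsplit(fix[, "ALT"], ",", fixed = TRUE), dec)
  ref <- fix[, "REF"]
  is_base <- function(x) nchar(x) == 1 & x %in% .dna_bases
  type <- vapply(seq_along(ref), function(j) {
    if (is_base(ref[j]) && all(is_base(alt_lists[[j]]))) "SNP" else "InDel"
  }, "")
  sites <- data.frame(seq = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = ref,
                      alt = vapply(alt_lists, paste, "", collapse = ","),
                      type = type, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(sites))
  samples <- colnames(gt)
  n <- length(samples)
  a1 <- a2 <- matrix(NA_character_, n, nrow(sites),
                     dimnames = list(samples, NULL))
  for (j in seq_len(nrow(sites))) {
    alleles <- c(sites$ref[j], alt_lists[[j]])
    parts <- strsplit(gt[j, ], "[/|]")
    for (i in seq_len(n)) {
      p <- suppressWarnings(as.integer(parts[[i]]))
      if (length(p) == 2 && !anyNA(p)) {
        a1[i, j] <- alleles[p[1] + 1L]
        a2[i, j] <- alleles[p[2] + 1L]
      }
    }
  }
  genotype_matrix(samples, sites, a1, a2)
}

#' Read a single-parent site-support table from a VCF
#'
#' For the real-data entry of the phase classifier: a per-parent VCF whose
#' sample carries `AD` (allelic depths) or at least `DP`. Each REF/ALT
#' allele with positive depth becomes one `seq, pos, ref, allele, depth`
#' row; with only `DP` present the called GT alleles share the site depth.
#'
#' @param path VCF path.
#' @param sample Sample column to use (default: first).
#' @return data.frame `seq, pos, ref, allele, depth`.
#' @export
read_parent_sites_vcf <- function(path, sample = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP"), error = function(e) NULL)
  gt <- vcfR::extract.gt(v, element = "GT")
  as_mat <- function(x) if (is.null(x) || !is.null(dim(x))) x else
    matrix(x, nrow = nrow(fix))
  ad <- as_mat(ad); dp <- as_mat(dp); gt <- as_mat(gt)
  rows <- list()
  for (j in seq_len(nrow(fix))) {
    alleles <- c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",")[[1]])
    if (!is.null(ad) && !is.na(ad[j, sample])) {
      depths <- suppressWarnings(as.integer(strsplit(ad[j, sample], ",")[[1]]))
      for (k in seq_along(depths)) {
        if (!is.na(depths[k]) && depths[k] > 0 && k <= length(alleles))
          rows[[length(rows) + 1L]] <- data.frame(
            seq = fix[j, "CHROM"], pos = as.integer(fix[j, "POS"]),
            ref = fix[j, "REF"], allele = alleles[k], depth = depths[k],
            stringsAsFactors = FALSE)
      }
    } else if (!is.null(dp) && !is.na(dp[j, sample]) && !is.na(gt[j, sample])) {
      idx <- unique(suppressWarnings(
        as.integer(strsplit(gt[j, sample], "[/|]")[[1]]))) + 1L
      idx <- idx[!is.na(idx) & idx >= 1 & idx <= length(alleles)]
      for (k in idx)
        rows[[length(rows) + 1L]] <- data.frame(
          seq = fix[j, "CHROM"], pos = as.integer(fix[j, "POS"]),
          ref = fix[j, "REF"], allele = alleles[k],
          depth = as.integer(dp[j, sample]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seq = character(), pos = integer(), ref = character(),
                      allele = character(), depth = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a square distance matrix as TSV with header row and column
#' @param d A `distance_matrix` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as_dist_matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write_tsv(df, path, comment = "pairwise allele-difference distances")
}

#' Read a square distance matrix TSV written by [write_distance_tsv()]
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a tree in Newick format
#' @param tree An [ape] `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
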