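# S-locus haplotype analysis. In Prunus-type gametophytic
# self-incompatibility (GSI) the pistil determinant (S-RNase) and the pollen
# determinant (SFB) are completely linked; the pair defines an S haplotype
# class. Pollen carrying a class present in the seed parent is rejected, so
# every out-crossed individual is S-heterozygous and a trio offspring
# carries one maternal class plus one paternal class absent from the
# mother.

#' Read S-locus allele sequences from FASTA
#'
#' Header grammar: `accession|gene|copy`, with `gene` one of `S-RNase` or
#' `SFB` and `copy` 1 or 2 marking the two linked locus copies of the
#' accession (copy pairing encodes the S-RNase/SFB linkage).
#'
#' @param path FASTA file path.
#' @return data.frame `accession, gene, copy, sequence`.
#' @export
read_s_alleles <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("S-allele FASTA headers must follow 'accession|gene|copy'")
  df <- data.frame(accession = vapply(parts, `[`, "", 1),
                   gene = vapply(parts, `[`, "", 2),
                   copy = as.integer(vapply(parts, `[`, "", 3)),
                   sequence = as.character(x),
                   stringsAsFactors = FALSE)
  validate_s_alleles(df)
  df
}

#' Write S-locus alleles to FASTA with the `accession|gene|copy` grammar
#' @param alleles data.frame `accession, gene, copy, sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_s_alleles <- function(alleles, path) {
  seqs <- Biostrings::DNAStringSet(alleles$sequence)
  names(seqs) <- sprintf("%s|%s|%d", alleles$accession, alleles$gene,
                         alleles$copy)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

validate_s_alleles <- function(alleles) {
  stopifnot(all(c("accession", "gene", "copy", "sequence") %in%
                  names(alleles)),
            all(nchar(alleles$sequence) > 0),
            all(alleles$gene %in% c("S-RNase", "SFB")))
  cnt <- table(alleles$accession, alleles$gene)
  if (any(cnt != 2))
    stop("each accession needs exactly two locus copies per gene")
  invisible(alleles)
}

#' Pairwise sequence identity with free end gaps
#'
#' Global alignment scored match +1, mismatch -1, gap -2, with terminal
#' gaps free (alleles of a class differ modestly in length, so end
#' overhangs are not penalized). Identity is matching columns over
#' alignment columns excluding terminal gaps, but never over fewer columns
#' than the shorter sequence: when unrelated sequences align only over a
#' short chance overlap, the uncovered remainder counts against them
#' instead of being silently clipped.
#'
#' @param s1,s2 Nucleotide sequences (character).
#' @return Identity in `[0, 1]`.
#' @export
align_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) /
    max(Biostrings::nchar(aln), min(nchar(s1), nchar(s2)))
}

#' Cluster S alleles into haplotype classes
#'
#' Haplotype units are the linked (S-RNase, SFB) copy pairs of each
#' accession. Two units belong to one class when both genes align at or
#' above `identity_threshold`; classes are the single-linkage (connected
#' component) closure of that relation. Class labels `S1..Sn` are assigned
#' by descending class size, then first-seen order. An accession whose two
#' copies land in the same class is flagged a putative homozygote (a GSI
#' violation) but kept; a unit whose S-RNase links to one class and SFB to
#' another triggers a "putative recombinant S-locus" warning.
#'
#' @param alleles data.frame `accession, gene, copy, sequence` (see
#'   [read_s_alleles()]).
#' @param identity_threshold Minimum within-class identity (default 0.99).
#' @return Object of class `s_haplotypes`: list with `assignment`
#'   (data.frame `accession, class1, class2, flags`), `units` (per-unit
#'   class table), `classes` (class -> member units), and the threshold.
#' @export
cluster_s_alleles <- function(alleles, identity_threshold = 0.99) {
  validate_s_alleles(alleles)
  units <- unique(alleles[c("accession", "copy")])
  units <- units[order(units$accession, units$copy), , drop = FALSE]
  rownames(units) <- NULL
  nu <- nrow(units)
  seq_of <- function(acc, copy, gene) {
    alleles$sequence[alleles$accession == acc & alleles$copy == copy &
                       alleles$gene == gene]
  }
  rnase <- mapply(seq_of, units$accession, units$copy,
                  MoreArgs = list(gene = "S-RNase"))
  sfb <- mapply(seq_of, units$accession, units$copy,
                MoreArgs = list(gene = "SFB"))
  id_r <- diag(1, nu)
  id_f <- diag(1, nu)
  for (i in seq_len(nu - 1)) {
    for (j in (i + 1):nu) {
      id_r[i, j] <- id_r[j, i] <- align_identity(rnase[i], rnase[j])
      id_f[i, j] <- id_f[j, i] <- align_identity(sfb[i], sfb[j])
    }
  }
  link_both <- id_r >= identity_threshold & id_f >= identity_threshold
  link_one <- xor(id_r >= identity_threshold, id_f >= identity_threshold)
  if (any(link_one[upper.tri(link_one)]))
    warning("putative recombinant S-locus: S-RNase and SFB of some allele ",
            "pairs link to different classes")
  g <- igraph::graph_from_adjacency_matrix(link_both, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # label by descending size, then first appearance
  first_seen <- tapply(seq_len(nu), comp, min)
  sizes <- tabulate(comp)
  ord <- order(-sizes, first_seen)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  units$class <- sprintf("S%d", relabel[comp])
  assignment <- do.call(rbind, lapply(split(units, units$accession),
                                      function(u) {
    u <- u[order(u$copy), ]
    cls <- sort(u$class)
    data.frame(accession = u$accession[1],
               class1 = cls[1], class2 = cls[2],
               flags = if (cls[1] == cls[2]) "putative_homozygote" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(assignment) <- NULL
  classes <- split(sprintf("%s/%d", units$accession, units$copy),
                   units$class)
  structure(list(assignment = assignment, units = units, classes = classes,
                 identity_threshold = identity_threshold),
            class = "s_haplotypes")
}

#' @export
print.s_haplotypes <- function(x, ...) {
  cat(sprintf("s_haplotypes: %d accessions, %d classes (identity >= %.3f)\n",
              nrow(x$assignment), length(x$classes), x$identity_threshold))
  print.data.frame(x$assignment, row.names = FALSE)
  invisible(x)
}

assignment_pair <- function(assignment, accession) {
  row <- assignment[assignment$accession == accession, , drop = FALSE]
  if (nrow(row) != 1) stop("accession not assigned: ", accession)
  c(row$class1, row$class2)
}

#' Check a parent-offspring trio for S-haplotype consistency under GSI
#'
#' Consistent when the child's pair can be split into one class from the
#' mother and one from the father such that the paternally donated class is
#' absent from the mother (GSI pollen rejection); both donor assignments
#' are enumerated.
#'
#' @param child,mother,father Accession names.
#' @param assignment The `assignment` data.frame of an `s_haplotypes`
#'   object (or the object itself).
#' @return List with `consistent` (logical) and `donors` (named character
#'   vector `maternal, paternal`, or `NULL` when inconsistent).
#' @examples
#' a <- data.frame(accession = c("mo", "fa", "ch"),
#'                 class1 = c("S1", "S2", "S2"),
#'                 class2 = c("S2", "S3", "S3"))
#' check_trio("ch", "mo", "fa", a)  # S2 maternal, S3 paternal
#' @export
check_trio <- function(child, mother, father, assignment) {
  if (is(assignment, "s_haplotypes")) assignment <- assignment$assignment
  ch <- assignment_pair(assignment, child)
  mo <- assignment_pair(assignment, mother)
  fa <- assignment_pair(assignment, father)
  for (ix in 1:2) {
    mat_cand <- ch[ix]
    pat_cand <- ch[3 - ix]
    if (mat_cand %in% mo && pat_cand %in% fa && !(pat_cand %in% mo))
      return(list(consistent = TRUE,
                  donors = c(maternal = mat_cand, paternal = pat_cand)))
  }
  list(consistent = FALSE, donors = NULL)
}

#' Predict GSI cross compatibility between two S genotypes
#'
#' Counts pollen classes absent from the seed parent: 0 escape =
#' incompatible, 1 = semi-compatible (half the pollen passes), 2 = fully
#' compatible. Semi-compatibility is reported as its own level: crosses
#' between related individuals are typically reduced, not blocked.
#'
#' @param seed_parent,pollen_parent Character vectors of two class labels
#'   each.
#' @return `"incompatible"`, `"semi_compatible"` or `"fully_compatible"`.
#' @examples
#' predict_cross(c("S1", "S2"), c("S2", "S3"))
#' @export
predict_cross <- function(seed_parent, pollen_parent) {
  stopifnot(length(seed_parent) == 2, length(pollen_parent) == 2)
  escaped <- sum(!(pollen_parent %in% seed_parent))
  c("incompatible", "semi_compatible", "fully_compatible")[escaped + 1]
}

#' Build the shared-S-haplotype network between accessions
#'
#' Nodes are accessions (with optional taxon/location attributes); an edge
#' labeled with the shared class connects two accessions whenever their
#' class sets intersect, one edge per shared class per pair, in
#' deterministic (sorted) order.
#'
#' @param assignment An `s_haplotypes` object or its `assignment`
#'   data.frame.
#' @param metadata Optional data.frame with column `accession` plus node
#'   attributes (e.g. `taxon`, `location`).
#' @return List with `edges` (data.frame `from, to, class`) and `graph`
#'   (an [igraph::graph_from_data_frame()] object).
#' @export
build_s_network <- function(assignment, metadata = NULL) {
  if (is(assignment, "s_haplotypes")) assignment <- assignment$assignment
  accs <- sort(assignment$accession)
  pairs <- list()
  for (i in seq_along(accs)) {
    for (j in seq_along(accs)) {
      if (j <= i) next
      shared <- intersect(assignment_pair(assignment, accs[i]),
                          assignment_pair(assignment, accs[j]))
      for (cl in sort(shared))
        pairs[[length(pairs) + 1L]] <- data.frame(
          from = accs[i], to = accs[j], class = cl,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(from = character(), to = character(), class = character(),
               stringsAsFactors = FALSE)
  vertices <- data.frame(name = accs, stringsAsFactors = FALSE)
  if (!is.null(metadata))
    vertices <- merge(vertices, metadata, by.x = "name",
                      by.y = "accession", all.x = TRUE, sort = TRUE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  list(edges = edges, graph = g)
}

#' Write a shared-haplotype network to edge-list TSV and GraphML
#' @param network Output of [build_s_network()].
#' @param edge_path TSV path for the edge list.
#' @param graphml_path Optional GraphML path.
#' @return `edge_path`, invisibly.
#' @export
write_s_network <- function(network, edge_path, graphml_path = NULL) {
  write_tsv(network$edges, edge_path,
            comment = "shared S-haplotype edges")
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  invisible(edge_path)
}
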