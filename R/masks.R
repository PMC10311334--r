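#' Construct an attention mask
#'
#' A sparse set of ordered gene-index pairs (i, j) permitted to exchange
#' attention.  Undirected dependencies are encoded as the two ordered
#' pairs (i, j) and (j, i); self pairs are never stored (the attention
#' layer always includes the self pair implicitly).  Pairs are kept as a
#' coordinate list, never densified: at transcriptome scale a dense
#' gene-by-gene matrix does not fit in memory.
#'
#' @param pairs two-column integer matrix of 1-based gene indices.
#' @param n_genes number of genes the indices refer to.
#' @param provenance one of `"coexp"`, `"ppi"`, `"both"`, `"random"`.
#' @param source_seed integer seed used to derive the mask, or `NULL`.
#' @return An `attention_mask` object; pairs are deduplicated and sorted.
#' @export
attention_mask <- function(pairs, n_genes,
                           provenance = c("coexp", "ppi", "both", "random"),
                           source_seed = NULL) {
  provenance <- match.arg(provenance)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0) {
    if (min(pairs) < 1L || max(pairs) > n_genes)
      stop("pair indices out of range [1, n_genes]")
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
  }
  structure(list(pairs = pairs, n_genes = as.integer(n_genes),
                 provenance = provenance, source_seed = source_seed),
            class = "attention_mask")
}

#' @export
print.attention_mask <- function(x, ...) {
  cat("<attention_mask> ", nrow(x$pairs), " ordered pairs over ",
      x$n_genes, " genes (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Number of ordered pairs in a mask
#' @param mask an `attention_mask`.
#' @return Integer pair count.
#' @export
mask_size <- function(mask) nrow(mask$pairs)

#' Per-gene degree vector of a mask
#' @param mask an `attention_mask`.
#' @return Integer vector of length `n_genes`: number of ordered pairs in
#'   which each gene appears as the attending gene i.
#' @export
mask_degrees <- function(mask) {
  tabulate(mask$pairs[, 1], nbins = mask$n_genes)
}

symmetrize_pairs <- function(pairs) {
  unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
}

#' Build a co-expression attention mask
#'
#' Keeps gene pairs whose absolute Pearson correlation on the training
#' split reaches `threshold`; the symmetric closure is applied.  Constant
#' genes have undefined correlations, which are treated as 0 (the gene is
#' excluded) with a warning.  An optional `max_pairs` cap keeps only the
#' strongest pairs to bound memory.
#'
#' @param train `expression_dataset` with at least 3 samples.
#' @param threshold absolute-correlation cutoff in (0, 1].
#' @param max_pairs optional cap on the number of unordered pairs kept
#'   (strongest first).
#' @return An `attention_mask` with provenance `"coexp"`.
#' @export
coexpression_mask <- function(train, threshold, max_pairs = NULL) {
  stopifnot(inherits(train, "expression_dataset"))
  if (nrow(train$values) < 3) stop("need >= 3 samples to estimate correlations")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  sds <- apply(train$values, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant gene(s); their correlations treated as 0")
  cc <- suppressWarnings(stats::cor(train$values))
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  keep <- which(abs(cc) >= threshold & upper.tri(cc), arr.ind = TRUE)
  if (!is.null(max_pairs) && nrow(keep) > max_pairs) {
    strength <- abs(cc[keep])
    keep <- keep[order(strength, decreasing = TRUE)[seq_len(max_pairs)], ,
                 drop = FALSE]
  }
  pairs <- symmetrize_pairs(unname(keep))
  attention_mask(pairs, ncol(train$values), "coexp")
}

#' Build a protein-protein-interaction attention mask
#'
#' Reads a TSV/CSV edge list with columns `gene_a`, `gene_b`, `score`
#' (header optional) and keeps edges whose both endpoints map to
#' `gene_ids` and whose score reaches `min_score`.  Unmapped genes are
#' counted and reported via a message; zero mappable edges yields an empty
#' mask with a warning, not an error.  Duplicate edges are deduplicated.
#'
#' @param edges path to the edge list, or a data.frame with the three
#'   columns.
#' @param gene_ids character vector of gene identifiers in matrix column
#'   order.
#' @param min_score minimum confidence score to keep an edge (default 0:
#'   keep all provided edges).
#' @return An `attention_mask` with provenance `"ppi"`; the number of
#'   unmapped endpoint genes is stored in the `unmapped` attribute.
#' @export
ppi_mask <- function(edges, gene_ids, min_score = 0) {
  if (is.character(edges)) {
    sep <- detect_sep(edges)
    raw <- utils::read.table(edges, header = FALSE, sep = sep,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 3) stop("edge list needs columns gene_a, gene_b, score")
    # header detection: third field of the first row must be numeric data
    if (is.na(suppressWarnings(as.numeric(raw[1, 3]))))
      raw <- raw[-1, , drop = FALSE]
    edges <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                        score = as.numeric(raw[[3]]),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  ia <- match(edges$gene_a, gene_ids)
  ib <- match(edges$gene_b, gene_ids)
  unmapped_genes <- unique(c(edges$gene_a[is.na(ia)], edges$gene_b[is.na(ib)]))
  ok <- !is.na(ia) & !is.na(ib)
  if (length(unmapped_genes))
    message(length(unmapped_genes), " edge-list gene(s) not present in ",
            "the expression gene set; ", sum(!ok), "/", nrow(edges),
            " edges dropped")
  pairs <- cbind(ia[ok], ib[ok])
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0)
    warning("no mappable PPI edges; returning an empty mask")
  out <- attention_mask(symmetrize_pairs(pairs), length(gene_ids), "ppi")
  attr(out, "unmapped") <- unmapped_genes
  out
}

#' Merge two attention masks
#'
#' Union of the pair sets; provenance becomes `"both"`.
#'
#' @param a,b `attention_mask` objects over the same gene set.
#' @return Merged `attention_mask`.
#' @export
merge_masks <- function(a, b) {
  stopifnot(inherits(a, "attention_mask"), inherits(b, "attention_mask"))
  if (a$n_genes != b$n_genes) stop("masks cover different numbers of genes")
  attention_mask(rbind(a$pairs, b$pairs), a$n_genes, "both")
}

#' Degree-preserving random permutation of a mask (lesion control)
#'
#' Applies one uniformly random permutation pi of the gene indices to
#' every pair, (i, j) -> (pi(i), pi(j)).  The pair count and the per-node
#' degree multiset are preserved exactly (the permuted mask is isomorphic
#' to the source), so any difference in downstream behaviour isolates the
#' role of *which* genes attend, not how many.
#'
#' @param source non-empty `attention_mask`.
#' @param seed integer seed.
#' @param perm optional explicit permutation (testing hook); overrides the
#'   seeded draw.
#' @return An `attention_mask` with provenance `"random"`.
#' @export
random_permutation_mask <- function(source, seed = 0L, perm = NULL) {
  stopifnot(inherits(source, "attention_mask"))
  if (nrow(source$pairs) == 0) stop("source mask is empty")
  d <- source$n_genes
  if (is.null(perm)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perm <- sample.int(d)
  }
  stopifnot(length(perm) == d, all(sort(perm) == seq_len(d)))
  pairs <- cbind(perm[source$pairs[, 1]], perm[source$pairs[, 2]])
  attention_mask(pairs, d, "random", source_seed = as.integer(seed))
}

#' Write a mask as a two-column TSV of index pairs
#' @param mask an `attention_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("i", "j"))
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path TSV of index pairs.
#' @param n_genes gene count of the mask.
#' @param provenance provenance tag to record.
#' @return An `attention_mask`.
#' @export
read_mask <- function(path, n_genes, provenance = "coexp") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  attention_mask(as.matrix(tab), n_genes, provenance)
}
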