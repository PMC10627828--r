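#' Aggregate taxa to (sub)genus analysis labels
#'
#' Sums counts within each analysis label. The label of a taxon is its
#' \code{subgenus} where one is defined (for example the custom
#' Lactobacillus subgenera) and its \code{genus} otherwise. Column order
#' of the result is label-sorted and deterministic; row sums are
#' preserved exactly.
#'
#' @param counts samples x taxa count matrix.
#' @param taxonomy data frame with \code{taxon_id}, \code{genus} and
#'   optionally \code{subgenus} (NA where not applicable); must cover
#'   every taxon in \code{counts}.
#' @return samples x labels count matrix.
#' @export
aggregate_taxa <- function(counts, taxonomy) {
  check_count_matrix(counts)
  miss <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(miss))
    stop("taxa absent from taxonomy: ", paste(miss, collapse = ", "))
  tx <- taxonomy[match(colnames(counts), taxonomy$taxon_id), , drop = FALSE]
  sub <- if ("subgenus" %in% names(tx)) tx$subgenus else rep(NA_character_, nrow(tx))
  label <- ifelse(is.na(sub) | sub == "", tx$genus, sub)
  if (anyNA(label)) stop("taxa with no genus/subgenus label: ",
                         paste(colnames(counts)[is.na(label)], collapse = ", "))
  out <- t(rowsum(t(counts), group = label, reorder = TRUE))
  storage.mode(out) <- storage.mode(counts)
  out
}

#' Relative abundance
#'
#' Divides each sample row by its total. Rows with zero total are an
#' error (they should have been removed by QC).
#'
#' @param counts samples x taxa count matrix.
#' @return samples x taxa matrix of relative abundances (rows sum to 1),
#'   with a \code{provenance} attribute.
#' @export
relative_abundance <- function(counts) {
  check_count_matrix(counts)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-sum sample row(s): ",
         paste(rownames(counts)[rs == 0], collapse = ", "))
  out <- counts / rs
  attr(out, "provenance") <- "relative"
  out
}

#' Centred log-ratio transform
#'
#' Per sample, \code{clr_i = log(x_i) - mean(log x)} (natural log) after
#' zero replacement. The default zero strategy adds a pseudocount of 0.5
#' to the counts before closure, the common amplicon convention; pass
#' \code{pseudocount = 0} for strictly positive input. Every output row
#' sums to zero.
#'
#' @param x samples x taxa matrix of counts or (zero-free) relative
#'   abundances.
#' @param pseudocount value added to every entry before closure
#'   (default 0.5).
#' @return samples x taxa matrix of CLR values with a
#'   \code{pseudocount} attribute.
#' @examples
#' clr_transform(matrix(c(0.5, 0.25, 0.25), 1, 3,
#'                      dimnames = list("s", c("a", "b", "c"))),
#'               pseudocount = 0)
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  check_count_matrix(x, "x")
  if (any(rowSums(x) == 0)) stop("all-zero sample row(s) cannot be CLR-transformed")
  y <- x + pseudocount
  if (any(y <= 0)) stop("non-positive entries after pseudocount; increase 'pseudocount'")
  ly <- log(y / rowSums(y))
  out <- ly - rowMeans(ly)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Dominance calling
#'
#' The dominant taxon of a sample is its most abundant taxon provided
#' that taxon reaches at least \code{threshold} (default 30\%) relative
#' abundance; otherwise the call is \code{"No dominance"}. A sample is
#' dual-dominant when its second most abundant taxon also reaches the
#' threshold. Ties are broken by taxon label order and flagged.
#'
#' @param abundances samples x taxa relative-abundance matrix.
#' @param threshold dominance threshold (default 0.30).
#' @return data frame: \code{sample_id}, \code{top_taxon},
#'   \code{top_fraction}, \code{second_taxon}, \code{second_fraction},
#'   \code{call}, \code{dual_dominant}, \code{tie}.
#' @export
call_dominance <- function(abundances, threshold = 0.30) {
  check_count_matrix(abundances, "abundances")
  labs <- colnames(abundances)
  ord_lab <- order(labs)  # lexicographic tie-break
  res <- t(apply(abundances[, ord_lab, drop = FALSE], 1L, function(x) {
    o <- order(-x)  # stable: earlier (lexicographically smaller) label wins ties
    c(o[1L], x[o[1L]], o[2L], x[o[2L]])
  }))
  top_taxon <- labs[ord_lab][res[, 1L]]
  second_taxon <- labs[ord_lab][res[, 3L]]
  top_fraction <- res[, 2L]; second_fraction <- res[, 4L]
  data.frame(
    sample_id = rownames(abundances),
    top_taxon = top_taxon, top_fraction = top_fraction,
    second_taxon = second_taxon, second_fraction = second_fraction,
    call = ifelse(top_fraction >= threshold, top_taxon, "No dominance"),
    dual_dominant = second_fraction >= threshold,
    tie = top_fraction == second_fraction,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse rare top-taxon labels
#'
#' For embedding figures: top/second labels of taxa that occur fewer
#' than \code{min_occurrences} times as a cohort's most dominant taxon
#' are replaced by \code{"other"} (strict "less than").
#'
#' @param dominance a data frame from \code{\link{call_dominance}}.
#' @param min_occurrences minimum top-taxon frequency (default 200).
#' @return data frame: \code{sample_id}, \code{top_label},
#'   \code{second_label}.
#' @export
top2_labels <- function(dominance, min_occurrences = 200) {
  freq <- table(dominance$top_taxon)
  keep <- names(freq)[freq >= min_occurrences]
  relabel <- function(x) ifelse(x %in% keep, x, "other")
  data.frame(sample_id = dominance$sample_id,
             top_label = relabel(dominance$top_taxon),
             second_label = relabel(dominance$second_taxon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shannon diversity
#'
#' \eqn{-\sum_i x_i \log x_i} over taxa with \eqn{x_i > 0}; natural log
#' by default.
#'
#' @param abundances samples x taxa relative-abundance matrix.
#' @param base logarithm base (default \code{exp(1)}).
#' @return named numeric vector, one value per sample.
#' @export
shannon_diversity <- function(abundances, base = exp(1)) {
  check_count_matrix(abundances, "abundances")
  vegan::diversity(abundances, index = "shannon", base = base)
}

#' Bray-Curtis distances
#'
#' Pairwise Bray-Curtis dissimilarities between sample profiles.
#'
#' @param abundances samples x taxa relative-abundance matrix.
#' @return a \code{\link[stats]{dist}} object (entries in [0, 1]).
#' @export
bray_curtis <- function(abundances) {
  check_count_matrix(abundances, "abundances")
  vegan::vegdist(abundances, method = "bray")
}

#' Two-dimensional embedding of a distance matrix
#'
#' \code{pcoa}: classical principal coordinates (top two axes of the
#' double-centred distance matrix), deterministic. \code{tsne}:
#' t-distributed stochastic neighbour embedding run on the distance
#' matrix (exact distances, no PCA preprocessing), deterministic given
#' \code{seed}; requires the Rtsne package.
#'
#' @param distances a \code{dist} or square symmetric matrix.
#' @param method \code{"pcoa"} (default) or \code{"tsne"}.
#' @param seed integer seed (used by t-SNE).
#' @param perplexity t-SNE perplexity (default 30; lowered automatically
#'   for small cohorts).
#' @return samples x 2 coordinate matrix.
#' @export
embed_2d <- function(distances, method = c("pcoa", "tsne"), seed = 1L,
                     perplexity = 30) {
  method <- match.arg(method)
  d <- as.dist(distances)
  n <- attr(d, "Size")
  if (n < 3L) stop("embedding needs at least 3 samples")
  if (method == "pcoa") {
    xy <- cmdscale(d, k = 2L)
  } else {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("method 'tsne' requires the Rtsne package")
    perplexity <- min(perplexity, floor((n - 1) / 3))
    set.seed(seed)
    xy <- Rtsne::Rtsne(d, is_distance = TRUE, perplexity = perplexity,
                       pca = FALSE, theta = 0.0, check_duplicates = FALSE)$Y
    rownames(xy) <- attr(d, "Labels")
  }
  colnames(xy) <- c("x", "y")
  xy
}

#' Nearest-centroid community state type assignment
#'
#' Assigns each sample to the reference centroid with maximal
#' similarity. The default similarity is the Yue-Clayton theta,
#' \eqn{\theta = \sum x_i y_i / (\sum x_i^2 + \sum y_i^2 - \sum x_i y_i)}.
#' Centroid taxa are matched to the table's taxon vocabulary by name;
#' unmatched taxa (on either side) are dropped and reported in the
#' \code{dropped_taxa} attribute. Ties are assigned to the
#' lexicographically first centroid label and flagged.
#'
#' @param abundances samples x taxa relative-abundance matrix.
#' @param centroids centroids x taxa matrix of reference profiles
#'   (rownames are CST labels).
#' @param similarity \code{"yue_clayton"} (default) or \code{"cosine"}.
#' @return data frame: \code{sample_id}, \code{cst}, \code{similarity},
#'   \code{tie}; attribute \code{dropped_taxa} lists unmatched taxa.
#' @export
assign_cst <- function(abundances, centroids,
                       similarity = c("yue_clayton", "cosine")) {
  similarity <- match.arg(similarity)
  check_count_matrix(abundances, "abundances")
  if (is.null(dim(centroids)) || nrow(centroids) == 0L)
    stop("empty centroid set")
  shared <- intersect(colnames(abundances), colnames(centroids))
  if (!length(shared)) stop("no taxa shared between table and centroids")
  dropped <- c(setdiff(colnames(abundances), shared),
               setdiff(colnames(centroids), shared))
  # documented label order: lexicographic; ties go to the first
  centroids <- centroids[order(rownames(centroids)), shared, drop = FALSE]
  X <- abundances[, shared, drop = FALSE]
  XY <- X %*% t(centroids)                       # cross products
  x2 <- rowSums(X^2); y2 <- rowSums(centroids^2)
  sim <- switch(similarity,
    yue_clayton = XY / (outer(x2, y2, "+") - XY),
    cosine = XY / outer(sqrt(x2), sqrt(y2)))
  best <- apply(sim, 1L, which.max)  # which.max takes the first on ties
  best_sim <- sim[cbind(seq_len(nrow(sim)), best)]
  tie <- apply(sim, 1L, function(s) sum(s == max(s)) > 1L)
  out <- data.frame(sample_id = rownames(abundances),
                    cst = rownames(centroids)[best],
                    similarity = best_sim, tie = tie,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Paired-platform per-taxon concordance
#'
#' Spearman correlation, per taxon, between the relative abundances of
#' samples profiled on two platforms (for example amplicon versus
#' shotgun). Taxa with constant abundance on either platform get
#' \code{NA}.
#'
#' @param table_a,table_b samples x taxa relative-abundance matrices;
#'   samples are matched by rowname (at least 3 shared required).
#' @param taxa optional taxon subset (default: taxa shared by both).
#' @return data frame: \code{taxon}, \code{rho}, \code{n}.
#' @export
paired_platform_concordance <- function(table_a, table_b, taxa = NULL) {
  shared_s <- intersect(rownames(table_a), rownames(table_b))
  if (length(shared_s) < 3L) stop("fewer than 3 shared samples")
  taxa <- taxa %||% intersect(colnames(table_a), colnames(table_b))
  rho <- vapply(taxa, function(t) {
    a <- table_a[shared_s, t]; b <- table_b[shared_s, t]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, numeric(1))
  data.frame(taxon = taxa, rho = rho, n = length(shared_s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Within- and between-group distance distributions
#'
#' Exhaustively enumerates the unordered sample pairs of a distance
#' matrix and partitions their distances by the (unordered) pair of
#' group labels, e.g. for comparing beta-diversity distributions within
#' and between community state types.
#'
#' @param distances a \code{dist} or square symmetric matrix.
#' @param groups group label per sample (in distance-matrix order).
#' @return data frame: \code{group1}, \code{group2} (sorted within
#'   pair), \code{type} ("within"/"between"), \code{distance}.
#' @export
beta_group_distributions <- function(distances, groups) {
  m <- as.matrix(distances)
  n <- nrow(m)
  if (length(groups) != n) stop("'groups' must label every sample")
  groups <- as.character(groups)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  g1 <- groups[idx[, 1L]]; g2 <- groups[idx[, 2L]]
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  data.frame(group1 = lo, group2 = hi,
             type = ifelse(lo == hi, "within", "between"),
             distance = m[idx], row.names = NULL, stringsAsFactors = FALSE)
}
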