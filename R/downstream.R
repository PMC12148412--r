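#' Hierarchical clustering of fold-change profiles
#'
#' Groups proteins by the shape of their log fold-change profiles
#' (e.g. per-temperature ratios or per-condition logFC blocks) with
#' agglomerative hierarchical clustering: Euclidean distance, average
#' linkage, tree cut to `k` clusters (default 5). Residual missing cells
#' are imputed with the row mean before distances are computed. Rows are
#' sorted by protein identifier first, so the result does not depend on
#' input order and distance ties resolve toward the lower identifier.
#'
#' @param logfc_matrix numeric matrix, proteins (rows, named) x features
#'   (columns); NAs allowed if every row has at least one finite value.
#' @param k number of clusters; default 5; must satisfy
#'   `2 <= k <= nrow(logfc_matrix)`.
#' @param method linkage method passed to [stats::hclust()]; default
#'   `"average"`.
#' @return data.frame with columns `protein_id` and `cluster` (integer
#'   1..k); the `"hclust"` attribute carries the dendrogram.
#' @export
cluster_profiles <- function(logfc_matrix, k = 5, method = "average") {
  stopifnot(is.matrix(logfc_matrix), k >= 2)
  if (is.null(rownames(logfc_matrix))) {
    stop("logfc_matrix must have protein ids as row names")
  }
  if (k > nrow(logfc_matrix)) {
    stop("k (", k, ") exceeds the number of proteins (",
         nrow(logfc_matrix), ")")
  }
  m <- logfc_matrix[order(rownames(logfc_matrix)), , drop = FALSE]
  rm <- rowMeans(m, na.rm = TRUE)
  if (any(!is.finite(rm))) stop("row(s) with no finite value cannot be imputed")
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- rm[idx[, 1]]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
  cl <- stats::cutree(hc, k = k)
  out <- data.frame(protein_id = rownames(m), cluster = unname(cl))
  rownames(out) <- NULL
  attr(out, "hclust") <- hc
  out
}

#' Protein-complex co-melting summary
#'
#' Proteins in a complex tend to melt together, so a perturbation that
#' destabilizes a complex shows up as a high fraction of hit subunits.
#' For each complex this summarizes how many scored members are hits and
#' adds a hypergeometric enrichment test (drawing the complex's scored
#' members from a universe containing all hits) with BH-adjusted q-values
#' across complexes — an extension beyond descriptive matching.
#'
#' @param hits character vector of hit protein ids (or a hit data.frame
#'   with a `protein_id` column).
#' @param universe character vector of all scored protein ids; must
#'   contain every hit.
#' @param complexes complex table from [read_complex_table()] (columns
#'   `complex_id`, `complex_name`, list-column `subunits`).
#' @return data.frame, one row per complex with at least one member in
#'   the universe: `complex_id`, `complex_name`, `n_members_in_universe`,
#'   `n_hit_members`, `hit_fraction`, `p_enrich`, `q_enrich`.
#' @export
complex_comelt <- function(hits, universe, complexes) {
  if (is.data.frame(hits)) hits <- hits$protein_id
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe)) {
    stop("universe must contain every hit protein")
  }
  K <- length(hits)
  N <- length(universe)
  rows <- lapply(seq_len(nrow(complexes)), function(i) {
    members <- intersect(complexes$subunits[[i]], universe)
    n <- length(members)
    if (n == 0) return(NULL)
    x <- length(intersect(members, hits))
    # P(X >= x) drawing n members from N with K hit successes
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(complex_id = complexes$complex_id[i],
               complex_name = complexes$complex_name[i],
               n_members_in_universe = n,
               n_hit_members = x,
               hit_fraction = x / n,
               p_enrich = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(complex_id = character(0), complex_name = character(0),
                      n_members_in_universe = integer(0),
                      n_hit_members = integer(0), hit_fraction = numeric(0),
                      p_enrich = numeric(0), q_enrich = numeric(0)))
  }
  out$q_enrich <- stats::p.adjust(out$p_enrich, method = "BH")
  rownames(out) <- NULL
  out
}
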