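## Cross-drug similarity structure: Jaccard similarity over key-signal
## sets, the percentile-thresholded network backbone, heatmap leaf
## ordering, and 2-D classical (Torgerson) multidimensional scaling.

#' Jaccard similarity matrix over drug signal sets
#'
#' `J(A, B) = |S_A intersect S_B| / |S_A union S_B|` over the key-signal
#' PT sets. When both sets are empty the union is empty and `J = 0` by
#' convention (a warning is emitted once); the diagonal is 1 for drugs
#' with non-empty sets. The dissimilarity view `1 - J` is a metric
#' (Jaccard distance).
#'
#' @param sm a [signal_matrix()] (or any logical drug x PT matrix).
#' @return an n x n `similarity_matrix` with drug labels and a `classes`
#'   attribute carried over from `sm`.
#' @export
jaccard_matrix <- function(sm) {
  m <- unclass(sm) * 1
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  j <- inter / uni
  if (any(uni == 0)) {
    warning("drug pair(s) with empty signal-set union: J set to 0",
            call. = FALSE)
    j[uni == 0] <- 0
  }
  dimnames(j) <- list(rownames(m), rownames(m))
  structure(j, class = c("similarity_matrix", "matrix", "array"),
            classes = attr(sm, "classes"))
}

#' Dissimilarity view of a similarity matrix
#'
#' @param sim a [jaccard_matrix()] result.
#' @return the matrix `1 - J`.
#' @export
dissimilarity <- function(sim) {
  d <- 1 - unclass(sim)
  diag(d) <- 0
  d
}

#' Percentile-thresholded network backbone
#'
#' The threshold is the linear-interpolation quantile (`stats::quantile`
#' type 7) of the `n(n-1)/2` off-diagonal upper-triangle similarities at
#' `percentile/100`; edges with weight at or above the threshold are
#' retained (ties at the threshold survive, so slightly more than the
#' nominal share of edges may be kept). The default 80th percentile keeps
#' the strongest ~20% of similarities; 70/90 are the conventional
#' sensitivity settings.
#'
#' @param sim a [jaccard_matrix()] result (n >= 2).
#' @param percentile real in (0, 100).
#' @return a `network_backbone`: list with `threshold`, `percentile`, and
#'   `edges` (data.table: `from`, `to`, `weight`, upper triangle only).
#' @export
backbone <- function(sim, percentile = 80) {
  m <- unclass(sim)
  n <- nrow(m)
  stopifnot(n >= 2)
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)", call. = FALSE)
  }
  ut <- upper.tri(m)
  vals <- m[ut]
  thr <- unname(stats::quantile(vals, percentile / 100, type = 7))
  idx <- which(ut & m >= thr, arr.ind = TRUE)
  edges <- data.table::data.table(
    from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
    weight = m[idx])
  data.table::setorder(edges, from, to)
  structure(list(threshold = thr, percentile = percentile, edges = edges,
                 nodes = rownames(m), classes = attr(sim, "classes")),
            class = "network_backbone")
}

#' Connected components of a backbone
#'
#' Isolated drugs (no surviving edge) form singleton components, so the
#' partition always covers the full drug panel.
#'
#' @param bb a [backbone()] result.
#' @return named integer vector: component id per drug.
#' @export
backbone_components <- function(bb) {
  nodes <- bb$nodes
  comp <- stats::setNames(seq_along(nodes), nodes)
  if (nrow(bb$edges)) {
    for (i in seq_len(nrow(bb$edges))) {
      ci <- comp[bb$edges$from[i]]
      cj <- comp[bb$edges$to[i]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  # renumber components in first-appearance order
  stats::setNames(match(comp, unique(comp)), nodes)
}

#' Heatmap leaf order by hierarchical clustering
#'
#' Agglomerative clustering (average linkage) on the Jaccard
#' dissimilarity `1 - J`; rows are pre-sorted by label so the leaf order
#' is deterministic under input permutation (ties broken by label).
#'
#' @param sim a [jaccard_matrix()] result (n >= 2).
#' @return character vector: drug labels in leaf order.
#' @export
cluster_order <- function(sim) {
  m <- unclass(sim)
  stopifnot(nrow(m) >= 2)
  ord <- order(rownames(m), method = "radix")
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  rownames(m)[hc$order]
}

#' Classical (Torgerson) MDS embedding of drug dissimilarities
#'
#' Double-centers the squared dissimilarity matrix,
#' `B = -1/2 C D^2 C`, and extracts the top-2 eigenpairs. Negative
#' eigenvalues (possible because Jaccard distances need not be Euclidean)
#' are clamped to zero and their relative mass reported. Coordinates are
#' centered at the origin; the sign of each axis is fixed by making its
#' largest-magnitude coordinate positive, so embeddings are reproducible.
#'
#' @param sim a [jaccard_matrix()] result (n >= 3).
#' @param k embedding dimension (default 2, the first two principal
#'   coordinates).
#' @return an `mds_embedding`: list with `points` (n x k), `eig` (all
#'   eigenvalues, descending) and `negative_mass` (sum of clamped
#'   negative-eigenvalue magnitudes over total absolute mass).
#' @export
mds_embed <- function(sim, k = 2L) {
  d <- dissimilarity(sim)
  n <- nrow(d)
  if (n < 3) stop("MDS embedding needs at least 3 drugs", call. = FALSE)
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d^2) %*% cmat
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lam <- e$values
  neg_mass <- sum(abs(lam[lam < 0])) / max(sum(abs(lam)), .Machine$double.eps)
  lam_cl <- pmax(lam[seq_len(k)], 0)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam_cl), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts, eig = lam, negative_mass = neg_mass,
                 classes = attr(sim, "classes")),
            class = "mds_embedding")
}

#' Within- versus between-class mean similarity
#'
#' Summarizes class structure in a similarity matrix: the mean Jaccard
#' similarity over drug pairs sharing a target class versus pairs from
#' different classes.
#'
#' @param sim a [jaccard_matrix()] with a `classes` attribute.
#' @param classes optional named class vector overriding the attribute.
#' @return list with `within`, `between` (means; `NaN` when a group has
#'   no pairs).
#' @export
class_contrast <- function(sim, classes = NULL) {
  m <- unclass(sim)
  if (is.null(classes)) classes <- attr(sim, "classes")
  classes <- classes[rownames(m)]
  ut <- upper.tri(m)
  same <- outer(classes, classes, "==")
  list(within = mean(m[ut & same]), between = mean(m[ut & !same]))
}
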