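## Cross-cohort subtype transfer: a supervised embedding of the reference
## cohort on the overlapping hub proteins, nearest-centroid assignment of
## query samples with a distance-based unassignment rule, and cross-study
## subtype signature correlation.

#' Fit a supervised reference embedding
#'
#' Two modes share one contract (a deterministic transform that can project
#' query samples and assign them to the nearest embedded class centroid):
#'
#' * `linear_fallback` (default): features are standardized within the
#'   cohort, reduced by PCA (at most `n_pcs` components) and passed through a
#'   linear discriminant analysis; all `n_classes - 1` discriminants are kept
#'   for centroid assignment (within-class whitened units), and the first two
#'   serve as plot coordinates.  Fully deterministic.
#' * `supervised_umap`: label-supervised nonlinear 2-D embedding via the
#'   `uwot` package (n_neighbors = 10, n_components = 2, Euclidean metric,
#'   min_dist = 0.1 by default); stochastic up to its seed.
#'
#' Cross-cohort comparability comes from standardizing every protein within
#' its own cohort (mean 0, SD 1 across samples), so global abundance shifts
#' and platform scale differences cancel before projection.
#'
#' @param ref_expr reference hub-protein x sample matrix, already restricted
#'   to the proteins shared with the query cohort (>= 10).
#' @param labels reference subtype label per sample (>= 2 classes; NA
#'   samples are dropped).
#' @param mode `"linear_fallback"` or `"supervised_umap"`.
#' @param n_pcs PCA components retained before the discriminant step.
#' @param n_neighbors,min_dist supervised-umap parameters.
#' @param seed seed for the stochastic mode.
#' @return list of class `transfer_model`: `coords` (reference samples x 2,
#'   for plotting), `centroids` (class centroids in assignment space),
#'   `overlap_proteins`, `self_consistency` (fraction of reference samples
#'   whose nearest centroid is their own class), plus the retained
#'   transform.
#' @export
fit_reference_embedding <- function(ref_expr, labels,
                                    mode = c("linear_fallback", "supervised_umap"),
                                    n_pcs = 20L, n_neighbors = 10L,
                                    min_dist = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  check_expr(ref_expr, allow_na = FALSE)
  labels <- labels[colnames(ref_expr)]
  if (anyNA(labels)) {
    keep <- !is.na(labels)
    ref_expr <- ref_expr[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stopf("need >= 2 subtype labels")
  if (nrow(ref_expr) < 10) stopf("need >= 10 overlap proteins")
  X <- t(row_standardize(ref_expr))              # samples x proteins

  if (mode == "linear_fallback") {
    d <- min(n_pcs, nrow(X) - 1L, ncol(X))
    pc <- stats::prcomp(X, rank. = d)
    lda_fit <- MASS::lda(pc$x, grouping = factor(labels))
    scores <- stats::predict(lda_fit, pc$x)$x
    fit <- list(pc = pc, lda = lda_fit)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stopf("supervised_umap mode requires the 'uwot' package")
    set.seed(seed)
    fit <- uwot::umap(X, y = factor(labels), n_neighbors = n_neighbors,
                      n_components = 2L, metric = "euclidean",
                      min_dist = min_dist, ret_model = TRUE,
                      n_sgd_threads = 1L)
    scores <- fit$embedding
  }
  rownames(scores) <- colnames(ref_expr)
  cls <- sort(unique(labels))
  centroids <- t(vapply(cls, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]), numeric(ncol(scores))))
  rownames(centroids) <- cls

  d <- centroid_distances(scores, centroids)
  self <- mean(cls[max.col(-d, ties.method = "first")] == labels)

  coords <- if (ncol(scores) >= 2) scores[, 1:2] else cbind(scores[, 1], 0)
  colnames(coords) <- c("dim1", "dim2")
  structure(list(mode = mode, fit = fit, scores = scores, coords = coords,
                 centroids = centroids, labels = labels,
                 overlap_proteins = rownames(ref_expr),
                 reference_means = rowMeans(ref_expr),
                 self_consistency = self),
            class = "transfer_model")
}

#' @noRd
centroid_distances <- function(scores, centroids) {
  d <- matrix(0, nrow(scores), nrow(centroids),
              dimnames = list(rownames(scores), rownames(centroids)))
  for (k in seq_len(nrow(centroids)))
    d[, k] <- sqrt(rowSums(sweep(scores, 2L, centroids[k, ])^2))
  d
}

#' Project query samples and assign subtypes by nearest centroid
#'
#' Query features are standardized within the query cohort, projected
#' through the reference transform, and assigned to the subtype with the
#' nearest embedded centroid in Euclidean distance; a query strictly more
#' than `cutoff` from every centroid is left unassigned (a distance exactly
#' equal to the cutoff still assigns).  Overlap proteins missing from the
#' query are filled with the reference means and counted.
#'
#' @param model a `transfer_model` from [fit_reference_embedding()].
#' @param query_expr query protein x sample matrix (complete).
#' @param cutoff unassignment distance in embedding units (default 3;
#'   scale-dependent - meaningful relative to the embedding's within-class
#'   spread, which is ~1 per dimension in fallback mode).
#' @return list of class `transfer_result`: `assignments` (data frame
#'   sample, label, distance, assigned), `coords` (2-D), `n_filled_proteins`.
#' @export
project_and_assign <- function(model, query_expr, cutoff = 3.0) {
  check_expr(query_expr, allow_na = FALSE)
  shared <- intersect(model$overlap_proteins, rownames(query_expr))
  if (!length(shared)) stopf("query shares no proteins with the reference model")
  Xq <- matrix(model$reference_means, nrow = length(model$overlap_proteins),
               ncol = ncol(query_expr),
               dimnames = list(model$overlap_proteins, colnames(query_expr)))
  Xq[shared, ] <- query_expr[shared, , drop = FALSE]
  n_filled <- length(model$overlap_proteins) - length(shared)
  Xq <- t(row_standardize(Xq))

  scores <- if (model$mode == "linear_fallback") {
    stats::predict(model$fit$lda, stats::predict(model$fit$pc, Xq))$x
  } else {
    uwot::umap_transform(Xq, model$fit, n_sgd_threads = 1L)
  }
  rownames(scores) <- colnames(query_expr)

  d <- centroid_distances(scores, model$centroids)
  nearest <- max.col(-d, ties.method = "first")
  dist_min <- d[cbind(seq_len(nrow(d)), nearest)]
  label <- rownames(model$centroids)[nearest]
  assigned <- dist_min <= cutoff                  # strictly > cutoff unassigns
  label[!assigned] <- NA_character_
  coords <- if (ncol(scores) >= 2) scores[, 1:2] else cbind(scores[, 1], 0)
  colnames(coords) <- c("dim1", "dim2")
  structure(list(assignments = data.frame(sample = colnames(query_expr),
                                          label = label,
                                          distance = dist_min,
                                          assigned = assigned,
                                          stringsAsFactors = FALSE),
                 coords = coords,
                 n_filled_proteins = n_filled,
                 cutoff = cutoff),
            class = "transfer_result")
}

#' Mean-centered subtype signature matrix
#'
#' Per protein, the subtype means minus the reference-subtype mean, z-scored
#' across the non-reference subtypes (sample SD, n-1 denominator); the
#' reference column is excluded from the output.  Proteins constant across
#' subtypes are dropped with a warning.
#'
#' @param expr complete protein x sample matrix.
#' @param labels sample subtype labels.
#' @param reference_label the control-like reference subtype.
#' @return protein x subtype signature matrix.
#' @export
subtype_signature <- function(expr, labels, reference_label = "S1") {
  check_expr(expr, allow_na = FALSE)
  labels <- labels[colnames(expr)]
  cls <- sort(unique(labels[!is.na(labels)]))
  if (!reference_label %in% cls)
    stopf("reference label '%s' not present", reference_label)
  if (length(cls) < 3)
    stopf("need >= 2 non-reference subtypes")
  means <- vapply(cls, function(cl)
    rowMeans(expr[, !is.na(labels) & labels == cl, drop = FALSE]),
    numeric(nrow(expr)))
  centered <- means[, setdiff(cls, reference_label), drop = FALSE] -
    means[, reference_label]
  sds <- apply(centered, 1L, stats::sd)
  keep <- !is.na(sds) & sds > 0
  if (any(!keep))
    warnf("%d proteins constant across subtypes dropped from the signature",
          sum(!keep))
  (centered[keep, , drop = FALSE] -
      rowMeans(centered[keep, , drop = FALSE])) / sds[keep]
}

#' Cross-study subtype signature correlation
#'
#' Biweight midcorrelation between every subtype column of two signature
#' matrices over their shared proteins, with Student-t p-values.
#'
#' @param sig_a,sig_b protein x subtype signature matrices.
#' @param min_shared minimum shared proteins (default 10).
#' @return list: `bicor` (subtypes of A x subtypes of B), `p`, `n_shared`.
#' @export
signature_correlation <- function(sig_a, sig_b, min_shared = 10L) {
  shared <- intersect(rownames(sig_a), rownames(sig_b))
  if (length(shared) < min_shared)
    stopf("only %d shared proteins (need >= %d)", length(shared), min_shared)
  A <- sig_a[shared, , drop = FALSE]
  B <- sig_b[shared, , drop = FALSE]
  r <- bicor_cross(t(A), t(B))
  n <- length(shared)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  dimnames(r) <- dimnames(p) <- list(colnames(A), colnames(B))
  list(bicor = r, p = p, n_shared = n)
}
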