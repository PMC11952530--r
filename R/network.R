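## Weighted co-expression network construction: biweight midcorrelation,
## signed soft-threshold adjacency, topological overlap, average-linkage
## clustering with a dynamic branch cut, module eigenproteins, kME,
## module-trait correlation and marker-set enrichment.

#' Internal: biweight-normalized rows
#'
#' Each row is centered on its median and weighted by the Tukey biweight with
#' the standard 9-MAD outlier cut, then scaled to unit sum of squares, so the
#' biweight midcorrelation of two rows is the inner product of their
#' normalized forms.  Rows with zero MAD fall back to the Pearson
#' normalization (mean/SD), as in the reference treatment of the statistic.
#' @return list(mat = normalized rows, fallback = logical per row)
#' @noRd
bicor_normalize <- function(x) {
  x <- as.matrix(x)
  med <- row_medians(x)
  mad <- apply(x, 1L, stats::mad, constant = 1)
  fallback <- mad == 0 | is.na(mad)
  u <- (x - med) / (9 * mad)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  if (any(fallback)) {
    mu <- rowMeans(x[fallback, , drop = FALSE])
    xt[fallback, ] <- x[fallback, , drop = FALSE] - mu
  }
  ss <- sqrt(rowSums(xt^2))
  zero <- ss == 0
  ss[zero] <- 1
  list(mat = xt / ss, fallback = fallback, constant = zero)
}

#' Biweight midcorrelation matrix
#'
#' Outlier-robust correlation between all row pairs: observations are
#' weighted by the Tukey biweight around the row median (weights vanish
#' beyond 9 MADs).  Zero-MAD rows use a Pearson fallback with a warning;
#' constant rows give 0 against everything (and 1 on the diagonal).
#'
#' @param expr complete numeric matrix, variables in rows, >= 3 columns.
#' @return symmetric correlation matrix with unit diagonal, values in
#'   \[-1, 1\].
#' @export
bicor_matrix <- function(expr) {
  check_expr(expr, allow_na = FALSE)
  if (ncol(expr) < 3) stopf("bicor needs >= 3 samples")
  nz <- bicor_normalize(expr)
  if (any(nz$fallback))
    warnf("%d zero-MAD rows used the Pearson fallback", sum(nz$fallback))
  r <- tcrossprod(nz$mat)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Biweight midcorrelation between the rows of two matrices
#'
#' @param x,y matrices with the same columns (samples).
#' @return `nrow(x)` x `nrow(y)` correlation matrix.
#' @export
bicor_cross <- function(x, y) {
  if (ncol(x) != ncol(y)) stopf("x and y must share samples (columns)")
  if (ncol(x) < 3) stopf("bicor needs >= 3 samples")
  r <- tcrossprod(bicor_normalize(x)$mat, bicor_normalize(y)$mat)
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Biweight midcorrelation of two vectors
#' @param x,y numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  as.numeric(bicor_cross(rbind(x), rbind(y)))
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Signed form `((1 + cor) / 2)^beta` keeps anticorrelated proteins apart
#' (adjacency -> 0 at cor = -1); unsigned form is `|cor|^beta`.
#'
#' @param cor correlation matrix.
#' @param power soft threshold beta >= 1 (default 6).
#' @param signed use the signed transform (default TRUE).
#' @return adjacency in \[0, 1\] with unit diagonal.
#' @export
adjacency_matrix <- function(cor, power = 6, signed = TRUE) {
  if (power < 1) stopf("soft-threshold power must be >= 1")
  a <- if (signed) ((1 + cor) / 2)^power else abs(cor)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivities `k` excluding the diagonal: the similarity of two nodes'
#' weighted neighborhoods, 1 when they share all neighbors and each other.
#'
#' @param adj adjacency matrix with entries in \[0, 1\].
#' @return symmetric TOM with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (any(adj < 0 | adj > 1)) stopf("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom
}

#' Scale-free topology fit across candidate soft powers
#'
#' Diagnostic only: for each power, the R-squared of the log-log regression
#' of the connectivity distribution and the mean connectivity.
#'
#' @param cor correlation matrix.
#' @param powers candidate powers.
#' @param signed signed adjacency flag.
#' @param n_breaks histogram bins for the degree distribution fit.
#' @return data frame: power, sft_r2, slope, mean_k.
#' @export
pick_soft_threshold <- function(cor, powers = c(1:10, seq(12, 20, 2)),
                                signed = TRUE, n_breaks = 10) {
  res <- lapply(powers, function(b) {
    a <- adjacency_matrix(cor, power = b, signed = signed)
    diag(a) <- 0
    k <- rowSums(a)
    cut <- cut(k, breaks = n_breaks)
    dk <- tapply(k, cut, mean)
    pk <- tapply(k, cut, length) / length(k)
    ok <- !is.na(dk) & dk > 0 & pk > 0
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    data.frame(power = b,
               sft_r2 = summary(fit)$r.squared,
               slope = stats::coef(fit)[2],
               mean_k = mean(k))
  })
  do.call(rbind, res)
}

#' Cut an average-linkage dendrogram into modules
#'
#' Builds the average-linkage tree of `1 - TOM` dissimilarities and splits
#' it top-down: a branch is divided when both children hold at least
#' `min_module_size` proteins and the merge sits clearly above the children's
#' own core heights (the 60th percentile of their internal merge heights), by
#' a gap that shrinks as the `deep_split` sensitivity grows (0 =
#' conservative, 4 = aggressive).  This lets correlated-but-distinct branches
#' separate even when stray proteins chain onto them near the top of the
#' tree.  Branches smaller than `min_module_size` are dissolved; their
#' proteins are re-assigned to the closest qualifying module by average
#' dissimilarity when they fall within that module's 95th-percentile
#' internal dissimilarity, otherwise left unassigned (NA).  A tree with no
#' height structure yields no modules.
#'
#' @param diss dissimilarity matrix (1 - TOM).
#' @param min_module_size smallest allowed module (default 10).
#' @param deep_split 0-4 branch-split sensitivity (default 2).
#' @return character vector of labels M1.. (size-ordered) or NA, named by
#'   protein.
#' @export
cluster_and_cut <- function(diss, min_module_size = 10L, deep_split = 2L) {
  p <- nrow(diss)
  labels <- stats::setNames(rep(NA_character_, p), rownames(diss))
  if (p < min_module_size) {
    warnf("fewer proteins (%d) than min_module_size (%d): all unassigned",
          p, min_module_size)
    return(labels)
  }
  if (!deep_split %in% 0:4) stopf("deep_split must be in 0..4")
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- hc$height
  span <- max(h) - min(h)
  if (span < 1e-10) return(labels)              # no structure
  gap_frac <- c(`0` = 0.20, `1` = 0.12, `2` = 0.06, `3` = 0.03, `4` = 0.015)
  gap <- gap_frac[[as.character(deep_split)]] * span

  ## per-node leaves and internal merge heights (merge rows are height-sorted)
  n_node <- nrow(hc$merge)
  leaves <- vector("list", n_node)
  node_heights <- vector("list", n_node)
  for (i in seq_len(n_node)) {
    ch <- hc$merge[i, ]
    lv <- hts <- list()
    for (c_ in ch) {
      if (c_ < 0) { lv <- c(lv, list(-c_)) } else {
        lv <- c(lv, list(leaves[[c_]]))
        hts <- c(hts, list(node_heights[[c_]]))
      }
    }
    leaves[[i]] <- unlist(lv)
    node_heights[[i]] <- c(unlist(hts), hc$height[i])
  }
  core_height <- function(node) {
    if (node < 0) return(min(h))
    hh <- node_heights[[node]]
    hh <- hh[-length(hh)]                       # exclude the node's own merge
    if (!length(hh)) return(min(h))
    stats::quantile(hh, 0.6, names = FALSE)
  }
  size_of <- function(node) if (node < 0) 1L else length(leaves[[node]])

  raw <- integer(p)
  next_cl <- 0L
  assign_cluster <- function(node) {
    next_cl <<- next_cl + 1L
    idx <- if (node < 0) -node else leaves[[node]]
    raw[idx] <<- next_cl
  }
  descend <- function(node) {
    if (node < 0) { assign_cluster(node); return(invisible()) }
    ch <- hc$merge[node, ]
    s1 <- size_of(ch[1]); s2 <- size_of(ch[2])
    if (min(s1, s2) < min_module_size && max(s1, s2) >= min_module_size) {
      ## stray branch chained onto a large one: shed it as its own (small)
      ## cluster - dissolved and re-attached below - and keep descending
      small <- if (s1 < s2) ch[1] else ch[2]
      big <- if (s1 < s2) ch[2] else ch[1]
      assign_cluster(small)
      descend(big)
      return(invisible())
    }
    splittable <- min(s1, s2) >= min_module_size &&
      hc$height[node] - max(core_height(ch[1]), core_height(ch[2])) >= gap
    if (splittable) { descend(ch[1]); descend(ch[2]) } else assign_cluster(node)
  }
  descend(n_node)

  sizes <- table(raw)
  core <- as.integer(names(sizes)[sizes >= min_module_size])
  if (!length(core)) return(labels)

  lab <- ifelse(raw %in% core, raw, NA_integer_)
  ## re-attach stray proteins to the closest qualifying branch when they sit
  ## closer to that branch's internal dissimilarity level than to the
  ## between-branch level (midpoint rule, scale-adaptive)
  internal_level <- vapply(core, function(cl) {
    dd <- diss[lab %in% cl, lab %in% cl]
    mean(dd[upper.tri(dd)])
  }, numeric(1))
  between_level <- vapply(core, function(cl)
    mean(diss[lab %in% cl, !is.na(lab) & !(lab %in% cl), drop = FALSE]),
    numeric(1))
  between_level[is.nan(between_level)] <- max(diss)
  stray <- which(is.na(lab))
  if (length(stray)) {
    avg_d <- vapply(core, function(cl)
      rowMeans(diss[stray, lab %in% cl, drop = FALSE]), numeric(length(stray)))
    avg_d <- matrix(avg_d, nrow = length(stray))
    best <- max.col(-avg_d, ties.method = "first")
    ok <- avg_d[cbind(seq_along(stray), best)] <
      (internal_level[best] + between_level[best]) / 2
    lab[stray[ok]] <- core[best[ok]]
  }
  labels[] <- ifelse(is.na(lab), NA_character_, paste0("C", lab))
  relabel_by_size(labels, prefix = "M")
}

#' Module eigenproteins
#'
#' The first right-singular vector of each module's row-standardized
#' submatrix, scaled to unit variance, with the sign chosen so the mean
#' correlation with the module's member proteins (kME) is positive.
#'
#' @param expr complete log2 matrix.
#' @param labels protein module labels (NA = unassigned).
#' @return list: `eigenproteins` (module x sample, unit variance rows),
#'   `var_explained` (named fraction per module).
#' @export
module_eigenproteins <- function(expr, labels) {
  check_expr(expr, allow_na = FALSE)
  labels <- labels[rownames(expr)]
  mods <- unique(labels[!is.na(labels)])
  if (!length(mods)) stopf("no assigned modules")
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", mods)))
  mods <- mods[order(!is.na(num), num, mods)]
  E <- matrix(NA_real_, length(mods), ncol(expr),
              dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    sub <- row_standardize(expr[which(labels == m), , drop = FALSE])
    sv <- svd(sub, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(t(sub), e)) < 0) e <- -e
    E[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigenproteins = E, var_explained = ve)
}

#' Merge modules with similar eigenproteins
#'
#' Repeatedly merges the pair of modules whose eigenprotein dissimilarity
#' `1 - cor` is smallest, while it is below `merge_cut_height`, recomputing
#' eigenproteins after every merge; the result is relabeled by size.
#'
#' @param expr complete matrix.
#' @param labels module labels.
#' @param merge_cut_height eigenprotein dissimilarity threshold (default
#'   0.7).
#' @return merged, size-ordered label vector.
#' @export
merge_modules <- function(expr, labels, merge_cut_height = 0.7) {
  labels <- labels[rownames(expr)]
  repeat {
    mods <- unique(labels[!is.na(labels)])
    if (length(mods) < 2) break
    E <- module_eigenproteins(expr, labels)$eigenproteins
    d <- 1 - stats::cor(t(E))
    diag(d) <- Inf
    ## deterministic, label-invariant tie-break: smallest d, then smallest
    ## combined member-ID key
    mn <- min(d)
    if (mn >= merge_cut_height) break
    cand <- which(d - mn < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      mem <- sort(names(labels)[which(labels %in% rownames(d)[ij])])
      paste(mem, collapse = "\r")
    })
    ij <- cand[order(keys)[1], ]
    a <- rownames(d)[ij[1]]; b <- rownames(d)[ij[2]]
    labels[labels == b] <- a
  }
  relabel_by_size(labels, prefix = "M")
}

#' kME table: protein-to-eigenprotein biweight midcorrelation
#'
#' @param expr complete matrix.
#' @param eigenproteins module x sample matrix from
#'   [module_eigenproteins()].
#' @return protein x module matrix of kME values.
#' @export
kme_table <- function(expr, eigenproteins) {
  bicor_cross(expr, eigenproteins)
}

#' Module-trait correlation table
#'
#' Biweight midcorrelation of each module eigenprotein with each numeric
#' trait, with the two-sided Student-t p-value.  For subjects measured in
#' both sets only the set-1 sample is used (`replicate_policy =
#' "first_set_only"`).
#'
#' @param eigenproteins module x sample matrix.
#' @param traits per-sample data frame (`sample_id`, `subject_id`, `set` plus
#'   columns of `trait_cols`), or a numeric data frame with sample rownames.
#' @param trait_cols numeric trait columns to correlate.
#' @param replicate_policy `"first_set_only"` or `"all"`.
#' @return data frame: module, trait, bicor, p, n.
#' @export
module_trait_correlation <- function(eigenproteins, traits, trait_cols,
                                     replicate_policy = c("first_set_only", "all")) {
  replicate_policy <- match.arg(replicate_policy)
  tr <- as.data.frame(traits)
  if (!is.null(tr$sample_id)) rownames(tr) <- tr$sample_id
  keep <- colnames(eigenproteins)[colnames(eigenproteins) %in% rownames(tr)]
  tr <- tr[keep, , drop = FALSE]
  if (replicate_policy == "first_set_only" &&
      all(c("subject_id", "set") %in% names(tr))) {
    ord <- order(tr$set)
    first <- !duplicated(tr$subject_id[ord])
    keep <- rownames(tr)[ord][first]
  }
  E <- eigenproteins[, keep, drop = FALSE]
  tr <- tr[keep, , drop = FALSE]

  rows <- list()
  for (tc in trait_cols) {
    v <- tr[[tc]]
    ok <- !is.na(v)
    for (m in rownames(E)) {
      if (sum(ok) < 3) {
        rows[[length(rows) + 1]] <- data.frame(module = m, trait = tc,
                                               bicor = NA_real_, p = NA_real_,
                                               n = sum(ok))
        next
      }
      r <- bicor(E[m, ok], v[ok])
      n <- sum(ok)
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      rows[[length(rows) + 1]] <- data.frame(module = m, trait = tc,
                                             bicor = r, p = p, n = n)
    }
  }
  do.call(rbind, rows)
}

#' Marker-set enrichment of modules (one-tailed Fisher)
#'
#' Hypergeometric upper-tail test of the overlap between each module and
#' each marker set, against the network background.
#'
#' @param labels protein module labels (NA = unassigned).
#' @param marker_sets named list of protein ID vectors.
#' @param background protein universe (default: all labeled input proteins).
#' @return data frame: module, set, overlap, module_size, set_size,
#'   odds_ratio, p (NA with a note when a set is empty after intersection).
#' @export
marker_enrichment <- function(labels, marker_sets,
                              background = names(labels)) {
  mods <- unique(labels[!is.na(labels)])
  rows <- list()
  for (sn in names(marker_sets)) {
    set <- intersect(marker_sets[[sn]], background)
    for (m in mods) {
      memb <- names(labels)[!is.na(labels) & labels == m]
      memb <- intersect(memb, background)
      if (!length(set)) {
        rows[[length(rows) + 1]] <- data.frame(module = m, set = sn,
                                               overlap = 0L, module_size = length(memb),
                                               set_size = 0L, odds_ratio = NA_real_,
                                               p = NA_real_)
        next
      }
      q <- length(intersect(memb, set))
      Nn <- length(background)
      p <- stats::phyper(q - 1, length(set), Nn - length(set), length(memb),
                         lower.tail = FALSE)
      a <- q; b <- length(memb) - q
      cc <- length(set) - q; d <- Nn - length(set) - b
      orat <- (a * d) / max(b * cc, .Machine$double.xmin)
      rows[[length(rows) + 1]] <- data.frame(module = m, set = sn, overlap = q,
                                             module_size = length(memb),
                                             set_size = length(set),
                                             odds_ratio = orat, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Full co-expression network stage
#'
#' bicor -> signed adjacency -> TOM -> average-linkage tree with dynamic cut
#' -> eigenprotein merge -> eigenproteins + kME, with defaults power = 6,
#' deep_split = 2, min_module_size = 10, merge_cut_height = 0.7.
#'
#' @param expr complete harmonized log2 matrix.
#' @param power,signed,deep_split,min_module_size,merge_cut_height network
#'   parameters.
#' @return list of class `module_assignment`: `labels`, `eigenproteins`,
#'   `var_explained`, `kme`, `params`.
#' @export
build_network <- function(expr, power = 6, signed = TRUE, deep_split = 2L,
                          min_module_size = 10L, merge_cut_height = 0.7) {
  cor <- bicor_matrix(expr)
  adj <- adjacency_matrix(cor, power = power, signed = signed)
  tom <- tom_similarity(adj)
  labels <- cluster_and_cut(1 - tom, min_module_size = min_module_size,
                            deep_split = deep_split)
  if (any(!is.na(labels)))
    labels <- merge_modules(expr, labels, merge_cut_height = merge_cut_height)
  eg <- if (any(!is.na(labels))) module_eigenproteins(expr, labels) else
    list(eigenproteins = NULL, var_explained = NULL)
  kme <- if (!is.null(eg$eigenproteins)) kme_table(expr, eg$eigenproteins) else NULL
  structure(list(labels = labels,
                 eigenproteins = eg$eigenproteins,
                 var_explained = eg$var_explained,
                 kme = kme,
                 params = list(power = power, signed = signed,
                               deep_split = deep_split,
                               min_module_size = min_module_size,
                               merge_cut_height = merge_cut_height)),
            class = "module_assignment")
}
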