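## Modularity-based subtyping of samples on a hub-protein similarity graph:
## top-kME hub selection, signed soft-thresholded sample graph sparsified to
## a target average degree, weighted Newman-Girvan modularity, seeded
## multilevel greedy community detection with min/max size constraints, a
## grid search scored by replicate-pair consistency, and per-sample
## hub-profile correlation diagnostics.

#' Select module hub proteins by kME
#'
#' Per module, the top `hubs_per_module` members ranked by own-module kME
#' (ties broken by protein ID); modules smaller than the quota contribute
#' all members.
#'
#' @param kme protein x module kME matrix.
#' @param labels protein module labels.
#' @param hubs_per_module hub quota per module (default 30).
#' @return data frame: protein, module, kme, ordered by module then rank.
#' @export
select_hubs <- function(kme, labels, hubs_per_module = 30L) {
  labels <- labels[rownames(kme)]
  mods <- unique(labels[!is.na(labels)])
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", mods)))
  mods <- mods[order(!is.na(num), num, mods)]
  out <- lapply(mods, function(m) {
    memb <- rownames(kme)[!is.na(labels) & labels == m]
    k <- kme[memb, m]
    ord <- order(-k, memb)
    take <- memb[ord][seq_len(min(hubs_per_module, length(memb)))]
    data.frame(protein = take, module = m, kme = kme[take, m],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Weighted sample-similarity graph from hub proteins
#'
#' Sample-sample biweight midcorrelation of hub profiles, transformed by the
#' signed soft threshold `((1 + cor) / 2)^power` (default power 13), then
#' sparsified by keeping the `ceiling(n * k / 2)` highest-weight edges so the
#' mean degree is about the requested `avg_degree`.
#'
#' @param hub_expr hub-protein x sample matrix (complete).
#' @param power soft power on the signed similarity (default 13).
#' @param avg_degree target mean degree k (< number of samples).
#' @return symmetric weighted adjacency matrix (0 = no edge, zero diagonal).
#' @export
sample_graph <- function(hub_expr, power = 13, avg_degree = 25) {
  check_expr(hub_expr, allow_na = FALSE)
  n <- ncol(hub_expr)
  if (avg_degree >= n) stopf("avg_degree (%s) must be < n samples (%d)",
                             avg_degree, n)
  cor <- bicor_matrix(t(hub_expr))
  w <- ((1 + cor) / 2)^power
  diag(w) <- 0
  n_edges <- ceiling(n * avg_degree / 2)
  ut <- which(upper.tri(w))
  ord <- ut[order(-w[ut])]
  keep <- ord[seq_len(min(n_edges, length(ord)))]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[keep] <- w[keep]
  out + t(out)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `e_c` the internal edge weight
#' of community c, `d_c` its total weighted degree and `m` the total edge
#' weight.  Unassigned nodes are not allowed (the partition must cover the
#' graph).
#'
#' @param graph symmetric weighted adjacency matrix (zero diagonal).
#' @param membership community label per node (no NAs).
#' @return numeric Q in \[-0.5, 1\].
#' @export
modularity_q <- function(graph, membership) {
  n <- nrow(graph)
  if (n == 0 || sum(graph) == 0) stopf("empty graph")
  if (length(membership) != n || anyNA(membership))
    stopf("membership must cover all nodes")
  m2 <- sum(graph)                    # = 2m
  d <- rowSums(graph)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(graph[idx, idx])       # = 2 * internal weight
    d_c <- sum(d[idx])
    q <- q + e_c / m2 - (d_c / m2)^2
  }
  q
}

#' Seeded multilevel greedy modularity maximization (one restart)
#' @noRd
louvain_once <- function(graph, seed) {
  set.seed(seed)
  n0 <- nrow(graph)
  node_groups <- as.list(seq_len(n0))   # original nodes per supernode
  W <- graph
  repeat {
    n <- nrow(W)
    comm <- seq_len(n)
    m2 <- sum(W)
    if (m2 == 0) break
    deg <- unname(rowSums(W))
    tot <- deg                          # degree sum per community id
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (v in sample.int(n)) {
        cv <- comm[v]
        wl <- W[v, ]
        nb <- which(wl > 0)
        nb <- nb[nb != v]               # self-loops stay internal
        lc <- if (length(nb)) tapply(wl[nb], comm[nb], sum) else numeric(0)
        cids <- as.integer(names(lc))
        lv <- as.numeric(lc)
        if (!cv %in% cids) { cids <- c(cids, cv); lv <- c(lv, 0) }
        tot[cv] <- tot[cv] - deg[v]
        gain <- lv - deg[v] * tot[cids] / m2
        best <- which.max(gain)
        own <- match(cv, cids)
        if (gain[best] > gain[own] + 1e-12 && cids[best] != cv) {
          comm[v] <- cids[best]
          moved <- TRUE; moved_any <- TRUE
        }
        tot[comm[v]] <- tot[comm[v]] + deg[v]
      }
      if (!moved) break
    }
    if (!moved_any) break
    ## aggregate
    uc <- sort(unique(comm))
    map <- match(comm, uc)
    k <- length(uc)
    agg <- matrix(0, k, k)
    for (i in seq_len(k)) {
      idx <- which(map == i)
      for (j in i:k) {
        jdx <- which(map == j)
        agg[i, j] <- agg[j, i] <- sum(W[idx, jdx, drop = FALSE])
      }
    }
    node_groups <- lapply(seq_len(k), function(i)
      unlist(node_groups[map == i], use.names = FALSE))
    W <- agg
    if (k == n) break
  }
  out <- integer(n0)
  for (i in seq_along(node_groups)) out[node_groups[[i]]] <- i
  out
}

#' @noRd
louvain_cluster <- function(graph, seed = 1L, n_restarts = 10L) {
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    memb <- louvain_once(graph, seed = seed + 7L * (r - 1L))
    q <- modularity_q(graph, memb)
    if (q > best_q + 1e-12) { best_q <- q; best <- memb }
  }
  best
}

#' Community detection with min/max size constraints
#'
#' Seeded multilevel greedy modularity maximization (multiple restarts, best
#' Q kept); communities larger than `max_size` are recursively re-clustered
#' on their induced subgraph; communities smaller than `min_size` are
#' dissolved and their members re-assigned to the neighboring community with
#' the greatest total edge weight, or left unassigned (NA) when isolated.
#'
#' @param graph symmetric weighted adjacency matrix.
#' @param min_size minimum community size i.
#' @param max_size maximum community size j.
#' @param seed integer seed (node-visit order).
#' @param n_restarts greedy restarts per level.
#' @return list: `membership` (S1.. by decreasing size, NA unassigned),
#'   `Q` (modularity of the assigned part).
#' @export
detect_communities <- function(graph, min_size = 15L, max_size = 200L,
                               seed = 1L, n_restarts = 10L) {
  n <- nrow(graph)
  if (n == 0) stopf("empty graph")
  memb <- louvain_cluster(graph, seed = seed, n_restarts = n_restarts)

  ## recursively split oversized communities
  next_id <- max(memb) + 1L
  repeat {
    sizes <- table(memb)
    big <- names(sizes)[sizes > max_size]
    if (!length(big)) break
    split_done <- FALSE
    for (b in big) {
      idx <- which(memb == as.integer(b))
      sub <- graph[idx, idx, drop = FALSE]
      if (sum(sub) == 0) next
      sm <- louvain_cluster(sub, seed = seed + 1L, n_restarts = n_restarts)
      if (length(unique(sm)) <= 1) next
      memb[idx] <- next_id + sm
      next_id <- next_id + max(sm) + 1L
      split_done <- TRUE
    }
    if (!split_done) break              # indivisible oversized community
  }

  ## dissolve undersized communities
  out <- as.integer(memb)
  repeat {
    sizes <- table(out)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    ## dissolve the smallest first for determinism
    b <- small[order(as.integer(sizes[small]), as.integer(small))][1]
    victims <- which(out == as.integer(b))
    out[victims] <- NA_integer_
    for (v in victims) {
      wl <- graph[v, ]
      wsum <- tapply(wl, out, sum)
      wsum <- wsum[!is.na(names(wsum)) & wsum > 0]
      if (length(wsum)) out[v] <- as.integer(names(wsum)[which.max(wsum)])
    }
  }
  labels <- relabel_by_size(ifelse(is.na(out), NA_character_, paste0("c", out)),
                            prefix = "S")
  names(labels) <- rownames(graph)
  q <- if (all(is.na(labels))) NA_real_ else {
    asn <- !is.na(labels)
    tryCatch(modularity_q(graph[asn, asn, drop = FALSE], labels[asn]),
             error = function(e) NA_real_)
  }
  list(membership = labels, Q = q)
}

#' Replicate-pair subtype consistency
#'
#' Rate at which same-subject sample pairs land in the same subtype; a pair
#' with an unassigned member counts as inconsistent.  Subjects of
#' inconsistent pairs are listed for exclusion from downstream statistics.
#'
#' @param membership sample subtype labels (named by sample ID).
#' @param subjects subject ID per sample (same order/names).
#' @return list: `rate` (NA when no pairs), `n_pairs`,
#'   `inconsistent_subjects`.
#' @export
replicate_consistency <- function(membership, subjects) {
  df <- split(seq_along(subjects), subjects)
  pairs <- df[lengths(df) >= 2]
  if (!length(pairs))
    return(list(rate = NA_real_, n_pairs = 0L,
                inconsistent_subjects = character(0)))
  ok <- vapply(pairs, function(idx) {
    labs <- membership[idx]
    !anyNA(labs) && length(unique(labs)) == 1
  }, logical(1))
  list(rate = mean(ok), n_pairs = length(pairs),
       inconsistent_subjects = names(pairs)[!ok])
}

#' Per-sample correlation with its subtype's mean hub profile
#'
#' Pearson correlation of each sample's hub-protein profile with the
#' leave-self-out mean profile of its assigned subtype; low values flag
#' peripheral ("non-hub") samples.  Singletons and unassigned samples get
#' NA.
#'
#' @param hub_expr hub-protein x sample matrix.
#' @param membership sample subtype labels.
#' @return named numeric vector per sample.
#' @export
hub_correlation <- function(hub_expr, membership) {
  out <- stats::setNames(rep(NA_real_, ncol(hub_expr)), colnames(hub_expr))
  for (s in unique(membership[!is.na(membership)])) {
    idx <- which(!is.na(membership) & membership == s)
    if (length(idx) < 2) next
    tot <- rowSums(hub_expr[, idx, drop = FALSE])
    for (i in idx) {
      mean_other <- (tot - hub_expr[, i]) / (length(idx) - 1)
      out[i] <- stats::cor(hub_expr[, i], mean_other)
    }
  }
  out
}

#' Grid search over community-detection parameters
#'
#' Runs [sample_graph()] + [detect_communities()] for every (min size i,
#' max size j, average degree k) cell of the grid, scores each cell by
#' replicate-pair consistency (primary), modularity Q (tie-break) under the
#' constraint that the community count falls in `count_range`, and returns
#' the winning partition with the full score table.  Without replicate
#' pairs, Q alone ranks the cells.
#'
#' @param hub_expr hub-protein x sample matrix.
#' @param subjects subject ID per sample (replicate pairing).
#' @param grid_i,grid_j,grid_k parameter grids (defaults: i in 10/15/20/25,
#'   j in 100..400 by 50, k in 25/50).
#' @param power soft power of the sample graph (default 13).
#' @param count_range admissible community counts (default 2..12).
#' @param seed integer seed.
#' @return list of class `subtype_partition`: `membership`, `Q`, `params`,
#'   `consistency`, `excluded_pairs`, `hub_correlation`, `score_table`.
#' @export
grid_search_subtypes <- function(hub_expr, subjects,
                                 grid_i = c(10L, 15L, 20L, 25L),
                                 grid_j = seq(100L, 400L, 50L),
                                 grid_k = c(25L, 50L),
                                 power = 13, count_range = c(2L, 12L),
                                 seed = 1L) {
  if (!length(grid_i) || !length(grid_j) || !length(grid_k))
    stopf("empty grid")
  n <- ncol(hub_expr)
  cells <- expand.grid(i = grid_i, j = grid_j, k = grid_k)
  cells <- cells[cells$i < cells$j & cells$k < n, , drop = FALSE]
  if (!nrow(cells)) stopf("no admissible grid cells for n = %d samples", n)

  graphs <- lapply(unique(cells$k), function(k)
    sample_graph(hub_expr, power = power, avg_degree = k))
  names(graphs) <- as.character(unique(cells$k))

  score <- cells
  score$n_communities <- NA_integer_
  score$Q <- NA_real_
  score$consistency <- NA_real_
  parts <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    det <- detect_communities(graphs[[as.character(cells$k[r])]],
                              min_size = cells$i[r], max_size = cells$j[r],
                              seed = seed)
    parts[[r]] <- det
    score$n_communities[r] <- length(unique(det$membership[!is.na(det$membership)]))
    score$Q[r] <- det$Q
    score$consistency[r] <- replicate_consistency(det$membership, subjects)$rate
  }

  ok <- score$n_communities >= count_range[1] & score$n_communities <= count_range[2]
  if (!any(ok)) {
    print(score)
    stopf("every grid cell violates the community-count constraint [%d, %d]",
          count_range[1], count_range[2])
  }
  cons <- ifelse(is.na(score$consistency), -Inf, score$consistency)
  cons[!ok] <- -Inf
  qv <- ifelse(ok, score$Q, -Inf)
  win <- order(-cons, -qv)[1]

  det <- parts[[win]]
  rc <- replicate_consistency(det$membership, subjects)
  structure(list(membership = det$membership,
                 Q = det$Q,
                 params = as.list(cells[win, c("i", "j", "k")]),
                 consistency = rc$rate,
                 n_pairs = rc$n_pairs,
                 excluded_pairs = rc$inconsistent_subjects,
                 hub_correlation = hub_correlation(hub_expr, det$membership),
                 score_table = score),
            class = "subtype_partition")
}
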