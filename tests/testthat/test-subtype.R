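test_that("select_hubs takes the top kME members per module", {
  net <- fixture_network()
  hubs <- select_hubs(net$kme, net$labels, hubs_per_module = 30)
  quota <- sum(pmin(table(net$labels), 30))
  expect_identical(nrow(hubs), as.integer(quota))
  ## ten modules that all hold >= 30 members yield exactly 300 hubs
  big_lab <- stats::setNames(rep(paste0("M", 1:10), each = 35),
                             sprintf("h%03d|x", 1:350))
  big_kme <- matrix(stats::runif(350 * 10), 350, 10,
                    dimnames = list(names(big_lab), paste0("M", 1:10)))
  expect_identical(nrow(select_hubs(big_kme, big_lab, 30)), 300L)
  ## a small module contributes all members
  lab5 <- stats::setNames(c(rep("M1", 5), rep("M2", 40)), rownames(net$kme)[1:45])
  h2 <- select_hubs(net$kme[1:45, ], lab5, hubs_per_module = 30)
  expect_identical(sum(h2$module == "M1"), 5L)
  expect_identical(sum(h2$module == "M2"), 30L)
  ## hubs are planted members of their module
  coh <- fixture_cohort()
  agree <- mean(coh$truth_modules[hubs$protein] == hubs$module)
  expect_gte(agree, 0.9)
})

test_that("sample_graph sparsifies to the requested edge count", {
  harm <- fixture_harmonized()[1:60, 1:100]
  g <- sample_graph(harm, power = 13, avg_degree = 25)
  expect_identical(sum(g > 0) / 2, ceiling(100 * 25 / 2))   # 1250 edges
  expect_true(isSymmetric(g))
  expect_equal(unname(diag(g)), rep(0, 100))
  ## duplicated samples have the maximal weight, so their edge survives
  dup <- cbind(harm, dup = harm[, 1])
  colnames(dup)[ncol(dup)] <- "dup.1"
  g2 <- sample_graph(dup, power = 13, avg_degree = 10)
  expect_gt(g2[colnames(harm)[1], "dup.1"], 0)
  expect_equal(g2[colnames(harm)[1], "dup.1"], 1, tolerance = 1e-9)
  expect_error(sample_graph(harm, avg_degree = 100), "must be <")
  ## closed form: cor 0 pair at power 13 weighs 2^-13
  expect_equal(((1 + 0) / 2)^13, 2^-13)
})

test_that("modularity matches closed forms and exhaustive enumeration", {
  ## single community: Q = 0
  g <- matrix(1, 4, 4) - diag(4)
  expect_equal(modularity_q(g, rep(1, 4)), 0, tolerance = 1e-12)
  ## two disconnected equal cliques: Q = 0.5
  cl <- matrix(0, 8, 8)
  cl[1:4, 1:4] <- 1; cl[5:8, 5:8] <- 1
  diag(cl) <- 0
  expect_equal(modularity_q(cl, rep(1:2, each = 4)), 0.5, tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 2, 2), c(1, 2)), "empty")
  ## random weighted graphs: agree with igraph's implementation
  skip_if_not_installed("igraph")
  for (sd in 1:10) {
    w <- random_graph(6, sd)
    part <- sample(1:3, 6, replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity_q(w, part),
                 igraph::modularity(ig, part, weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("detect_communities finds planted structure and obeys size bounds", {
  ## two disconnected cliques of 20: exact 2-block partition, Q = 0.5
  g <- matrix(0, 40, 40)
  g[1:20, 1:20] <- 1; g[21:40, 21:40] <- 1
  diag(g) <- 0
  dimnames(g) <- list(paste0("s", 1:40), paste0("s", 1:40))
  det <- detect_communities(g, min_size = 10, max_size = 200, seed = 1)
  expect_identical(length(unique(det$membership)), 2L)
  expect_equal(det$Q, 0.5, tolerance = 1e-12)
  expect_identical(unname(table(det$membership)), c(20L, 20L), ignore_attr = TRUE)
  ## min-size dissolution: a 3-node appendage joins its neighbor community
  g2 <- g
  g2[1, 21] <- g2[21, 1] <- 0.01       # weak bridge so the graph is connected
  det2 <- detect_communities(g2, min_size = 25, max_size = 200, seed = 1)
  expect_lte(length(unique(stats::na.omit(det2$membership))), 2L)
  ## max-size splitting: a merged pair of cliques larger than j is
  ## re-clustered into its constituent cliques
  g4 <- matrix(0, 40, 40)
  for (b in 0:3) g4[b * 10 + 1:10, b * 10 + 1:10] <- 1
  g4[1:10, 11:20] <- g4[11:20, 1:10] <- 0.9     # pair (1,2)
  g4[21:30, 31:40] <- g4[31:40, 21:30] <- 0.9   # pair (3,4)
  diag(g4) <- 0
  dimnames(g4) <- list(paste0("t", 1:40), paste0("t", 1:40))
  coarse <- detect_communities(g4, min_size = 5, max_size = 200, seed = 1)
  expect_identical(length(unique(coarse$membership)), 2L)
  det3 <- detect_communities(g4, min_size = 5, max_size = 15, seed = 1)
  expect_identical(length(unique(stats::na.omit(det3$membership))), 4L)
})

test_that("detect_communities attains the exhaustive optimum on small graphs", {
  parts <- lapply(4:7, all_partitions)
  names(parts) <- as.character(4:7)
  hits <- 0; total <- 40
  for (sd in 1:total) {
    n <- 4 + (sd %% 4)
    w <- random_graph(n, sd + 500)
    if (sum(w) == 0) { hits <- hits + 1; next }
    best <- brute_force_modularity(w, parts[[as.character(n)]])
    det <- detect_communities(w, min_size = 1, max_size = n, seed = sd)
    expect_false(anyNA(det$membership))
    if (det$Q >= best - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("replicate_consistency counts pairs and names inconsistent subjects", {
  memb <- c(a1 = "S1", a2 = "S1", b1 = "S1", b2 = "S2", c1 = "S3")
  subj <- c("a", "a", "b", "b", "c")
  rc <- replicate_consistency(memb, subj)
  expect_equal(rc$rate, 0.5)
  expect_identical(rc$n_pairs, 2L)
  expect_identical(rc$inconsistent_subjects, "b")
  ## no pairs: flagged undefined
  rc0 <- replicate_consistency(memb[c(1, 3, 5)], c("a", "b", "c"))
  expect_true(is.na(rc0$rate))
  ## duplicated columns assigned together give rate 1
  rc1 <- replicate_consistency(c(x1 = "S1", x2 = "S1"), c("x", "x"))
  expect_equal(rc1$rate, 1)
})

test_that("hub_correlation is high for cohesive members, NA for singletons", {
  set.seed(9)
  base <- matrix(rnorm(50 * 3), 50, 3)
  expr <- cbind(base[, rep(1, 4)] + matrix(rnorm(200, sd = 0.1), 50),
                base[, rep(2, 4)] + matrix(rnorm(200, sd = 0.1), 50),
                base[, 3])
  colnames(expr) <- paste0("s", 1:9)
  rownames(expr) <- paste0("p", 1:50)
  memb <- stats::setNames(c(rep("S1", 4), rep("S2", 4), "S3"), colnames(expr))
  hc <- hub_correlation(expr, memb)
  expect_true(all(hc[1:8] > 0.9))
  expect_true(is.na(hc[9]))              # singleton subtype
  ## an orthogonal sample shows ~0 correlation with its cluster mean
  expr2 <- expr
  expr2[, 4] <- rnorm(50)
  hc2 <- hub_correlation(expr2, memb)
  expect_lt(abs(hc2[4]), 0.35)
})

test_that("grid search returns the consistency-then-Q winner with audit table", {
  coh <- fixture_cohort()
  harm <- fixture_harmonized()
  net <- fixture_network()
  hubs <- select_hubs(net$kme, net$labels, 30)
  hub_expr <- harm[hubs$protein, ]
  subjects <- coh$traits$subject_id[match(colnames(hub_expr),
                                          coh$traits$sample_id)]
  part <- grid_search_subtypes(hub_expr, subjects,
                               grid_i = c(10L, 15L), grid_j = c(100L, 200L),
                               grid_k = c(25L), seed = 1)
  expect_s3_class(part, "subtype_partition")
  expect_identical(nrow(part$score_table), 4L)
  ok <- part$score_table$n_communities >= 2 & part$score_table$n_communities <= 12
  cons <- ifelse(is.na(part$score_table$consistency), -Inf,
                 part$score_table$consistency)
  expect_equal(part$consistency, max(cons[ok]))   # argmax property
  ## single-cell grid returns that cell
  part1 <- grid_search_subtypes(hub_expr, subjects, grid_i = 15L,
                                grid_j = 200L, grid_k = 25L, seed = 1)
  expect_identical(unlist(part1$params), c(i = 15L, j = 200L, k = 25L))
  ## labels are size-ordered
  tab <- table(part$membership)
  expect_identical(names(tab)[which.max(tab)], "S1")
})

test_that("planted subtypes are recovered end to end with consistent replicates", {
  spec <- mid_spec(seed = 77, n_samples = 300)
  coh <- generate_cohort(spec)
  tr <- coh$traits
  harm0 <- impute_knn(filter_missingness(coh$expression[, !tr$is_gis], 0.5))
  eg <- module_eigenproteins(harm0, coh$truth_modules[rownames(harm0)])
  kme <- kme_table(harm0, eg$eigenproteins)
  hubs <- select_hubs(kme, coh$truth_modules[rownames(harm0)], 30)
  g <- sample_graph(harm0[hubs$protein, ], 13, 25)
  det <- detect_communities(g, 15, 200, seed = 1)
  truth <- coh$truth_subtypes[colnames(harm0)]
  expect_gte(adjusted_rand_index(det$membership, truth), 0.9)
  subjects <- tr$subject_id[match(colnames(harm0), tr$sample_id)]
  rc <- replicate_consistency(det$membership, subjects)
  expect_gte(rc$rate, 0.85)
  ## inconsistent subjects sit less centrally than consistent ones
  hc <- hub_correlation(harm0[hubs$protein, ], det$membership)
  if (length(rc$inconsistent_subjects)) {
    bad <- subjects %in% rc$inconsistent_subjects
    expect_lt(mean(hc[bad], na.rm = TRUE), mean(hc[!bad], na.rm = TRUE))
  }
})
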