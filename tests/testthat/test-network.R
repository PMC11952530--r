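test_that("bicor matches its defining cases and tracks Pearson on clean data", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  ## Gaussian data without outliers: |bicor - Pearson| < 0.05 elementwise
  m <- matrix(rnorm(20 * 200), 20, 200,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:200)))
  b <- bicor_matrix(m)
  p <- stats::cor(t(m))
  expect_lt(max(abs(b - p)), 0.05)
  ## robustness: one gross outlier barely moves bicor, but moves Pearson
  x2 <- rnorm(60); y2 <- x2 + rnorm(60, sd = 0.3)
  r0 <- bicor(x2, y2)
  x2o <- x2; x2o[1] <- 50
  expect_lt(abs(bicor(x2o, y2) - r0), 0.1)
  ## constant row falls back with a warning
  mm <- rbind(a = x2, b = rep(1, 60))
  colnames(mm) <- paste0("s", 1:60)
  expect_warning(bicor_matrix(mm), "fallback")
})

test_that("signed adjacency follows ((1+cor)/2)^beta", {
  cor <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  a <- adjacency_matrix(cor, power = 6, signed = TRUE)
  expect_equal(a[1, 2], 0.5^6)           # cor 0 -> (1/2)^6 = 0.015625
  expect_equal(a[1, 2], 0.015625)
  expect_equal(a[1, 3], 0)               # cor -1 -> 0
  expect_equal(diag(a), rep(1, 3))
  au <- adjacency_matrix(cor, power = 6, signed = FALSE)
  expect_equal(au[1, 3], 1)              # |cor| = 1
  expect_error(adjacency_matrix(cor, power = 0.5), ">= 1")
})

test_that("tom equals the brute-force triple loop", {
  brute_tom <- function(a) {
    d <- a; diag(d) <- 0
    k <- rowSums(d)
    n <- nrow(a)
    out <- diag(n)
    for (i in 1:n) for (j in 1:n) if (i != j) {
      l <- sum(d[i, -c(i, j)] * d[-c(i, j), j])
      out[i, j] <- (l + d[i, j]) / (min(k[i], k[j]) + 1 - d[i, j])
    }
    out
  }
  for (sd in 1:5) {
    set.seed(sd)
    n <- sample(5:20, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_lt(max(abs(tom_similarity(a) - brute_tom(a))), 1e-12)
  }
  ## clique: identical neighborhoods give overlap 1; disjoint pair gives 0
  cl <- matrix(1, 5, 5)
  expect_equal(tom_similarity(cl), matrix(1, 5, 5))
  two <- diag(2)
  expect_equal(tom_similarity(two)[1, 2], 0)
})

test_that("cluster_and_cut separates planted blocks and refuses no-structure", {
  ids <- sprintf("p%03d", 1:100)
  d <- matrix(0.9, 100, 100, dimnames = list(ids, ids))
  d[1:50, 1:50] <- 0.1; d[51:100, 51:100] <- 0.1
  diag(d) <- 0
  lab <- cluster_and_cut(d, min_module_size = 10, deep_split = 2)
  expect_identical(sort(unique(lab)), c("M1", "M2"))
  expect_identical(unname(table(lab)[c("M1", "M2")]), c(50L, 50L),
                   ignore_attr = TRUE)
  ## equal dissimilarities: nothing to cut
  flat <- matrix(0.5, 40, 40, dimnames = list(ids[1:40], ids[1:40]))
  diag(flat) <- 0
  expect_true(all(is.na(cluster_and_cut(flat))))
  ## fewer proteins than the minimum size: warn, all unassigned
  expect_warning(out <- cluster_and_cut(d[1:5, 1:5], min_module_size = 10),
                 "unassigned")
  expect_true(all(is.na(out)))
})

test_that("eigenproteins: single protein, identical proteins, factor recovery", {
  harm <- fixture_harmonized()
  coh <- fixture_cohort()
  one <- harm[1, , drop = FALSE]
  eg1 <- module_eigenproteins(one, stats::setNames("M1", rownames(one)))
  z <- as.numeric(scale(harm[1, ]))
  expect_equal(abs(stats::cor(eg1$eigenproteins["M1", ], z)), 1, tolerance = 1e-12)
  ## p identical proteins: variance explained = 1
  dup <- harm[rep(1, 5), ]
  rownames(dup) <- paste0("d", 1:5, "|x")
  egd <- module_eigenproteins(dup, stats::setNames(rep("M1", 5), rownames(dup)))
  expect_equal(unname(egd$var_explained["M1"]), 1, tolerance = 1e-9)
  ## planted factor recovery on the synthetic cohort
  eg <- module_eigenproteins(harm, coh$truth_modules[rownames(harm)])
  f <- coh$truth_factors
  shared <- intersect(colnames(eg$eigenproteins), rownames(f))
  for (m in c("M1", "M2")) {          # subtype-structured modules
    r <- stats::cor(eg$eigenproteins[m, shared], f[shared, m])
    expect_gt(abs(r), 0.9)
  }
  r5 <- stats::cor(eg$eigenproteins["M5", shared], f[shared, "M5"])
  expect_gt(abs(r5), 0.8)              # subtype-neutral module, noisier
  ## sign convention: mean own-module kME positive
  kme <- kme_table(harm, eg$eigenproteins)
  for (m in rownames(eg$eigenproteins)) {
    memb <- names(which(coh$truth_modules[rownames(harm)] == m))
    expect_gt(mean(kme[memb, m]), 0)
  }
})

test_that("merge_modules merges below the cut height and is label-invariant", {
  harm <- fixture_harmonized()
  coh <- fixture_cohort()
  labels <- coh$truth_modules[rownames(harm)]
  ## split M1 artificially in half: the two halves share one factor, so
  ## their eigenprotein correlation is ~1 and they must re-merge
  m1 <- names(which(labels == "M1"))
  split_lab <- labels
  split_lab[m1[seq(1, length(m1), 2)]] <- "M1a"
  split_lab[m1[seq(2, length(m1), 2)]] <- "M1b"
  merged <- merge_modules(harm, split_lab, merge_cut_height = 0.7)
  m1a_new <- unique(merged[m1])
  expect_length(m1a_new, 1L)
  ## distinct factors (cor well below 1 - 0.7) stay separate
  expect_gt(length(unique(merged[!is.na(merged)])), 5)
  ## permutation of module labels yields the identical final partition
  perm <- split_lab
  map <- c(M2 = "Mx9", M3 = "Mx1")
  perm[perm %in% names(map)] <- map[perm[perm %in% names(map)]]
  merged_perm <- merge_modules(harm, perm, merge_cut_height = 0.7)
  expect_identical(merged, merged_perm)
})

test_that("kme is bounded and separates members from non-members", {
  harm <- fixture_harmonized()
  coh <- fixture_cohort()
  labels <- coh$truth_modules[rownames(harm)]
  eg <- module_eigenproteins(harm, labels)
  kme <- kme_table(harm, eg$eigenproteins)
  expect_true(all(kme >= -1 & kme <= 1))
  ## planted members' own-module kME beats non-members' in >= 95% of cases
  hits <- unlist(lapply(rownames(eg$eigenproteins), function(m) {
    memb <- !is.na(labels) & labels == m
    kme[memb, m] > stats::quantile(kme[!memb, m], 0.95)
  }))
  expect_gt(mean(hits), 0.9)
})

test_that("module-trait correlation recovers planted signs", {
  harm <- fixture_harmonized()
  coh <- fixture_cohort()
  eg <- module_eigenproteins(harm, coh$truth_modules[rownames(harm)])
  et <- encode_traits(coh$traits)
  tr_all <- cbind(coh$traits[match(rownames(et), coh$traits$sample_id),
                             c("sample_id", "subject_id", "set")], et)
  rownames(tr_all) <- tr_all$sample_id
  tab <- module_trait_correlation(eg$eigenproteins, tr_all,
                                  trait_cols = c("sex", "race", "diagnosis"))
  get <- function(m, t) tab$bicor[tab$module == m & tab$trait == t]
  expect_gt(get("M1", "sex"), 0)        # planted +
  expect_gt(get("M1", "race"), 0)       # planted +
  expect_gt(get("M2", "diagnosis"), 0)  # planted +
  expect_lt(get("M2", "sex"), 0)        # planted -
  expect_lt(get("M2", "race"), 0)       # planted -
  ## a trait equal to an eigenprotein correlates perfectly
  tr_all$self <- eg$eigenproteins["M1", tr_all$sample_id]
  tab2 <- module_trait_correlation(eg$eigenproteins, tr_all, trait_cols = "self",
                                   replicate_policy = "all")
  expect_equal(tab2$bicor[tab2$module == "M1"], 1, tolerance = 1e-9)
  expect_lt(tab2$p[tab2$module == "M1"], 1e-10)
  ## replicate policy: first_set_only drops the set-2 twin
  n_first <- tab$n[1]
  tab_all <- module_trait_correlation(eg$eigenproteins, tr_all,
                                      trait_cols = "sex", replicate_policy = "all")
  expect_gt(tab_all$n[1], n_first)
})

test_that("marker enrichment equals the hypergeometric tail", {
  labels <- stats::setNames(c(rep("M1", 10), rep("M2", 20), rep(NA, 70)),
                            sprintf("p%03d", 1:100))
  sets <- list(hit = names(labels)[1:10], none = sprintf("q%03d", 1:5))
  res <- marker_enrichment(labels, sets, background = names(labels))
  hit <- res[res$module == "M1" & res$set == "hit", ]
  ## enumeration oracle: P(overlap >= 10) drawing 10 of 100 with 10 marked
  expect_equal(hit$p, 1 / choose(100, 10), tolerance = 1e-9)
  expect_lt(hit$p, 1e-6)
  miss <- res[res$module == "M2" & res$set == "hit", ]
  expect_equal(miss$p, 1, tolerance = 1e-12)
  expect_true(all(is.na(res$p[res$set == "none"])))
  ## 2x2 (5,5,5,85) oracle: upper-tail hypergeometric sum, cross-checked
  ## against the one-sided Fisher test
  lab2 <- stats::setNames(c(rep("M1", 10), rep(NA, 90)), sprintf("p%03d", 1:100))
  set2 <- list(s = names(lab2)[c(1:5, 11:15)])
  r2 <- marker_enrichment(lab2, set2)
  fisher <- stats::fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(r2$p, fisher$p.value, tolerance = 1e-9)
})

test_that("full network stage recovers the planted modules", {
  net <- fixture_network()
  coh <- fixture_cohort()
  n_mod <- length(unique(net$labels[!is.na(net$labels)]))
  expect_gte(n_mod, 8); expect_lte(n_mod, 12)
  expect_gte(adjusted_rand_index(net$labels, coh$truth_modules[names(net$labels)]),
             0.8)
  ## M1 is the largest module
  expect_identical(names(which.max(table(net$labels))), "M1")
  ## eigenprotein rows are unit variance
  expect_equal(apply(net$eigenproteins, 1, stats::sd),
               rep(1, nrow(net$eigenproteins)), tolerance = 1e-9,
               ignore_attr = TRUE)
})
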