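## TAMPOR oracle helper: direct two-way median polish on a tiny matrix,
## written independently of the package implementation.
hand_median_polish <- function(log2_mat, batch, centers, n_iter = 50) {
  R <- 2^log2_mat
  for (it in seq_len(n_iter)) {
    for (b in unique(batch)) {
      cols <- which(batch == b)
      ctr <- intersect(cols, centers)
      med <- apply(R[, ctr, drop = FALSE], 1, median)
      R[, cols] <- R[, cols, drop = FALSE] / med
    }
    R <- sweep(R, 2, apply(R, 2, median), "/")
  }
  log2(R)
}

test_that("tampor is a fixed point on an already-centered matrix", {
  ## 2 batches x 2 samples each (one GIS per batch); rows centered so the
  ## GIS entries are 0 and every sample median is 0
  m <- rbind(c(0, 1, 0, -2),
             c(0, -1, 0, 2),
             c(0, 0, 0, 0))
  dimnames(m) <- list(paste0("p", 1:3), paste0("s", 1:4))
  batch <- c("b1", "b1", "b2", "b2")
  is_gis <- c(TRUE, FALSE, TRUE, FALSE)
  r <- tampor(m, batch, "GIS", is_gis = is_gis)
  expect_equal(r$harmonized, m, tolerance = 1e-12)
  expect_identical(r$iterations, 1L)
  expect_true(r$converged)
})

test_that("tampor removes a planted batch offset exactly (hand oracle)", {
  set.seed(1)
  base <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  batch <- c("b1", "b1", "b2", "b2")
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 1   # +1 log2 on batch 2
  is_gis <- c(TRUE, FALSE, TRUE, FALSE)
  r <- tampor(shifted, batch, "GIS", is_gis = is_gis)
  oracle <- hand_median_polish(shifted, batch, centers = which(is_gis))
  expect_equal(r$harmonized, oracle, tolerance = 1e-9)
  ## the two batches agree after polish: GIS columns are zeroed
  expect_equal(unname(r$harmonized[, 1]), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(r$harmonized[, 3]), c(0, 0, 0), tolerance = 1e-9)
  ## batch offset gone: non-GIS columns equal the base contrast
  expect_equal(r$harmonized[, 2] - r$harmonized[, 4],
               oracle[, 2] - oracle[, 4], tolerance = 1e-12)
})

test_that("tampor errors are informative", {
  m <- matrix(0, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_error(tampor(m, c("b1", "b2"), "GIS", is_gis = c(TRUE, FALSE)),
               "batch 'b2' has no center")
  m2 <- m; m2[1, ] <- NA
  expect_error(tampor(m2, c("b1", "b1"), "GIS", is_gis = c(TRUE, TRUE)),
               "all-missing")
})

test_that("tampor converges fast and is idempotent on random matrices", {
  for (sd in 1:20) {
    set.seed(sd)
    m <- matrix(rnorm(200 * 60, sd = 1), 200, 60,
                dimnames = list(sprintf("p%03d", 1:200), sprintf("s%02d", 1:60)))
    batch <- rep(paste0("b", 1:6), each = 10)
    is_gis <- rep(c(TRUE, rep(FALSE, 9)), 6)
    r <- tampor(m, batch, "GIS", is_gis = is_gis)
    expect_true(r$converged)
    expect_lte(r$iterations, 250L)
    r2 <- tampor(r$harmonized, batch, "GIS", is_gis = is_gis)
    expect_lt(max(abs(r2$harmonized - r$harmonized)), 1e-6)
  }
})

test_that("two-round harmonization shrinks set variance and replicate distance", {
  coh <- fixture_cohort()
  tr <- coh$traits
  expr <- filter_missingness(coh$expression, 0.5)
  refs <- tr$sample_id[!tr$is_gis & tr$diagnosis == "Control" & tr$race == "NHW"]
  hr <- two_round_harmonize(expr, tr, refs)
  expect_true(hr$converged)
  harm <- impute_knn(hr$harmonized)
  cov <- tr[match(colnames(harm), tr$sample_id),
            c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
  out <- regress_batch(harm, cov, n_boot = 50, seed = 1)
  ## unique set contribution (net of biology): set ordered last
  ve <- variance_explained(out, cov,
                           factors = c("age", "sex", "race", "diagnosis",
                                       "batch", "set"))
  expect_lt(stats::median(ve$set), 0.01)
  ## replicate pairs move closer together than in the raw data
  pair_dist <- function(m) {
    bio <- tr[match(colnames(m), tr$sample_id), ]
    dup <- names(which(table(bio$subject_id) == 2))
    vapply(dup, function(s) {
      ids <- bio$sample_id[bio$subject_id == s]
      sqrt(mean((m[, ids[1]] - m[, ids[2]])^2))
    }, numeric(1))
  }
  raw <- impute_knn(filter_missingness(coh$expression[, !tr$is_gis], 0.5))
  expect_lt(stats::median(pair_dist(harm)), stats::median(pair_dist(raw)))
  ## reference group missing from a set is an error
  s1_only <- tr$sample_id[!tr$is_gis & tr$set == 1][1]
  expect_error(two_round_harmonize(expr, tr, s1_only), "no sample in set")
  expect_error(two_round_harmonize(expr, tr, character(0)), "empty")
})

test_that("regress_batch: identity, OLS equivalence, parameter recovery", {
  harm <- fixture_harmonized()[1:50, ]
  coh <- fixture_cohort()
  cov <- coh$traits[match(colnames(harm), coh$traits$sample_id),
                    c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
  expect_identical(regress_batch(harm, cov, remove = character(0)), harm)
  ## full-sample switch equals plain OLS removal
  ols <- regress_batch(harm, cov, n_boot = 1, full_sample = TRUE)
  X <- stats::model.matrix(~ factor(batch) + age + sex + race + diagnosis, cov)
  fit <- stats::lm.fit(X, t(harm))
  bcols <- grep("batch", colnames(X))
  manual <- harm - t(X[, bcols, drop = FALSE] %*% fit$coefficients[bcols, ])
  expect_equal(ols, manual, tolerance = 1e-8, ignore_attr = TRUE)
  ## protected covariate confounded with a removed factor errors
  cov2 <- cov; cov2$diagnosis <- cov2$set
  expect_error(regress_batch(harm, cov2, remove = "set",
                             protect = c("age", "diagnosis")),
               "confounded")
})

test_that("planted sex effect survives regression while batch variance dies", {
  ## parameter recovery: proteins in module 1 carry a planted sex effect.
  ## Each seed's estimate carries a common design-realization error shared by
  ## all M1 proteins (one batch/sex randomization), so preservation is
  ## asserted on the across-seed mean of the recovery ratio.
  ratios <- c()
  for (sd in c(1, 2, 3, 4)) {
    spec <- mid_spec(seed = sd)
    coh <- generate_cohort(spec)
    tr <- coh$traits
    expr <- filter_missingness(coh$expression, 0.5)
    refs <- tr$sample_id[!tr$is_gis & tr$diagnosis == "Control" & tr$race == "NHW"]
    harm <- impute_knn(two_round_harmonize(expr, tr, refs)$harmonized)
    cov <- tr[match(colnames(harm), tr$sample_id),
              c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
    out <- regress_batch(harm, cov, n_boot = 50, seed = sd)
    ## unique batch contribution (ordered after the biology it may alias)
    ve <- variance_explained(out, cov,
                             factors = c("set", "age", "sex", "race",
                                         "diagnosis", "batch"))
    expect_lt(stats::median(ve$batch), 0.01)
    ## protected sex effect on M1 proteins, compared against the same
    ## estimate on the median-normalized ideal matrix (the identifiable
    ## target: column median normalization is part of the pipeline contract)
    m1 <- intersect(names(which(coh$truth_modules == "M1")), rownames(out))
    est_on <- function(mat) {
      cols <- intersect(colnames(mat), colnames(coh$ideal))
      sexn <- as.numeric(tr$sex[match(cols, tr$sample_id)] == "M")
      dxn <- as.numeric(tr$diagnosis[match(cols, tr$sample_id)] == "AD")
      rcn <- as.numeric(tr$race[match(cols, tr$sample_id)] == "AA")
      stats::median(vapply(m1, function(p)
        stats::coef(stats::lm(mat[p, cols] ~ sexn + dxn + rcn))[["sexn"]],
        numeric(1)))
    }
    ratios <- c(ratios, est_on(out) / est_on(column_median_normalize(coh$ideal)))
  }
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("filter_missingness applies the >= 50% boundary inclusively", {
  m <- matrix(NA_real_, 6, 10,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:10)))
  obs <- c(10, 9, 5, 4, 1, 0)
  for (i in 1:6) if (obs[i] > 0) m[i, seq_len(obs[i])] <- 1
  kept <- filter_missingness(m, 0.5)
  expect_identical(rownames(kept), c("p1", "p2", "p3"))   # exactly 50% kept
})

test_that("impute_knn: identity, exact twin, beats row-median recovery", {
  m <- fixture_harmonized()[1:80, 1:60]
  expect_identical(impute_knn(m), m)
  ## duplicated protein with one masked cell recovers its twin's value
  twin <- rbind(m, twin = m[3, ])
  rownames(twin)[nrow(twin)] <- "twin|X"
  twin["twin|X", 5] <- NA
  out <- impute_knn(twin, k = 1)
  expect_equal(out["twin|X", 5], m[3, 5], tolerance = 1e-12)
  ## mask-and-recover: knn beats the naive row median
  set.seed(4)
  mask <- cbind(sample(nrow(m), 120, TRUE), sample(ncol(m), 120, TRUE))
  mask <- mask[!duplicated(mask), ]
  masked <- m; masked[mask] <- NA
  knn <- impute_knn(masked, k = 10)
  med <- masked
  for (i in unique(mask[, 1]))
    med[i, is.na(masked[i, ])] <- stats::median(masked[i, ], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[mask] - m[mask])^2))
  expect_lt(rmse(knn), rmse(med))
})

test_that("zscore_by_set matches the textbook values and scale invariance", {
  tr <- data.frame(set = c(1, 1, 1), ttau = c(1, 2, 3), ptau = 1:3, abeta = 1:3)
  z <- zscore_by_set(tr)
  expect_equal(z$ttau_z, c(-1, 0, 1))
  tr2 <- data.frame(set = rep(1:2, each = 3),
                    ttau = c(1, 2, 3, 100, 200, 300),
                    ptau = rep(1:3, 2), abeta = rep(1:3, 2))
  z2 <- zscore_by_set(tr2)
  expect_equal(z2$ttau_z[1:3], z2$ttau_z[4:6])
  tr3 <- data.frame(set = 1, ttau = c(1, 1), ptau = c(1, 2), abeta = c(1, 2))
  expect_error(zscore_by_set(tr3), "zero variance")
})

test_that("qc_exclude applies the 0.226 ratio rule with an inclusive boundary", {
  tr <- data.frame(sample_id = paste0("s", 1:6),
                   diagnosis = c("AD", "AD", "AD", "Control", "Control", "AD"),
                   ttau = c(0.30, 0.226, 0.10, 0.10, 0.30, 0.2259999),
                   abeta = 1,
                   is_gis = FALSE)
  qc <- qc_exclude(tr, ratio_cutoff = 0.226)
  expect_true(all(c("s1", "s2", "s4") %in% qc$kept))
  expect_identical(qc$excluded$reason[qc$excluded$sample_id == "s3"],
                   "ratio_below_cutoff")
  expect_identical(qc$excluded$reason[qc$excluded$sample_id == "s5"],
                   "ratio_above_cutoff")
  expect_true("s6" %in% qc$excluded$sample_id)   # just below the boundary
  tr$abeta[1] <- 0
  expect_error(qc_exclude(tr), "0")
})

test_that("apoe_risk counts e4 minus e2", {
  expect_identical(apoe_risk(c("e3/e3", "e2/e4", "e4/e4", "e2/e2", "e2/e3")),
                   c(0, 0, 2, -2, -1))
  expect_error(apoe_risk("e3/e5"), "unknown")
})

test_that("variance_explained: pure indicators, null expectation, unit sum", {
  set.seed(2)
  n <- 60
  cov <- data.frame(sample_id = paste0("s", 1:n),
                    set = rep(1:2, each = n / 2),
                    batch = rep(paste0("b", 1:6), each = 10))
  ## protein = pure batch indicator
  m <- rbind(as.numeric(cov$batch %in% c("b1", "b2")) + 0,
             rnorm(n))
  dimnames(m) <- list(c("ind|1", "noise|2"), cov$sample_id)
  ve <- variance_explained(m, cov, factors = c("set", "batch"))
  expect_equal(ve["ind|1", "set"] + ve["ind|1", "batch"], 1, tolerance = 1e-9)
  expect_equal(rowSums(ve), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
  ## constant protein: all residual
  m2 <- rbind(m, const = rep(1, n)); rownames(m2)[3] <- "const|3"
  ve2 <- variance_explained(m2, cov, factors = c("set", "batch"))
  expect_equal(ve2["const|3", "residual"], 1)
  ## pure-noise proteins: factor fractions average their df/(n-1) share
  mn <- matrix(rnorm(1000 * n), 1000, n,
               dimnames = list(sprintf("r%04d|r", 1:1000), cov$sample_id))
  ven <- variance_explained(mn, cov, factors = c("set", "batch"))
  expect_equal(mean(ven$set), 1 / (n - 1), tolerance = 0.3)
  expect_equal(mean(ven$batch), 4 / (n - 1), tolerance = 0.2)
})
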