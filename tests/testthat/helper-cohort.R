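## Shared small fixtures, built once per test run.

small_module_sizes <- c(40L, 35L, 30L, 28L, 26L, 24L, 22L, 20L, 18L, 16L)
mid_module_sizes <- c(80L, 70L, 60L, 55L, 50L, 45L, 40L, 35L, 30L, 25L)

small_spec <- function(seed = 1L, n_samples = 80L, ...) {
  cohort_spec(n_proteins = 300L, n_samples = n_samples,
              module_specs = default_module_specs(sizes = small_module_sizes),
              seed = seed, ...)
}

mid_spec <- function(seed = 1L, n_samples = 200L, ...) {
  cohort_spec(n_proteins = 600L, n_samples = n_samples,
              module_specs = default_module_specs(sizes = mid_module_sizes),
              seed = seed, ...)
}

## one cached mid-size cohort + light harmonization reused across files
.fixture_env <- new.env()

fixture_cohort <- function() {
  if (is.null(.fixture_env$coh)) .fixture_env$coh <- generate_cohort(mid_spec(seed = 42L))
  .fixture_env$coh
}

fixture_harmonized <- function() {
  if (is.null(.fixture_env$harm)) {
    coh <- fixture_cohort()
    tr <- coh$traits
    expr <- filter_missingness(coh$expression, 0.5)
    refs <- tr$sample_id[!tr$is_gis & tr$diagnosis == "Control" & tr$race == "NHW"]
    hr <- two_round_harmonize(expr, tr, refs)
    harm <- impute_knn(hr$harmonized, k = 10)
    cov <- tr[match(colnames(harm), tr$sample_id),
              c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
    .fixture_env$harm <- regress_batch(harm, cov, n_boot = 50, seed = 1)
  }
  .fixture_env$harm
}

fixture_network <- function() {
  if (is.null(.fixture_env$net)) .fixture_env$net <- build_network(fixture_harmonized())
  .fixture_env$net
}

## random symmetric weighted graph for modularity oracles
random_graph <- function(n, seed, p_edge = 0.6) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  e <- stats::runif(sum(ut)) < p_edge
  w[ut][e] <- stats::runif(sum(e), 0.1, 1)
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  w
}

## all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

## brute-force maximum modularity by enumeration
brute_force_modularity <- function(graph, partitions = NULL) {
  n <- nrow(graph)
  if (is.null(partitions)) partitions <- all_partitions(n)
  best_q <- -Inf
  for (p in partitions) {
    q <- modularity_q(graph, p)
    if (q > best_q) best_q <- q
  }
  best_q
}

## transfer fixture: reference cohort + 40%-overlap replication cohort
transfer_fixture <- function(seed = 21L) {
  if (!is.null(.fixture_env$transfer) && .fixture_env$transfer_seed == seed)
    return(.fixture_env$transfer)
  spec <- mid_spec(seed = seed, n_samples = 300L)
  coh <- generate_cohort(spec)
  tr <- coh$traits
  harm0 <- impute_knn(filter_missingness(coh$expression[, !tr$is_gis], 0.5))
  eg <- module_eigenproteins(harm0, coh$truth_modules[rownames(harm0)])
  kme <- kme_table(harm0, eg$eigenproteins)
  hubs <- select_hubs(kme, coh$truth_modules[rownames(harm0)], 30)
  qspec <- mid_spec(seed = seed, n_samples = 120L)
  repc <- generate_replication_cohort(qspec, overlap_fraction = 0.4)
  qexpr <- impute_knn(filter_missingness(repc$expression[, !repc$traits$is_gis], 0.5))
  out <- list(coh = coh, hubs = hubs, ref = harm0[hubs$protein, ],
              truth = coh$truth_subtypes, repc = repc, query = qexpr)
  .fixture_env$transfer <- out
  .fixture_env$transfer_seed <- seed
  out
}

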