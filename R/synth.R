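## Synthetic cohort generator
##
## Latent-factor generative model: each co-expression module is driven by one
## factor per sample; a protein's profile is loading * factor + noise, plus
## batch and set offsets on the TMT layout.  Subtypes shift module factors;
## clinical traits (age, sex, race, diagnosis) enter the factors linearly.
## This is the minimal model under which correlation-network modules and
## modularity-based sample subtypes are both well defined, so it supplies
## ground truth for every downstream stage.

#' Build a validated synthetic-cohort specification
#'
#' @param n_proteins total proteins simulated (module members + unstructured
#'   background proteins).
#' @param n_samples number of distinct subjects; subjects selected as
#'   technical replicates contribute one additional sample in the other set.
#' @param module_specs list with one entry per planted module; each entry is a
#'   list with `size` (protein count), `within_module_cor` (target pairwise
#'   correlation inside the module, 0-1), `trait_effects` (named numeric
#'   vector, names in age/sex/race/diagnosis, log2 units per trait unit) and
#'   `subtype_effects` (numeric vector of per-subtype factor mean shifts,
#'   length `n_subtypes`).
#' @param n_subtypes number of planted sample subtypes.
#' @param subtype_proportions subtype mixing fractions, must sum to 1.
#' @param batch_layout list: `n_sets`, `batches_per_set` (NULL = as needed),
#'   `samples_per_batch`, `gis_per_batch` (global internal standard channels
#'   appended to every batch).
#' @param batch_effect_sd,set_effect_sd SD (log2) of per-protein batch / set
#'   offsets.
#' @param replicate_fraction fraction of set-1 subjects re-measured in set 2.
#' @param missingness list: `rate` (target marginal missing fraction over
#'   biological cells) and `abundance_dependence` (logistic slope on the
#'   z-scored log2 abundance; larger = stronger left-censoring).
#' @param noise_sd per-protein residual SD (log2).
#' @param ad_prob_by_subtype,male_prob_by_subtype,aa_prob_by_subtype optional
#'   per-subtype demographic probabilities (recycled to `n_subtypes`).
#' @param bbb_module index of the module treated as the blood-brain-barrier /
#'   plasma module (drives the albumin-ratio trait of replication cohorts and
#'   the plasma-like dilution class).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_proteins = 1000L,
                        n_samples = 430L,
                        module_specs = default_module_specs(),
                        n_subtypes = 6L,
                        subtype_proportions = c(74, 46, 83, 76, 77, 69) / 425,
                        batch_layout = list(n_sets = 2L, batches_per_set = NULL,
                                            samples_per_batch = 8L, gis_per_batch = 1L),
                        batch_effect_sd = 0.3,
                        set_effect_sd = 0.2,
                        replicate_fraction = 0.12,
                        missingness = list(rate = 0.08, abundance_dependence = 1.5),
                        noise_sd = 0.5,
                        ad_prob_by_subtype = c(0.05, 0.15, 0.50, 0.70, 0.80, 0.90),
                        male_prob_by_subtype = c(0.33, 0.33, 0.65, 0.33, 0.33, 0.33),
                        aa_prob_by_subtype = c(0.20, 0.20, 0.50, 0.20, 0.20, 0.20),
                        bbb_module = 1L,
                        seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_samples = as.integer(n_samples),
               module_specs = module_specs,
               n_subtypes = as.integer(n_subtypes),
               subtype_proportions = subtype_proportions,
               batch_layout = batch_layout,
               batch_effect_sd = batch_effect_sd,
               set_effect_sd = set_effect_sd,
               replicate_fraction = replicate_fraction,
               missingness = missingness,
               noise_sd = noise_sd,
               ad_prob_by_subtype = rep_len(ad_prob_by_subtype, n_subtypes),
               male_prob_by_subtype = rep_len(male_prob_by_subtype, n_subtypes),
               aa_prob_by_subtype = rep_len(aa_prob_by_subtype, n_subtypes),
               bbb_module = as.integer(bbb_module),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default planted-module layout
#'
#' Ten modules with sizes tapering from 150 to 50 proteins, within-module
#' correlation 0.6, a blood-brain-barrier-like module 1 (sex/race up), a
#' tau/neuronal module 2 (diagnosis up, lower in males and African
#' Americans), and six subtypes arranged in opposite pairs: each subtype
#' elevates one dedicated module and depresses its opposite subtype's module
#' (subtype 3 = BBB-like, high M1 / low M2; subtype 6 its neuronal mirror
#' image), leaving four modules subtype-neutral.
#'
#' @param n_subtypes number of subtypes the effects are laid out for.
#' @param sizes module sizes, largest first (default ten modules, 150 down
#'   to 50 proteins).
#' @param within_module_cor target within-module pairwise correlation.
#' @param subtype_effect_scale multiplier on the subtype signature matrix
#'   (factor-SD units; the default gives cohesive, recoverable subtypes).
#' @return list suitable for the `module_specs` field of [cohort_spec()].
#' @export
default_module_specs <- function(n_subtypes = 6L,
                                 sizes = c(150L, 120L, 100L, 90L, 80L, 70L,
                                           65L, 60L, 55L, 50L),
                                 within_module_cor = 0.6,
                                 subtype_effect_scale = 3) {
  n_mod <- length(sizes)
  if (n_mod > 10L) stopf("default layout supports at most 10 modules")
  trait_effects <- list(
    c(sex = 0.4, race = 0.4),                 # M1 BBB/plasma-like
    c(diagnosis = 0.7, sex = -0.3, race = -0.35), # M2 tau/neuronal-like
                                              # (tau lower in males and AA)
    numeric(0),                               # M3
    c(diagnosis = 0.6, age = 0.5),            # M4 ubiquitination-like
    numeric(0),                               # M5
    numeric(0),                               # M6
    c(age = 0.6, sex = 0.6),                  # M7 ECM-like
    numeric(0),                               # M8
    numeric(0),                               # M9
    numeric(0))                               # M10
  ## modules x subtypes mean shifts (log2 factor units).  Each subtype
  ## elevates one dedicated module and depresses the module of its opposite
  ## subtype (pairs 1-4, 2-5, 3-6), e.g. the BBB-like subtype 3 is high in
  ## the plasma module M1 and low in the tau/neuronal module M2, while
  ## subtype 6 is its mirror image - the inverse M1/M2 relationship seen in
  ## real CSF cohorts.  This geometry keeps all inter-module factor
  ## covariances <= 0, so a signed co-expression network keeps the modules
  ## apart while the subtypes stay well separated in factor space.
  up <- c(6, 3, 1, 9, 5, 2)         # subtype s raises module up[s]
  opp <- c(4, 5, 6, 1, 2, 3)        # opposite subtype pairs
  S <- matrix(0, nrow = 10, ncol = 6)
  for (s in 1:6) {
    S[up[s], s] <- 1
    S[up[s], opp[s]] <- -1
  }
  S <- S * subtype_effect_scale
  lapply(seq_along(sizes), function(m)
    list(size = sizes[m],
         within_module_cor = within_module_cor,
         trait_effects = trait_effects[[m]],
         subtype_effects = rep_len(S[m, ], n_subtypes)))
}

#' @noRd
validate_cohort_spec <- function(spec) {
  bad <- character(0)
  ms <- spec$module_specs
  if (sum(vapply(ms, `[[`, numeric(1), "size")) > spec$n_proteins)
    bad <- c(bad, "module_specs: sum of module sizes exceeds n_proteins")
  if (abs(sum(spec$subtype_proportions) - 1) > 1e-9)
    bad <- c(bad, "subtype_proportions: must sum to 1")
  if (length(spec$subtype_proportions) != spec$n_subtypes)
    bad <- c(bad, "subtype_proportions: length != n_subtypes")
  for (nm in c("batch_effect_sd", "set_effect_sd", "noise_sd"))
    if (spec[[nm]] < 0) bad <- c(bad, paste0(nm, ": must be >= 0"))
  if (spec$replicate_fraction < 0 || spec$replicate_fraction > 1)
    bad <- c(bad, "replicate_fraction: must be in [0,1]")
  wc <- vapply(ms, `[[`, numeric(1), "within_module_cor")
  if (any(wc < 0 | wc > 1))
    bad <- c(bad, "module_specs: within_module_cor must be in [0,1]")
  if (spec$missingness$rate < 0 || spec$missingness$rate >= 1)
    bad <- c(bad, "missingness$rate: must be in [0,1)")
  bl <- spec$batch_layout
  if (bl$n_sets < 1 || bl$samples_per_batch < 1 || bl$gis_per_batch < 0)
    bad <- c(bad, "batch_layout: n_sets >= 1, samples_per_batch >= 1, gis_per_batch >= 0 required")
  if (length(bad))
    stopf("invalid cohort spec:\n  %s", paste(bad, collapse = "\n  "))
  invisible(spec)
}

#' @noRd
protein_ids <- function(spec) {
  ids <- sprintf("G%04d|P%05d", seq_len(spec$n_proteins), seq_len(spec$n_proteins))
  ## designated proteins used to build immunoassay traits
  tau_idx <- module_index_ranges(spec)[[min(2L, length(spec$module_specs))]][1]
  ab_idx <- module_index_ranges(spec)[[min(4L, length(spec$module_specs))]][1]
  ids[tau_idx] <- "MAPTLIKE|SYN00001"
  if (ab_idx != tau_idx) ids[ab_idx] <- "ABETALIKE|SYN00002"
  ids
}

#' @noRd
module_index_ranges <- function(spec) {
  sizes <- vapply(spec$module_specs, `[[`, numeric(1), "size")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lapply(seq_along(sizes), function(m) starts[m]:ends[m])
}

#' Generate a synthetic multi-batch TMT cohort with planted structure
#'
#' Produces a log2 relative-abundance protein x sample matrix with planted
#' co-expression modules, sample subtypes, batch/set offsets, GIS reference
#' channels, cross-set technical replicate pairs, abundance-dependent
#' missingness, immunoassay biomarkers on set-specific platform scales, and
#' ApoE genotypes with subtype-dependent e4 frequency.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `generated_cohort` with elements
#'   `expression` (raw matrix incl. GIS columns, NAs where missing),
#'   `ideal` (batch/set-free, noise-only matrix of biological columns),
#'   `traits` (per-column data frame incl. batch, set, GIS flag, subject ID,
#'   demographics, immunoassays, ApoE genotype),
#'   `truth_modules` (protein -> planted module or NA),
#'   `truth_subtypes` (biological sample -> planted subtype),
#'   `truth_factors` (biological sample x module latent factor matrix),
#'   `truth_trait_effects` (planted module x trait effect map).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  M <- length(spec$module_specs)
  n <- spec$n_samples
  p <- spec$n_proteins
  ranges <- module_index_ranges(spec)

  ## ---- subjects ----
  subtype <- sample.int(spec$n_subtypes, n, replace = TRUE,
                        prob = spec$subtype_proportions)
  ad <- stats::rbinom(n, 1, spec$ad_prob_by_subtype[subtype])
  male <- stats::rbinom(n, 1, spec$male_prob_by_subtype[subtype])
  aa <- stats::rbinom(n, 1, spec$aa_prob_by_subtype[subtype])
  age <- stats::rnorm(n, 70, 8)
  age_z <- as.numeric(scale(age))
  moca <- pmin(30, pmax(0, round(27.5 - 5.5 * ad - 1.2 * pmax(age_z, 0) +
                                   stats::rnorm(n, 0, 1.8))))
  ## ApoE: e4 frequency rises with AD-enriched subtypes
  f4 <- stats::setNames(seq(0.12, 0.42, length.out = spec$n_subtypes),
                        NULL)[subtype]
  f2 <- 0.07
  draw_allele <- function(p4) sample(c("e2", "e3", "e4"), 1,
                                     prob = c(f2, 1 - f2 - p4, p4))
  apoe <- vapply(f4, function(p4)
    paste(sort(c(draw_allele(p4), draw_allele(p4))), collapse = "/"),
    character(1))

  ## ---- latent module factors (one per subject per module) ----
  Fmat <- matrix(stats::rnorm(n * M), n, M)
  trait_val <- cbind(age = age_z, sex = male, race = aa, diagnosis = ad)
  for (m in seq_len(M)) {
    msp <- spec$module_specs[[m]]
    Fmat[, m] <- Fmat[, m] + msp$subtype_effects[subtype]
    te <- msp$trait_effects
    for (tn in names(te)) Fmat[, m] <- Fmat[, m] + te[[tn]] * trait_val[, tn]
  }

  ## ---- protein loadings ----
  sigma <- spec$noise_sd
  loading <- numeric(p)
  modlab <- rep(NA_character_, p)
  for (m in seq_len(M)) {
    r <- spec$module_specs[[m]]$within_module_cor
    base <- if (sigma == 0) 1 else if (r >= 1) 1e6 else sigma * sqrt(r / (1 - r))
    loading[ranges[[m]]] <- base * stats::runif(length(ranges[[m]]), 0.8, 1.2)
    modlab[ranges[[m]]] <- paste0("M", m)
  }
  ## background proteins: unstructured noise on a comparable scale
  bg <- which(is.na(modlab))
  bg_sd <- sqrt(mean(loading[loading > 0]^2, na.rm = TRUE) + sigma^2)
  if (!length(loading[loading > 0])) bg_sd <- max(sigma, 1)
  mu <- stats::rnorm(p, 0, 1)

  ## ---- sample layout: sets, replicates, batches ----
  n1 <- round(0.58 * n)
  home_set <- c(rep(1L, n1), rep(2L, n - n1))[sample.int(n)]
  if (spec$batch_layout$n_sets == 1L) home_set[] <- 1L
  set1_subj <- which(home_set == 1L)
  n_rep <- if (spec$batch_layout$n_sets >= 2L)
    round(spec$replicate_fraction * length(set1_subj)) else 0L
  rep_subj <- if (n_rep > 0) sort(sample(set1_subj, n_rep)) else integer(0)

  col_subject <- integer(0); col_set <- integer(0)
  for (s in seq_len(spec$batch_layout$n_sets)) {
    subj_s <- which(home_set == s)
    if (s == 2L) subj_s <- c(subj_s, rep_subj)
    subj_s <- subj_s[sample.int(length(subj_s))]
    col_subject <- c(col_subject, subj_s)
    col_set <- c(col_set, rep(s, length(subj_s)))
  }
  ncol_bio <- length(col_subject)
  spb <- spec$batch_layout$samples_per_batch
  col_batch <- character(ncol_bio)
  for (s in seq_len(spec$batch_layout$n_sets)) {
    idx <- which(col_set == s)
    b <- ceiling(seq_along(idx) / spb)
    need <- max(b)
    cap <- spec$batch_layout$batches_per_set
    if (!is.null(cap) && need > cap)
      stopf("batch_layout: set %d needs %d batches but batches_per_set = %d",
            s, need, cap)
    col_batch[idx] <- sprintf("set%d.b%02d", s, b)
  }
  sample_id <- sprintf("s%04d.set%d", col_subject, col_set)

  ## ---- biological expression ----
  ideal <- matrix(0, p, ncol_bio)
  for (m in seq_len(M)) {
    idx <- ranges[[m]]
    ideal[idx, ] <- loading[idx] %o% Fmat[col_subject, m]
  }
  ideal <- ideal + mu +
    matrix(stats::rnorm(p * ncol_bio, 0, sigma), p, ncol_bio)
  if (length(bg))
    ideal[bg, ] <- mu[bg] + matrix(stats::rnorm(length(bg) * ncol_bio, 0, bg_sd),
                                   length(bg), ncol_bio)

  batches <- unique(col_batch)
  B_off <- matrix(stats::rnorm(p * length(batches), 0, spec$batch_effect_sd),
                  p, length(batches), dimnames = list(NULL, batches))
  S_off <- matrix(stats::rnorm(p * spec$batch_layout$n_sets, 0, spec$set_effect_sd),
                  p, spec$batch_layout$n_sets)
  expr <- ideal + B_off[, col_batch] + S_off[, col_set]

  ## ---- GIS channels ----
  ## one pooled standard (the cohort-wide mean profile), re-measured in every
  ## batch with that batch's offset: a fixed-composition reference, so GIS
  ## centering removes technical offsets without batch-specific biology
  gis_n <- spec$batch_layout$gis_per_batch
  gis_cols <- NULL; gis_meta <- NULL
  if (gis_n > 0) {
    pool <- rowMeans(ideal)
    batch_set <- col_set[match(batches, col_batch)]
    gis_list <- list()
    for (bi in seq_along(batches)) {
      b <- batches[bi]
      bm <- pool + B_off[, b] + S_off[, batch_set[bi]]
      for (g in seq_len(gis_n)) {
        gcol <- bm + stats::rnorm(p, 0, sigma / 2)
        gis_list[[sprintf("gis.%s.r%d", b, g)]] <- gcol
      }
    }
    gis_cols <- do.call(cbind, gis_list)
    gis_meta <- data.frame(
      sample_id = colnames(gis_cols),
      subject_id = NA_character_,
      set = as.integer(sub("^gis\\.set(\\d+)\\..*$", "\\1", colnames(gis_cols))),
      batch = sub("^gis\\.(set\\d+\\.b\\d+)\\.r\\d+$", "\\1", colnames(gis_cols)),
      is_gis = TRUE, stringsAsFactors = FALSE)
  }

  ## ---- abundance-dependent missingness on biological cells ----
  rate <- spec$missingness$rate
  if (rate > 0) {
    z <- (expr - mean(expr)) / stats::sd(expr)
    slope <- spec$missingness$abundance_dependence
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a - slope * z)) - rate,
                            c(-50, 50))$root
    miss <- matrix(stats::runif(length(expr)), nrow(expr)) <
      stats::plogis(alpha - slope * z)
    expr[miss] <- NA_real_
  }

  ## ---- immunoassay biomarkers on set-specific platform scales ----
  ids <- protein_ids(spec)
  tau_row <- match("MAPTLIKE|SYN00001", ids)
  ab_row <- match("ABETALIKE|SYN00002", ids)
  if (is.na(ab_row)) ab_row <- tau_row
  ztau <- as.numeric(scale(ideal[tau_row, ]))
  zab <- as.numeric(scale(ideal[ab_row, ]))
  ad_col <- ad[col_subject]
  ratio <- exp(log(0.12) + 1.4 * ad_col + 0.45 * ztau +
                 stats::rnorm(ncol_bio, 0, 0.3))
  plat_scale <- c(1, 3.5)[col_set]
  abeta <- 250 * plat_scale * 2^(-0.35 * zab + stats::rnorm(ncol_bio, 0, 0.2))
  ttau <- ratio * abeta
  ptau <- 0.10 * ttau * 2^stats::rnorm(ncol_bio, 0, 0.15)

  traits <- data.frame(
    sample_id = sample_id,
    subject_id = sprintf("subj%04d", col_subject),
    set = col_set,
    batch = col_batch,
    is_gis = FALSE,
    diagnosis = c("Control", "AD")[ad_col + 1],
    sex = c("F", "M")[male[col_subject] + 1],
    race = c("NHW", "AA")[aa[col_subject] + 1],
    age = age[col_subject],
    moca = moca[col_subject],
    ttau = ttau, ptau = ptau, abeta = abeta,
    platform = c("Luminex", "Elecsys")[col_set],
    apoe = apoe[col_subject],
    stringsAsFactors = FALSE)
  if (!is.null(gis_meta)) {
    gis_full <- traits[0, ][seq_len(nrow(gis_meta)), ]
    gis_full[] <- NA
    gis_full[names(gis_meta)] <- gis_meta
    traits <- rbind(traits, gis_full)
  }

  expr_all <- cbind(expr, gis_cols)
  rownames(expr_all) <- ids
  colnames(expr_all) <- traits$sample_id
  rownames(ideal) <- ids
  colnames(ideal) <- sample_id

  truth_trait_effects <- lapply(spec$module_specs, `[[`, "trait_effects")
  names(truth_trait_effects) <- paste0("M", seq_len(M))

  structure(list(
    expression = expr_all,
    ideal = ideal,
    traits = traits,
    truth_modules = stats::setNames(modlab, ids),
    truth_subtypes = stats::setNames(paste0("S", subtype[col_subject]), sample_id),
    truth_factors = {
      fm <- Fmat[col_subject, , drop = FALSE]
      dimnames(fm) <- list(sample_id, paste0("M", seq_len(M)))
      fm
    },
    truth_trait_effects = truth_trait_effects,
    spec = spec), class = "generated_cohort")
}

#' Generate a partial-overlap replication cohort
#'
#' Draws a fresh cohort from the same planted module/subtype model, restricts
#' the protein space to a random fraction of the reference proteins (partial
#' proteome overlap between platforms), applies a global abundance shift, and
#' adds a CSF/serum albumin-ratio trait driven by the planted blood-brain-
#' barrier module factor.
#'
#' @param spec a [cohort_spec()]; `n_samples` sizes the replication cohort.
#' @param overlap_fraction fraction (0,1] of reference proteins retained.
#' @param scale_shift global log2 abundance shift of the new cohort.
#' @param albumin_noise_sd SD of the noise added to the albumin-ratio trait
#'   around the BBB module factor.
#' @return `generated_cohort` with a single set, no replicates, subset
#'   proteins, and an `albumin_ratio` column in `traits`.
#' @export
generate_replication_cohort <- function(spec, overlap_fraction, scale_shift = 0,
                                        albumin_noise_sd = 0.5) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stopf("overlap_fraction must be in (0, 1]")
  spec2 <- spec
  spec2$batch_layout$n_sets <- 1L
  spec2$replicate_fraction <- 0
  spec2$seed <- spec$seed + 104729L
  class(spec2) <- "cohort_spec"
  coh <- generate_cohort(spec2)

  set.seed(spec$seed + 7919L)
  keep_n <- round(overlap_fraction * nrow(coh$expression))
  keep <- sort(sample.int(nrow(coh$expression), keep_n))
  coh$expression <- coh$expression[keep, , drop = FALSE] + scale_shift
  coh$ideal <- coh$ideal[keep, , drop = FALSE] + scale_shift
  coh$truth_modules <- coh$truth_modules[keep]

  bio <- !coh$traits$is_gis
  fac <- coh$truth_factors[, spec$bbb_module]
  alb <- fac + stats::rnorm(length(fac), 0, albumin_noise_sd)
  coh$traits$albumin_ratio <- NA_real_
  coh$traits$albumin_ratio[bio] <- alb[match(coh$traits$sample_id[bio],
                                             rownames(coh$truth_factors))]
  coh
}

#' Generate a plasma/albumin dilution concentration series
#'
#' Emulates spiking increasing volume fractions of plasma into a pooled CSF
#' background and re-quantifying: plasma-like proteins rise with the spiked
#' fraction, neuronal-like proteins are depleted multiplicatively (protease
#' exposure), a protected class and bystanders are unchanged up to noise.
#' Default magnitudes give roughly +280% for plasma-like and -26% for
#' neuronal-like proteins at the top fraction.
#'
#' @param spec a [cohort_spec()]; its module layout designates the classes:
#'   the `bbb_module` and last module are plasma-like, modules 2/5/6/8 (when
#'   present) neuronal-like, module 4 protected, everything else bystander.
#' @param fractions spiked volume fractions (percent units); must contain 0.
#' @param plasma_gain linear gain per unit fraction for plasma-like proteins.
#' @param decay_rate multiplicative decay rate per unit fraction for
#'   neuronal-like proteins.
#' @param n_replicates replicate injections simulated per fraction.
#' @param noise_sd log2 measurement noise of the series (0 = exact closed
#'   forms).
#' @return list of class `dilution_series`: `fractions`, `matrices` (one log2
#'   matrix per fraction), `truth_classes` (protein -> class).
#' @export
generate_dilution_series <- function(spec,
                                     fractions = c(0, 0.001, 0.01, 0.1, 1),
                                     plasma_gain = 2.8,
                                     decay_rate = 0.3,
                                     n_replicates = 3L,
                                     noise_sd = 0.05) {
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  fractions <- sort(unique(fractions))
  if (fractions[1] != 0) stopf("fractions must include 0 (baseline)")
  set.seed(spec$seed + 15485863L)

  p <- spec$n_proteins
  ids <- protein_ids(spec)
  ranges <- module_index_ranges(spec)
  M <- length(ranges)
  cls <- rep("bystander", p)
  plasma_mods <- unique(c(spec$bbb_module, M))
  neuronal_mods <- intersect(c(2L, 5L, 6L, 8L), seq_len(M))
  protected_mods <- intersect(4L, seq_len(M))
  for (m in plasma_mods) cls[ranges[[m]]] <- "plasma-like"
  for (m in neuronal_mods) cls[ranges[[m]]] <- "neuronal-like"
  for (m in protected_mods) cls[ranges[[m]]] <- "protected"

  base <- stats::rnorm(p, 0, 1)            # baseline log2 pooled profile
  mats <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    mult <- rep(1, p)
    mult[cls == "plasma-like"] <- 1 + plasma_gain * f
    mult[cls == "neuronal-like"] <- exp(-decay_rate * f)
    m <- matrix(rep(base + log2(mult), n_replicates), p, n_replicates)
    if (noise_sd > 0 && (f > 0 || fi > 1))
      m <- m + matrix(stats::rnorm(p * n_replicates, 0, noise_sd), p, n_replicates)
    dimnames(m) <- list(ids, sprintf("frac%g.rep%d", f, seq_len(n_replicates)))
    m
  })
  names(mats) <- as.character(fractions)

  structure(list(fractions = fractions,
                 matrices = mats,
                 truth_classes = stats::setNames(cls, ids),
                 truth_modules = {
                   ml <- rep(NA_character_, p)
                   for (m in seq_len(M)) ml[ranges[[m]]] <- paste0("M", m)
                   stats::setNames(ml, ids)
                 }),
            class = "dilution_series")
}

#' Numeric encoding of clinical traits for correlation analyses
#'
#' @param traits the `traits` data frame of a cohort.
#' @return data frame (rownames = sample IDs) with columns `age_z`, `sex`
#'   (male = 1), `race` (AA = 1), `diagnosis` (AD = 1), `moca`, z-scored
#'   immunoassays when present (`ttau_z`, `ptau_z`, `abeta_z` via
#'   [zscore_by_set()]), and `apoe_risk`.
#' @export
encode_traits <- function(traits) {
  bio <- traits[!traits$is_gis, , drop = FALSE]
  out <- data.frame(row.names = bio$sample_id,
                    age_z = as.numeric(scale(bio$age)),
                    sex = as.numeric(bio$sex == "M"),
                    race = as.numeric(bio$race == "AA"),
                    diagnosis = as.numeric(bio$diagnosis == "AD"),
                    moca = bio$moca)
  if (all(c("ttau", "ptau", "abeta", "set") %in% names(bio))) {
    z <- zscore_by_set(bio, biomarkers = c("ttau", "ptau", "abeta"))
    out$ttau_z <- z$ttau_z; out$ptau_z <- z$ptau_z; out$abeta_z <- z$abeta_z
  }
  if ("apoe" %in% names(bio))
    out$apoe_risk <- apoe_risk(bio$apoe)
  if ("albumin_ratio" %in% names(bio))
    out$albumin_ratio <- bio$albumin_ratio
  out
}
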