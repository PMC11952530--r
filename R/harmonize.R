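## Multi-batch harmonization: iterative median polish of abundance ratios
## (TAMPOR), bootstrap batch/set regression that preserves biological
## covariates, missingness filtering, deterministic KNN imputation,
## per-set biomarker z-scoring and diagnosis QC.

#' Iterative two-way median polish of abundance ratios (TAMPOR)
#'
#' Alternates (a) centering every protein within every batch on the median of
#' that batch's center samples (GIS channels, or a designated reference
#' group) and (b) centering every sample on its median ratio across proteins,
#' on the linear abundance scale, until the largest per-cell log2 change
#' drops below `tol` or `max_iter` is reached.  After convergence the median
#' of the center samples is 0 (log2) for every protein in every batch, which
#' removes additive batch offsets.
#'
#' @param expr log2 protein x sample matrix (NAs allowed).
#' @param batch character/factor of batch IDs per sample (length = ncol).
#' @param center_mode `"GIS"` (center samples looked up per batch via
#'   `is_gis`) or `"reference_group"` (the same `reference_samples` used in
#'   every batch).
#' @param is_gis logical per sample; required in GIS mode.
#' @param reference_samples sample IDs used as centers in reference mode.
#' @param max_iter,tol iteration cap and log2 convergence tolerance.
#' @return list of class `tampor_result`: `harmonized` (log2 matrix, original
#'   column order), `iterations`, `converged`, `max_delta`.
#' @export
tampor <- function(expr, batch, center_mode = c("GIS", "reference_group"),
                   is_gis = NULL, reference_samples = NULL,
                   max_iter = 250L, tol = 1e-8) {
  check_expr(expr)
  center_mode <- match.arg(center_mode)
  if (length(batch) != ncol(expr))
    stopf("batch must have one entry per sample")
  if (any(rowSums(!is.na(expr)) == 0))
    stopf("all-missing protein rows present; run filter_missingness() first")
  batches <- unique(as.character(batch))
  center_of <- lapply(batches, function(b) {
    in_b <- which(as.character(batch) == b)
    ctr <- if (center_mode == "GIS") {
      if (is.null(is_gis)) stopf("is_gis is required in GIS mode")
      in_b[is_gis[in_b]]
    } else {
      if (is.null(reference_samples)) stopf("reference_samples required in reference_group mode")
      in_b[colnames(expr)[in_b] %in% reference_samples]
    }
    if (!length(ctr))
      stopf("batch '%s' has no center sample in %s mode", b, center_mode)
    ctr
  })
  names(center_of) <- batches

  R <- 2^expr
  prev <- log2(R)
  iterations <- 0L
  max_delta <- Inf
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (b in batches) {
      in_b <- which(as.character(batch) == b)
      med <- row_medians(R[, center_of[[b]], drop = FALSE])
      ## a protein whose center samples are all missing in one batch keeps
      ## its global center median instead (left-censored GIS cell)
      if (anyNA(med)) {
        allc <- unlist(center_of, use.names = FALSE)
        gmed <- row_medians(R[, allc, drop = FALSE])
        med[is.na(med)] <- gmed[is.na(med)]
        med[is.na(med) | med == 0] <- 1
      }
      R[, in_b] <- R[, in_b, drop = FALSE] / med
    }
    smed <- apply(R, 2L, stats::median, na.rm = TRUE)
    R <- sweep(R, 2L, smed, "/")
    cur <- log2(R)
    max_delta <- max(abs(cur - prev), na.rm = TRUE)
    prev <- cur
    if (max_delta < tol) { converged <- TRUE; break }
  }
  structure(list(harmonized = prev, iterations = iterations,
                 converged = converged, max_delta = max_delta),
            class = "tampor_result")
}

#' Two-round TAMPOR harmonization across proteomic sets
#'
#' Round 1 runs TAMPOR within each set, centering every batch on its GIS
#' channels; round 2 runs TAMPOR on the concatenated biological columns,
#' treating each set as one batch and centering on a designated reference
#' group (e.g. the control cases of the majority demographic), which removes
#' residual set offsets.  GIS channels are consumed by round 1 and dropped
#' from the output.
#'
#' @param expr log2 matrix including GIS columns.
#' @param traits per-column data frame with `set`, `batch`, `is_gis`.
#' @param reference_samples sample IDs forming the round-2 reference group;
#'   at least one must fall in every set.
#' @param max_iter,tol forwarded to [tampor()].
#' @return list of class `tampor_result` with `harmonized` holding the
#'   biological columns only, plus `iterations_per_round` and `converged`.
#' @export
two_round_harmonize <- function(expr, traits, reference_samples,
                                max_iter = 250L, tol = 1e-8) {
  check_expr(expr)
  if (!length(reference_samples)) stopf("reference group is empty")
  stopifnot(all(c("set", "batch", "is_gis") %in% names(traits)))
  ord <- match(colnames(expr), traits$sample_id)
  if (anyNA(ord)) stopf("traits missing for samples: %s",
                        paste(colnames(expr)[is.na(ord)], collapse = ", "))
  tr <- traits[ord, ]

  sets <- sort(unique(tr$set))
  iters <- integer(0); conv <- logical(0)
  round1 <- expr
  for (s in sets) {
    in_s <- which(tr$set == s)
    r <- tampor(expr[, in_s, drop = FALSE], batch = tr$batch[in_s],
                center_mode = "GIS", is_gis = tr$is_gis[in_s],
                max_iter = max_iter, tol = tol)
    round1[, in_s] <- r$harmonized
    iters <- c(iters, r$iterations); conv <- c(conv, r$converged)
  }

  bio <- which(!tr$is_gis)
  for (s in sets) {
    if (!any(colnames(expr)[bio][tr$set[bio] == s] %in% reference_samples))
      stopf("reference group has no sample in set %s", s)
  }
  r2 <- tampor(round1[, bio, drop = FALSE], batch = as.character(tr$set[bio]),
               center_mode = "reference_group",
               reference_samples = reference_samples,
               max_iter = max_iter, tol = tol)
  structure(list(harmonized = r2$harmonized,
                 iterations_per_round = c(round1 = max(iters), round2 = r2$iterations),
                 converged = all(conv) && r2$converged,
                 max_delta = r2$max_delta),
            class = "tampor_result")
}

#' Remove residual batch/set variance by bootstrap regression
#'
#' Per protein, fits a linear model on dummy-coded nuisance factors
#' (`remove`) together with protected biological covariates (`protect`),
#' averages the coefficients over bootstrap resamples of samples, and
#' subtracts only the fitted nuisance component, leaving the protected
#' effects (age, sex, race, diagnosis) in the data.
#'
#' @param expr complete log2 matrix (impute first).
#' @param covariates data frame (one row per sample, rownames or `sample_id`
#'   matching columns) holding the `remove` and `protect` variables.
#' @param remove character vector of nuisance factor names (e.g. batch, set);
#'   empty = identity.
#' @param protect character vector of protected covariate names.
#' @param n_boot bootstrap resamples; with `full_sample = TRUE` a single
#'   full-data OLS fit is used instead.
#' @param seed integer seed for the resampling.
#' @param full_sample if TRUE, skip resampling (plain OLS removal).
#' @return matrix with the nuisance component removed.
#' @export
regress_batch <- function(expr, covariates, remove = c("batch", "set"),
                          protect = c("age", "sex", "race", "diagnosis"),
                          n_boot = 50L, seed = 1L, full_sample = FALSE) {
  check_expr(expr, allow_na = FALSE)
  if (!length(remove)) return(expr)
  cov <- as.data.frame(covariates)
  if (!is.null(cov$sample_id)) rownames(cov) <- cov$sample_id
  cov <- cov[colnames(expr), , drop = FALSE]
  miss <- setdiff(c(remove, protect), names(cov))
  if (length(miss)) stopf("covariates missing: %s", paste(miss, collapse = ", "))
  for (v in remove) cov[[v]] <- factor(cov[[v]])
  ## drop single-level terms (e.g. 'set' on a one-set cohort)
  remove <- remove[vapply(remove, function(v) nlevels(cov[[v]]) > 1, logical(1))]
  if (!length(remove)) return(expr)

  fml <- stats::reformulate(c(remove, protect))
  X <- stats::model.matrix(fml, data = cov)
  asg <- attr(X, "assign")
  term_lab <- attr(stats::terms(fml), "term.labels")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- qrX$pivot[-seq_len(qrX$rank)]
    aliased_terms <- term_lab[asg[aliased]]
    ## nuisance factors nested in one another (set within batch) are
    ## harmlessly redundant; a protected covariate confounded with a
    ## nuisance factor is not recoverable and must be flagged
    if (any(aliased_terms %in% protect))
      stopf("rank-deficient design: protected covariate(s) %s confounded with %s",
            paste(unique(aliased_terms[aliased_terms %in% protect]), collapse = ", "),
            paste(remove, collapse = "/"))
    X <- X[, sort(qrX$pivot[seq_len(qrX$rank)]), drop = FALSE]
    asg <- asg[sort(qrX$pivot[seq_len(qrX$rank)])]
  }
  rm_cols <- which(asg %in% which(term_lab %in% remove))

  Yt <- t(expr)                                # samples x proteins
  nsamp <- nrow(Yt)
  if (full_sample || n_boot <= 1L) {
    beta <- qr.coef(qrX, Yt)
  } else {
    set.seed(seed)
    beta <- 0
    done <- 0L
    while (done < n_boot) {
      idx <- sample.int(nsamp, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      bb <- tryCatch(solve(crossprod(Xb), crossprod(Xb, Yt[idx, , drop = FALSE])),
                     error = function(e) NULL)
      if (is.null(bb)) next                    # degenerate resample: redraw
      beta <- beta + bb / n_boot
      done <- done + 1L
    }
  }
  removed <- X[, rm_cols, drop = FALSE] %*% beta[rm_cols, , drop = FALSE]
  out <- expr - t(removed)
  dimnames(out) <- dimnames(expr)
  out
}

#' Keep proteins observed in at least a given fraction of samples
#'
#' @param expr matrix with NAs marking missing values.
#' @param min_fraction minimum observed fraction (boundary inclusive;
#'   default 0.5 keeps proteins present in >= 50% of samples).
#' @return filtered matrix.
#' @export
filter_missingness <- function(expr, min_fraction = 0.5) {
  check_expr(expr)
  frac <- rowMeans(!is.na(expr))
  expr[frac >= min_fraction, , drop = FALSE]
}

#' Deterministic KNN imputation over protein profiles
#'
#' Missing cells are filled with the mean of the `k` nearest protein
#' profiles (Euclidean distance on row-standardized profiles over co-observed
#' samples) that observe the missing sample.  A protein with no co-observed
#' neighbor for some cell falls back to its own median, with a warning.
#'
#' @param expr post-filter log2 matrix.
#' @param k number of neighbor proteins.
#' @return complete matrix.
#' @export
impute_knn <- function(expr, k = 10L) {
  check_expr(expr)
  if (!anyNA(expr)) return(expr)
  Z <- row_standardize(expr)
  Obs <- !is.na(Z)
  Z0 <- Z; Z0[!Obs] <- 0
  M <- Obs * 1
  ## mean squared difference over co-observed samples, via cross-products
  S2 <- (Z0^2) %*% t(M)
  Cross <- Z0 %*% t(Z0)
  Nco <- M %*% t(M)
  D2 <- (S2 + t(S2) - 2 * Cross) / pmax(Nco, 1)
  D2[Nco == 0] <- Inf
  diag(D2) <- Inf

  out <- expr
  fallback <- 0L
  need <- which(rowSums(!Obs) > 0)
  med <- row_medians(expr)
  for (i in need) {
    ord <- order(D2[i, ])
    miss_cols <- which(!Obs[i, ])
    for (jc in miss_cols) {
      cand <- ord[Obs[ord, jc] & is.finite(D2[i, ord])]
      if (!length(cand)) {
        out[i, jc] <- med[i]
        fallback <- fallback + 1L
      } else {
        nb <- cand[seq_len(min(k, length(cand)))]
        out[i, jc] <- mean(expr[nb, jc])
      }
    }
  }
  if (fallback > 0)
    warnf("%d cells had no co-observed neighbor; filled with protein medians",
          fallback)
  out
}

#' Z-score immunoassay biomarkers within each proteomic set
#'
#' Platforms differ between sets, so biomarkers are standardized per set
#' ((x - mean) / sd over non-missing entries, sample SD) to make them
#' comparable; new columns get a `_z` suffix.
#'
#' @param traits data frame with a `set` column and the biomarker columns.
#' @param biomarkers column names to standardize.
#' @return `traits` with added `<biomarker>_z` columns.
#' @export
zscore_by_set <- function(traits, biomarkers = c("ttau", "ptau", "abeta")) {
  stopifnot("set" %in% names(traits))
  for (bm in biomarkers) {
    z <- rep(NA_real_, nrow(traits))
    for (s in unique(traits$set[!is.na(traits$set)])) {
      idx <- which(traits$set == s & !is.na(traits[[bm]]))
      if (!length(idx)) next
      sdv <- stats::sd(traits[[bm]][idx])
      if (is.na(sdv) || sdv == 0)
        stopf("biomarker '%s' has zero variance in set %s", bm, s)
      z[idx] <- (traits[[bm]][idx] - mean(traits[[bm]][idx])) / sdv
    }
    traits[[paste0(bm, "_z")]] <- z
  }
  traits
}

#' Diagnosis QC by the tTau/Abeta immunoassay ratio
#'
#' AD samples are kept iff tTau/Abeta >= `ratio_cutoff` (boundary inclusive);
#' control samples are kept iff the ratio is below the cutoff.  An optional
#' MoCA incongruence check (off by default) additionally excludes AD samples
#' with MoCA above `moca_ad_max`.
#'
#' @param traits data frame with `sample_id`, `diagnosis`, `ttau`, `abeta`
#'   (raw platform scale), optionally `moca`.
#' @param ratio_cutoff tTau/Abeta ratio confirming AD (default 0.226).
#' @param moca_check enable the MoCA incongruence rule.
#' @param moca_ad_max maximum MoCA compatible with an AD diagnosis when the
#'   check is on.
#' @return list: `kept` (sample IDs), `excluded` (data frame sample_id,
#'   reason).
#' @export
qc_exclude <- function(traits, ratio_cutoff = 0.226,
                       moca_check = FALSE, moca_ad_max = 26) {
  bio <- if (is.null(traits$is_gis)) traits else
    traits[!(traits$is_gis %in% TRUE), , drop = FALSE]
  if (any(bio$abeta == 0, na.rm = TRUE)) stopf("Abeta value of 0 encountered")
  ratio <- bio$ttau / bio$abeta
  ad <- bio$diagnosis == "AD"
  reason <- rep(NA_character_, nrow(bio))
  reason[ad & ratio < ratio_cutoff] <- "ratio_below_cutoff"
  reason[!ad & ratio >= ratio_cutoff] <- "ratio_above_cutoff"
  if (moca_check && "moca" %in% names(bio))
    reason[ad & !is.na(bio$moca) & bio$moca > moca_ad_max & is.na(reason)] <-
      "moca_incongruent"
  excl <- !is.na(reason)
  list(kept = bio$sample_id[!excl],
       excluded = data.frame(sample_id = bio$sample_id[excl],
                             reason = reason[excl],
                             stringsAsFactors = FALSE))
}

#' ApoE allele-count risk score
#'
#' +1 for each e4 allele, -1 for each e2 allele; e3 is neutral.
#'
#' @param genotype character vector like `"e3/e4"` (any separator among
#'   `/`, `|`, space), or a 2-column matrix of allele tokens.
#' @return integer vector of risk scores in -2..2.
#' @export
apoe_risk <- function(genotype) {
  if (is.matrix(genotype)) {
    alleles <- cbind(as.character(genotype[, 1]), as.character(genotype[, 2]))
  } else {
    parts <- strsplit(tolower(as.character(genotype)), "[/| ]+")
    if (any(lengths(parts) != 2 & !is.na(genotype)))
      stopf("genotype must contain exactly two alleles")
    alleles <- do.call(rbind, lapply(parts, function(x) if (length(x) == 2) x else c(NA, NA)))
  }
  al <- tolower(gsub("[^a-z0-9]", "", alleles))
  al[al %in% c("2", "e2", "eps2", "apoe2")] <- "e2"
  al[al %in% c("3", "e3", "eps3", "apoe3")] <- "e3"
  al[al %in% c("4", "e4", "eps4", "apoe4")] <- "e4"
  bad <- !is.na(al) & !al %in% c("e2", "e3", "e4")
  if (any(bad)) stopf("unknown ApoE allele token(s): %s",
                      paste(unique(al[bad]), collapse = ", "))
  rowSums(al == "e4") - rowSums(al == "e2")
}

#' Per-protein variance fractions by design factor
#'
#' Sequential (type-I) OLS sums of squares in the fixed order given by
#' `factors`, so each factor is credited with the variance it explains after
#' the factors before it; the fractions plus the residual sum to 1.
#'
#' @param expr complete matrix.
#' @param covariates per-sample data frame holding the factors.
#' @param factors factor/covariate names in attribution order (convention:
#'   set, batch, then protected covariates).
#' @return data frame, one row per protein, one column per factor plus
#'   `residual`; constant proteins are all-residual.
#' @export
variance_explained <- function(expr, covariates,
                               factors = c("set", "batch", "age", "sex",
                                           "race", "diagnosis")) {
  check_expr(expr, allow_na = FALSE)
  cov <- as.data.frame(covariates)
  if (!is.null(cov$sample_id)) rownames(cov) <- cov$sample_id
  cov <- cov[colnames(expr), , drop = FALSE]
  factors <- intersect(factors, names(cov))
  for (f in factors)
    if (!is.numeric(cov[[f]])) cov[[f]] <- factor(cov[[f]])

  n <- ncol(expr)
  Yt <- t(expr)
  tot <- colSums(sweep(Yt, 2L, colMeans(Yt))^2)
  out <- matrix(0, nrow(expr), length(factors) + 1,
                dimnames = list(rownames(expr), c(factors, "residual")))
  prev_fit <- rep(0, nrow(expr))
  Q_prev <- matrix(1 / sqrt(n), n, 1)          # intercept-only basis
  for (fi in seq_along(factors)) {
    fml <- stats::reformulate(factors[seq_len(fi)])
    X <- stats::model.matrix(fml, data = cov)
    qq <- qr(X)
    Q <- qr.Q(qq)[, seq_len(qq$rank), drop = FALSE]
    fit_ss <- colSums((t(Q) %*% Yt)^2) - colSums((t(Q_prev) %*% Yt)^2)
    out[, fi] <- pmax(fit_ss, 0)
    Q_prev <- Q
  }
  explained <- rowSums(out[, seq_along(factors), drop = FALSE])
  out[, "residual"] <- pmax(tot - explained, 0)
  const <- tot <= .Machine$double.eps * n
  res <- sweep(out, 1L, pmax(rowSums(out), .Machine$double.xmin), "/")
  res[const, ] <- 0
  res[const, "residual"] <- 1
  as.data.frame(res)
}
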