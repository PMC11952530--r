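## Figure-level statistics: multi-factor ANOVA with Tukey HSD, chi-squared
## subtype demographic enrichment, the 3-SD plotting trim, column median
## normalization, and the plasma-dilution percent-of-baseline module
## response analysis.

#' Multi-factor ANOVA with Tukey HSD post-hoc contrasts
#'
#' Type-II sums-of-squares F-tests for up to three crossed factors (suited
#' to unbalanced cohorts), plus Tukey honest-significant-difference
#' contrasts between all factor-combination cells.
#'
#' @param values numeric response.
#' @param factors data frame of 1-3 factor columns.
#' @param interactions include interaction terms (requires >= 2 observations
#'   in every non-empty cell; an empty cell raises an error naming it).
#' @return list: `effects` (type-II ANOVA table as data frame),
#'   `tukey` (data frame contrast, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, factors, interactions = TRUE) {
  fac <- as.data.frame(factors)
  if (ncol(fac) < 1 || ncol(fac) > 3) stopf("1 to 3 factors supported")
  fac[] <- lapply(fac, factor)
  for (f in names(fac))
    if (nlevels(fac[[f]]) < 2) stopf("factor '%s' has < 2 levels", f)
  df <- data.frame(.y = values, fac)
  if (interactions && ncol(fac) > 1) {
    cell <- interaction(fac, drop = FALSE)
    counts <- table(cell)
    if (any(counts == 0))
      stopf("empty cell(s) with interactions requested: %s",
            paste(names(counts)[counts == 0], collapse = ", "))
    fml <- stats::reformulate(paste(names(fac), collapse = " * "),
                              response = ".y")
  } else {
    fml <- stats::reformulate(names(fac), response = ".y")
  }
  fit <- stats::lm(fml, data = df)
  eff <- as.data.frame(car::Anova(fit, type = 2))
  eff$term <- rownames(eff)

  cellf <- droplevels(interaction(fac, sep = ":"))
  tk <- stats::TukeyHSD(stats::aov(.y ~ cellf, data = df))$cellf
  tukey <- data.frame(contrast = rownames(tk), tk, row.names = NULL)
  names(tukey) <- c("contrast", "diff", "lwr", "upr", "p_adj")
  list(effects = eff, tukey = tukey)
}

#' Chi-squared enrichment of a binary trait within subtypes
#'
#' For each subtype, tests the 2x2 table (in-subtype vs rest x trait) by
#' chi-squared without continuity correction; when any expected cell is
#' below 1 the exact Fisher p-value is reported instead and flagged.
#' Swapping the trait's 0/1 coding flips the direction of enrichment but
#' leaves the p-value unchanged.
#'
#' @param membership subtype label per sample (NA = unassigned, dropped).
#' @param trait binary (0/1 or logical) vector per sample.
#' @return data frame: subtype, n, observed_pct, cohort_pct, statistic, p,
#'   test ("chisq" or "fisher").
#' @export
chisq_enrichment <- function(membership, trait) {
  tr <- as.numeric(trait)
  if (!all(tr %in% c(0, 1, NA))) stopf("trait must be binary 0/1")
  ok <- !is.na(membership) & !is.na(tr)
  membership <- membership[ok]; tr <- tr[ok]
  cohort_pct <- 100 * mean(tr)
  rows <- lapply(sort(unique(membership)), function(s) {
    ins <- membership == s
    tab <- table(factor(ins, c(FALSE, TRUE)), factor(tr, c(0, 1)))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 1)) {
      ft <- stats::fisher.test(tab)
      data.frame(subtype = s, n = sum(ins),
                 observed_pct = 100 * mean(tr[ins]), cohort_pct = cohort_pct,
                 statistic = NA_real_, p = ft$p.value, test = "fisher")
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      data.frame(subtype = s, n = sum(ins),
                 observed_pct = 100 * mean(tr[ins]), cohort_pct = cohort_pct,
                 statistic = unname(ct$statistic), p = ct$p.value,
                 test = "chisq")
    }
  })
  do.call(rbind, rows)
}

#' 3-SD plotting trim
#'
#' Per group, flags values inside mean +/- 3 SD for plotting; this is a
#' display convention only and never feeds back into test statistics.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return logical vector, TRUE = plot this point.
#' @export
trim_3sd <- function(values, groups) {
  keep <- rep(TRUE, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    mu <- mean(values[idx], na.rm = TRUE)
    sd <- stats::sd(values[idx], na.rm = TRUE)
    if (is.na(sd) || sd == 0) next
    keep[idx] <- !is.na(values[idx]) & abs(values[idx] - mu) <= 3 * sd
  }
  keep
}

#' Column median normalization
#'
#' Subtracts each sample's median log2 abundance, restoring a common center
#' across injections.
#'
#' @param expr log2 matrix (NAs allowed).
#' @return normalized matrix.
#' @export
column_median_normalize <- function(expr) {
  check_expr(expr)
  med <- apply(expr, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med)) stopf("all-missing column(s): %s",
                        paste(colnames(expr)[is.na(med)], collapse = ", "))
  sweep(expr, 2L, med)
}

#' Plasma-dilution module response analysis
#'
#' Every protein is expressed as a percent of its baseline (fraction 0)
#' abundance on the linear scale; module curves average those percents over
#' the subtyping hub proteins when `hub_proteins` is given, else over all
#' module members.  Per module, significance of the change from baseline to
#' the top fraction is a one-way ANOVA over protein-level log2 ratios with a
#' Tukey contrast (proteins as repeated units), and the dose trend is the
#' linear regression slope of the log2 ratio on the spiked fraction.
#'
#' @param series a `dilution_series` (list with `fractions` and `matrices`),
#'   or any list of log2 matrices named by fraction including "0".
#' @param module_labels protein -> module map (NA = unassigned, ignored).
#' @param hub_proteins optional protein subset used for the module curves.
#' @return list of class `dilution_response`: `protein_percent` (protein x
#'   fraction percent-of-baseline matrix), `module_curves` (module x
#'   fraction), `module_tests` (module, slope, p_top_vs_baseline).
#' @export
dilution_response <- function(series, module_labels, hub_proteins = NULL) {
  fractions <- series$fractions
  mats <- series$matrices
  if (is.null(fractions)) fractions <- as.numeric(names(mats))
  if (!0 %in% fractions) stopf("baseline fraction 0 is required")
  base_mat <- mats[[which(fractions == 0)]]
  ids <- rownames(base_mat)
  ok_all <- Reduce(intersect, lapply(mats, rownames))
  drop <- setdiff(ids, ok_all)
  if (length(drop)) {
    warnf("%d proteins missing from some fractions dropped", length(drop))
    ids <- intersect(ids, ok_all)
  }
  base_mean <- rowMeans(base_mat[ids, , drop = FALSE])

  ## percent of baseline per protein per fraction (linear-scale ratio x 100)
  pct <- vapply(seq_along(fractions), function(fi) {
    m <- mats[[fi]][ids, , drop = FALSE]
    100 * 2^(rowMeans(m) - base_mean)
  }, numeric(length(ids)))
  dimnames(pct) <- list(ids, as.character(fractions))
  pct[, "0"] <- 100                      # exact by construction

  labels <- module_labels[ids]
  mods <- unique(labels[!is.na(labels)])
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", mods)))
  mods <- mods[order(!is.na(num), num, mods)]
  curve_ids <- function(m) {
    memb <- ids[!is.na(labels) & labels == m]
    if (!is.null(hub_proteins)) {
      hub <- intersect(memb, hub_proteins)
      if (length(hub)) memb <- hub
    }
    memb
  }
  curves <- t(vapply(mods, function(m)
    colMeans(pct[curve_ids(m), , drop = FALSE]), numeric(length(fractions))))
  dimnames(curves) <- list(mods, as.character(fractions))

  top_i <- which.max(fractions)
  tests <- lapply(mods, function(m) {
    memb <- curve_ids(m)
    ratio0 <- as.numeric(base_mat[memb, , drop = FALSE] - base_mean[memb])
    ratioT <- as.numeric(mats[[top_i]][memb, , drop = FALSE] - base_mean[memb])
    p <- if (length(memb) >= 2 &&
             stats::sd(c(ratio0, ratioT)) > 0) {
      grp <- factor(rep(c("baseline", "top"),
                        c(length(ratio0), length(ratioT))))
      tk <- stats::TukeyHSD(stats::aov(c(ratio0, ratioT) ~ grp))$grp
      unname(tk[1, "p adj"])
    } else NA_real_
    ## dose trend: log2 ratio vs fraction over all fractions
    lr <- do.call(rbind, lapply(seq_along(fractions), function(fi)
      data.frame(f = fractions[fi],
                 y = as.numeric(mats[[fi]][memb, , drop = FALSE] -
                                  base_mean[memb]))))
    slope <- unname(stats::coef(stats::lm(y ~ f, data = lr))[2])
    data.frame(module = m, slope = slope, p_top_vs_baseline = p)
  })
  structure(list(protein_percent = pct,
                 module_curves = curves,
                 module_tests = do.call(rbind, tests),
                 fractions = fractions),
            class = "dilution_response")
}
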