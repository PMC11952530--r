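#' @keywords internal
"_PACKAGE"

## small shared helpers --------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check an expression matrix argument
#'
#' Proteins are rows, samples are columns; dimnames are mandatory because
#' every stage joins on them.
#' @noRd
check_expr <- function(expr, allow_na = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("expression must be a numeric matrix (proteins x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expression matrix must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stopf("duplicate protein IDs: %s",
          paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stopf("duplicate sample IDs: %s",
          paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (!allow_na && anyNA(expr))
    stopf("expression matrix contains missing values; impute first")
  invisible(expr)
}

#' Row medians / MADs with NA handling (no matrixStats dependency)
#' @noRd
row_medians <- function(x, na.rm = TRUE) apply(x, 1L, stats::median, na.rm = na.rm)

#' Standardize matrix rows to mean 0, sd 1 (sample sd)
#' @noRd
row_standardize <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1L, stats::sd, na.rm = TRUE)
  sd[sd == 0 | is.na(sd)] <- 1
  (x - mu) / sd
}

#' Adjusted Rand index between two label vectors
#'
#' Permutation-invariant agreement between a recovered partition and a
#' reference partition; 1 = identical up to relabeling, 0 = chance.
#' Entries that are NA in either vector are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Size-ordered relabeling: largest group becomes <prefix>1
#'
#' Ties on size break by order of first appearance so the relabeling is
#' deterministic.
#' @noRd
relabel_by_size <- function(labels, prefix = "M", na_label = NA) {
  assigned <- !is.na(labels)
  if (!any(assigned)) return(labels)
  tab <- table(labels[assigned])
  first_seen <- vapply(names(tab), function(l) match(l, labels), integer(1))
  ord <- names(tab)[order(-as.integer(tab), first_seen)]
  new <- stats::setNames(paste0(prefix, seq_along(ord)), ord)
  out <- rep(na_label, length(labels))
  out[assigned] <- unname(new[as.character(labels[assigned])])
  names(out) <- names(labels)
  out
}
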