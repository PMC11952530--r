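## Orchestration and I/O: lossless TSV / GCT 1.2 matrix round-trips, YAML
## run configuration, staged execution with a reproducibility manifest.

#' Read a protein x sample expression matrix
#'
#' TSV dialect: first column = protein ID ("SYMBOL|ACCESSION" convention;
#' bare symbols accepted with a warning), remaining columns numeric samples.
#' GCT 1.2 dialect: `#1.2` header, dimensions line, `Name`/`Description`
#' columns.  Duplicate protein or sample IDs and non-numeric cells are
#' rejected with coordinates.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"gct_1_2"`.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, dialect = c("tsv", "gct_1_2")) {
  dialect <- match.arg(dialect)
  if (dialect == "gct_1_2") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2 || hdr[1] != "#1.2")
      stopf("not a GCT 1.2 file (missing #1.2 header): %s", path)
    dims <- as.integer(strsplit(hdr[2], "\t")[[1]])
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
      stopf("GCT dimension line (%d x %d) does not match table (%d x %d)",
            dims[1], dims[2], nrow(df), ncol(df) - 2L)
    ids <- df[[1]]
    vals <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stopf("matrix file needs an ID column plus samples: %s", path)
    ids <- df[[1]]
    vals <- df[, -1, drop = FALSE]
  }
  if (!nrow(vals) || !ncol(vals)) stopf("empty matrix in %s", path)
  if (anyDuplicated(ids))
    stopf("duplicate protein IDs: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(vals)))
    stopf("duplicate sample IDs: %s",
          paste(unique(colnames(vals)[duplicated(colnames(vals))]), collapse = ", "))
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stopf("non-numeric cell at protein '%s', sample '%s': '%s'",
              ids[bad[1]], colnames(vals)[j], col[bad[1]])
      vals[[j]] <- num
    }
  }
  if (!all(grepl("\\|", ids)))
    warnf("%d protein IDs lack the SYMBOL|ACCESSION form", sum(!grepl("\\|", ids)))
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write an expression matrix (TSV or GCT 1.2), losslessly to 1e-9
#'
#' @param expr numeric matrix with dimnames.
#' @param path output file.
#' @param dialect `"tsv"` or `"gct_1_2"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(expr, path, dialect = c("tsv", "gct_1_2")) {
  dialect <- match.arg(dialect)
  check_expr(expr)
  fmt <- format(expr, digits = 15, trim = TRUE, scientific = FALSE)
  fmt[is.na(expr)] <- "NA"
  if (dialect == "gct_1_2") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(expr)), collapse = "\t"), con)
    body <- cbind(rownames(expr), "na", fmt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  } else {
    df <- data.frame(protein = rownames(expr), fmt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("protein", colnames(expr))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
default_run_config <- function() {
  list(seed = 1L,
       stages = c("simulate", "harmonize", "network", "subtype"),
       simulate = list(n_proteins = 600L, n_samples = 150L),
       harmonize = list(min_fraction = 0.5, n_boot = 25L, knn_k = 10L),
       network = list(power = 6, deep_split = 2L, min_module_size = 10L,
                      merge_cut_height = 0.7, signed = TRUE),
       subtype = list(hubs_per_module = 30L, power = 13,
                      grid_i = c(10L, 15L), grid_j = c(100L, 200L),
                      grid_k = c(25L)))
}

#' @noRd
validate_run_config <- function(config) {
  known <- c("simulate", "harmonize", "network", "subtype")
  if (is.null(config$stages) || !length(config$stages))
    stopf("config$stages is empty")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  ord <- match(config$stages, known)
  if (is.unsorted(ord)) stopf("stages out of dependency order; expected subset of: %s",
                              paste(known, collapse = " -> "))
  if (is.null(config$seed)) stopf("config$seed is required")
  invisible(config)
}

#' Run the synthetic subtyping pipeline end to end
#'
#' Executes the requested stages in dependency order
#' (simulate -> harmonize -> network -> subtype), writes every stage's
#' tables under `out_dir`, and records a JSON manifest with the seed,
#' parameters, per-stage runtimes and output file checksums; a rerun with
#' the same config reproduces the checksums bit for bit.
#'
#' @param config nested list (or path to a YAML file) with `seed`, `stages`,
#'   and per-stage parameter blocks; missing blocks take package defaults.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_run_config()
  config <- utils::modifyList(def, config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  state <- list()

  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    prm <- config[[stage]]
    if (stage == "simulate") {
      base_sizes <- c(150L, 120L, 100L, 90L, 80L, 70L, 65L, 60L, 55L, 50L)
      sizes <- pmax(10L, as.integer(round(base_sizes * prm$n_proteins / 1000)))
      spec <- cohort_spec(n_proteins = prm$n_proteins, n_samples = prm$n_samples,
                          module_specs = default_module_specs(sizes = sizes),
                          seed = config$seed)
      coh <- generate_cohort(spec)
      state$cohort <- coh
      outputs <- c(outputs,
                   write_matrix(coh$expression, file.path(out_dir, "expression.tsv")),
                   write_tsv(coh$traits, file.path(out_dir, "traits.tsv")),
                   write_tsv(data.frame(protein = names(coh$truth_modules),
                                        module = coh$truth_modules),
                             file.path(out_dir, "truth_modules.tsv")),
                   write_tsv(data.frame(sample = names(coh$truth_subtypes),
                                        subtype = coh$truth_subtypes),
                             file.path(out_dir, "truth_subtypes.tsv")))
      counts <- list(proteins = nrow(coh$expression), samples = ncol(coh$expression))
    } else if (stage == "harmonize") {
      coh <- state$cohort %||% stopf("harmonize stage needs the simulate stage")
      tr <- coh$traits
      refs <- tr$sample_id[!tr$is_gis & tr$diagnosis == "Control" & tr$race == "NHW"]
      expr <- filter_missingness(coh$expression, prm$min_fraction)
      hr <- two_round_harmonize(expr, tr, reference_samples = refs)
      harm <- impute_knn(hr$harmonized, k = prm$knn_k)
      cov <- tr[match(colnames(harm), tr$sample_id),
                c("sample_id", "batch", "set", "age", "sex", "race", "diagnosis")]
      harm <- regress_batch(harm, cov, n_boot = prm$n_boot, seed = config$seed)
      state$harmonized <- harm
      qc <- qc_exclude(tr)
      ve <- variance_explained(harm, cov)
      outputs <- c(outputs,
                   write_matrix(harm, file.path(out_dir, "harmonized.tsv")),
                   write_tsv(qc$excluded, file.path(out_dir, "qc_exclusions.tsv")),
                   write_tsv(cbind(protein = rownames(ve), ve),
                             file.path(out_dir, "variance_report.tsv")))
      counts <- list(proteins = nrow(harm), samples = ncol(harm),
                     qc_excluded = nrow(qc$excluded),
                     tampor_iterations = unname(hr$iterations_per_round))
    } else if (stage == "network") {
      harm <- state$harmonized %||% stopf("network stage needs the harmonize stage")
      net <- build_network(harm, power = prm$power, signed = prm$signed,
                           deep_split = prm$deep_split,
                           min_module_size = prm$min_module_size,
                           merge_cut_height = prm$merge_cut_height)
      state$network <- net
      own_kme <- vapply(seq_along(net$labels), function(i) {
        l <- net$labels[i]
        if (is.na(l)) NA_real_ else net$kme[i, l]
      }, numeric(1))
      outputs <- c(outputs,
                   write_tsv(data.frame(protein = names(net$labels),
                                        module = net$labels, own_kme = own_kme),
                             file.path(out_dir, "modules.tsv")),
                   write_matrix(net$eigenproteins, file.path(out_dir, "eigenproteins.tsv")),
                   write_matrix(net$kme, file.path(out_dir, "kme.tsv")))
      counts <- list(modules = length(unique(net$labels[!is.na(net$labels)])),
                     unassigned = sum(is.na(net$labels)))
    } else if (stage == "subtype") {
      net <- state$network %||% stopf("subtype stage needs the network stage")
      harm <- state$harmonized
      tr <- state$cohort$traits
      hubs <- select_hubs(net$kme, net$labels, prm$hubs_per_module)
      hub_expr <- harm[hubs$protein, , drop = FALSE]
      subjects <- tr$subject_id[match(colnames(hub_expr), tr$sample_id)]
      part <- grid_search_subtypes(hub_expr, subjects,
                                   grid_i = prm$grid_i, grid_j = prm$grid_j,
                                   grid_k = prm$grid_k, power = prm$power,
                                   seed = config$seed)
      state$subtypes <- part
      outputs <- c(outputs,
                   write_tsv(data.frame(sample = names(part$membership),
                                        subtype = part$membership,
                                        hub_correlation = part$hub_correlation),
                             file.path(out_dir, "subtypes.tsv")),
                   write_tsv(part$score_table, file.path(out_dir, "gridsearch.tsv")),
                   write_tsv(data.frame(subject = part$excluded_pairs),
                             file.path(out_dir, "excluded_pairs.tsv")))
      counts <- list(subtypes = length(unique(part$membership[!is.na(part$membership)])),
                     consistency = part$consistency)
    }
    manifest$stages[[stage]] <- list(params = prm, counts = counts,
                                     runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
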