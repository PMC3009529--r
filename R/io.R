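#' Write a replicate series set as TSV files
#'
#' One tab-delimited file per replicate: mandatory first column `time`, then
#' one column per gene, header row with gene names.
#'
#' @param data an [expression_series_set()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are `<prefix>_<m>.tsv`.
#' @return invisibly, the written file paths.
#' @export
write_series_set <- function(data, dir, prefix = "replicate") {
  stopifnot(inherits(data, "expression_series_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(data$series))
  for (m in seq_along(data$series)) {
    df <- data.frame(time = data$times, data$series[[m]],
                     check.names = FALSE)
    paths[m] <- file.path(dir, sprintf("%s_%02d.tsv", prefix, m))
    utils::write.table(df, paths[m], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a directory of replicate TSV time series
#'
#' Expects the layout written by [write_series_set()]: each file has a
#' `time` first column and identical gene headers. Files are read in sorted
#' name order.
#'
#' @param path directory containing `.tsv` replicate files (or an explicit
#'   character vector of file paths).
#' @return an [expression_series_set()].
#' @export
read_series_dir <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  else path
  if (length(files) == 0L) stop("no .tsv replicate files found in ", path)
  ref_header <- NULL
  times <- NULL
  series <- vector("list", length(files))
  for (i in seq_along(files)) {
    df <- utils::read.delim(files[i], check.names = FALSE)
    if (ncol(df) < 2L || names(df)[1] != "time")
      stop("file ", files[i], " must start with a `time` column")
    if (is.null(ref_header)) {
      ref_header <- names(df)
      times <- df$time
    } else {
      if (!identical(names(df), ref_header))
        stop("header of ", files[i], " does not match the first replicate (",
             paste(setdiff(union(names(df), ref_header),
                           intersect(names(df), ref_header)),
                   collapse = ", "), ")")
      if (nrow(df) != length(times))
        stop("file ", files[i], " has a different number of rows")
    }
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals) || any(!is.finite(vals)))
      stop("non-numeric or missing expression values in ", files[i])
    series[[i]] <- vals
  }
  expression_series_set(series, times, ref_header[-1])
}

#' Write a network as a signed edge list
#'
#' TSV with columns `regulator`, `target`, `sign` (+/-) and `weight`.
#'
#' @param pred a [network_prediction()] or [gold_standard()].
#' @param path output file.
#' @return invisibly, the edge data frame written.
#' @export
write_edge_list <- function(pred, path) {
  edges <- as_edge_list(pred)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}

#' @rdname write_edge_list
#' @export
as_edge_list <- function(pred) {
  if (inherits(pred, "gold_standard")) {
    W <- gold_weight_matrix(pred)
  } else if (inherits(pred, "network_prediction")) {
    W <- pred$weights
  } else {
    W <- as.matrix(pred)
  }
  idx <- which(W != 0, arr.ind = TRUE)
  genes <- rownames(W)
  data.frame(
    regulator = genes[idx[, 2]],
    target = genes[idx[, 1]],
    sign = ifelse(W[idx] > 0, "+", "-"),
    weight = W[idx]
  )
}

gold_weight_matrix <- function(gold) {
  W <- gold$adjacency * ifelse(gold$sign == 0, 1, gold$sign)
  dimnames(W) <- list(gold$gene_names, gold$gene_names)
  W
}

#' Read a signed edge list as a gold standard
#'
#' @param path TSV with `regulator`, `target` and optional `sign` columns
#'   (signs as `+`/`-` or numeric).
#' @param gene_names gene panel; defaults to the genes appearing in the file.
#' @return a [gold_standard()].
#' @export
read_edge_list <- function(path, gene_names = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("regulator", "target") %in% names(df)))
    stop("edge list needs `regulator` and `target` columns")
  if (is.null(gene_names))
    gene_names <- sort(unique(c(df$regulator, df$target)))
  sgn <- if ("sign" %in% names(df))
    ifelse(df$sign %in% c("+", "1"), 1, ifelse(df$sign %in% c("-", "-1"), -1, 0))
  else rep(0, nrow(df))
  gold_standard(data.frame(regulator = df$regulator, target = df$target,
                           sign = sgn),
                gene_names = gene_names)
}

#' Write a consensus report
#'
#' Per ordered gene pair: mean, sd and Z over runs plus the retained flag.
#'
#' @param cons a [zscore_consensus()] result.
#' @param path output TSV.
#' @return invisibly, the data frame written.
#' @export
write_consensus_report <- function(cons, path) {
  stopifnot(inherits(cons, "consensus_result"))
  genes <- rownames(cons$mean)
  idx <- expand.grid(target = seq_along(genes), regulator = seq_along(genes))
  df <- data.frame(
    regulator = genes[idx$regulator],
    target = genes[idx$target],
    mean = cons$mean[cbind(idx$target, idx$regulator)],
    sd = cons$sd[cbind(idx$target, idx$regulator)],
    Z = cons$Z[cbind(idx$target, idx$regulator)],
    retained = cons$retained[cbind(idx$target, idx$regulator)]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Load expression kinetics in the wide SOS-experiment layout
#'
#' Reads one wide tab-delimited table per experiment (first column `time`,
#' one column per gene), optionally restricts to a gene subset, drops leading
#' rows that are all zero (identical initial conditions carry no dynamic
#' information), normalises each gene to (0, 1] against its maximum over all
#' experiments, and replaces remaining zeros with `zero_floor`. No data ships
#' with the package; point this at locally downloaded tables.
#'
#' @param files character vector of experiment file paths.
#' @param genes optional character subset of gene columns to keep.
#' @param zero_floor replacement for zero expression values.
#' @return an [expression_series_set()].
#' @export
read_sos_experiments <- function(files, genes = NULL, zero_floor = 1e-4) {
  raw <- read_series_dir(files)
  series <- raw$series
  times <- raw$times
  keep_genes <- raw$gene_names
  if (!is.null(genes)) {
    idx <- match_gene(genes, raw$gene_names)
    series <- lapply(series, function(s) s[, idx, drop = FALSE])
    keep_genes <- raw$gene_names[idx]
  }
  drop <- which(Reduce(`&`, lapply(series, function(s) rowSums(s != 0) == 0)))
  if (length(drop)) {
    drop <- drop[drop == seq_along(drop)]  # only leading all-zero rows
    if (length(drop)) {
      series <- lapply(series, function(s) s[-drop, , drop = FALSE])
      times <- times[-drop]
    }
  }
  normalize_series(expression_series_set(series, times, keep_genes),
                   zero_floor = zero_floor)
}
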