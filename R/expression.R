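#' Gene-expression matrix for one environment
#'
#' Thin validated wrapper around a genes x samples matrix of non-negative,
#' FPKM-like abundances, tagged with the environment (layer) it came from.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   dimnames; entries must be finite and >= 0.
#' @param layer_id environment label.
#' @return object of class `expression_matrix` (the matrix, with a `layer_id`
#'   attribute).
#' @export
expression_matrix <- function(values, layer_id) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene and sample identifiers as dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicated gene or sample identifiers", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  structure(values, layer_id = as.character(layer_id), class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "<expression_matrix> layer '", attr(x, "layer_id"), "': ",
    nrow(x), " genes x ", ncol(x), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write an expression matrix as CSV
#'
#' Genes in rows, samples in columns, first column `gene` holding gene
#' identifiers (the on-disk convention used throughout the package).
#'
#' @param path CSV file path.
#' @param layer_id environment label to attach.
#' @return [expression_matrix()].
#' @export
read_expression_csv <- function(path, layer_id) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes
  expression_matrix(values, layer_id)
}

#' @rdname read_expression_csv
#' @param expr an [expression_matrix()].
#' @export
write_expression_csv <- function(expr, path) {
  tab <- tibble::as_tibble(unclass(expr), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene = rownames(expr)), tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Median expression summary per gene and layer
#'
#' For each requested gene in each expression matrix, the log10 of the median
#' expression across samples. Genes whose median is zero are recorded as
#' missing (`NA`) with a warning, since log10 is undefined there.
#'
#' @param expr_list list of [expression_matrix()] objects (one per layer).
#' @param gene_ids genes to summarise (default: all genes of the first layer).
#' @return tibble with columns `layer`, `gene`, `median_expression`,
#'   `log10_median`.
#' @export
expression_summary <- function(expr_list, gene_ids = NULL) {
  if (inherits(expr_list, "expression_matrix")) expr_list <- list(expr_list)
  gene_ids <- gene_ids %||% rownames(expr_list[[1]])
  out <- purrr::map_dfr(expr_list, function(e) {
    med <- apply(unclass(e)[gene_ids, , drop = FALSE], 1, stats::median)
    tibble::tibble(
      layer = attr(e, "layer_id"),
      gene = gene_ids,
      median_expression = unname(med)
    )
  })
  if (any(out$median_expression == 0)) {
    warning(
      sum(out$median_expression == 0),
      " gene/layer combination(s) with zero median expression recorded as missing",
      call. = FALSE
    )
  }
  out$log10_median <- ifelse(out$median_expression > 0, log10(out$median_expression), NA_real_)
  out
}
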