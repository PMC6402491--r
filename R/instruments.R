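#' Filter summary records by association p-value
#'
#' Retains exactly the records with `pvalue` strictly below the threshold
#' (the genome-wide significance convention `p < 5e-8`), preserving input
#' order.
#'
#' @param records A data frame with a `pvalue` column.
#' @param threshold Significance threshold in (0, 1); default `5e-8`.
#' @return The subset of `records` passing the filter.
#' @export
filter_by_pvalue <- function(records, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  out <- records[!is.na(records$pvalue) & records$pvalue < threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise LD r-squared from allele dosages
#'
#' Computes the matrix of squared Pearson correlations between dosage
#' columns, the standard linkage-disequilibrium r² between variants.
#'
#' @param genotypes Numeric matrix of allele dosages in \[0, 2\],
#'   individuals as rows, SNPs as columns (column names = snp ids).
#' @return A symmetric matrix of class `"ld_matrix"` with unit diagonal and
#'   snp ids as dimnames.
#' @export
compute_ld_r2 <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2) stop("need at least 2 individuals")
  if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance SNP(s): ",
         paste(colnames(genotypes)[v == 0], collapse = ", "))
  r2 <- stats::cor(genotypes)^2
  diag(r2) <- 1
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Greedy LD pruning of instruments
#'
#' Selects an independent instrument set by greedy pruning: repeatedly take
#' the remaining record with the smallest p-value (ties broken by
#' lexicographic `snp_id` for determinism) and drop every remaining record
#' whose r² with it exceeds the threshold. No retained pair exceeds the
#' threshold; the postcondition is re-checked exhaustively on every run.
#'
#' @param records Data frame with `snp_id` and `pvalue` columns.
#' @param ld An r² matrix with dimnames covering every `snp_id` in `records`
#'   (e.g. from [compute_ld_r2()] or [read_ld_matrix()]).
#' @param r2_threshold Maximum allowed pairwise r² (default 0.1).
#' @return The retained subset of `records`, in original input order, with
#'   attribute `"pruned"` listing dropped snp ids and the index SNP each was
#'   correlated with.
#' @export
ld_prune <- function(records, ld, r2_threshold = 0.1) {
  ids <- records$snp_id
  missing <- setdiff(ids, rownames(ld))
  if (length(missing) > 0)
    stop("snp_id(s) absent from LD matrix: ", paste(missing, collapse = ", "))
  remaining <- ids
  taken <- character(0)
  pruned <- data.frame(snp_id = character(), index_snp = character(),
                       stringsAsFactors = FALSE)
  pv <- stats::setNames(records$pvalue, ids)
  while (length(remaining) > 0) {
    ord <- order(pv[remaining], remaining)  # p then lexicographic id
    idx <- remaining[ord[1]]
    taken <- c(taken, idx)
    remaining <- remaining[remaining != idx]
    if (length(remaining) > 0) {
      r2 <- ld[idx, remaining]
      drop <- remaining[r2 > r2_threshold]
      if (length(drop) > 0) {
        pruned <- rbind(pruned, data.frame(snp_id = drop, index_snp = idx,
                                           stringsAsFactors = FALSE))
        remaining <- setdiff(remaining, drop)
      }
    }
  }
  out <- records[records$snp_id %in% taken, , drop = FALSE]
  rownames(out) <- NULL
  # exhaustive postcondition check: no retained pair above threshold
  if (nrow(out) > 1) {
    sub <- ld[out$snp_id, out$snp_id]
    diag(sub) <- 0
    stopifnot(all(sub <= r2_threshold))
  }
  attr(out, "pruned") <- pruned
  out
}

#' Filter a harmonized set by imputation quality
#'
#' Removes instruments whose imputation info score falls below `min_info`
#' (strictly; the boundary value is retained by default, configurable).
#' SNPs with missing info are retained and logged by default.
#'
#' @param set An `mr_data` object.
#' @param min_info Minimum info score in \[0, 1\] (default 0.8).
#' @param info_source Optional named numeric vector `snp_id -> info`
#'   overriding the set's own `info` column.
#' @param boundary_inclusive If `TRUE` (default), `info == min_info` is
#'   retained (drop only `info < min_info`); if `FALSE` the boundary is
#'   dropped too.
#' @param missing_action `"retain"` (default) or `"drop"` for SNPs with no
#'   info score.
#' @param quiet Suppress messages about missing info scores.
#' @return The filtered `mr_data`, drop reasons appended to its `"drops"`
#'   attribute.
#' @export
filter_by_info <- function(set, min_info = 0.8, info_source = NULL,
                           boundary_inclusive = TRUE,
                           missing_action = c("retain", "drop"),
                           quiet = FALSE) {
  stopifnot(min_info >= 0, min_info <= 1)
  missing_action <- match.arg(missing_action)
  info <- if (!is.null(info_source)) {
    unname(info_source[set$snp_id])
  } else {
    set$info
  }
  is_missing <- is.na(info)
  low <- !is_missing &
    (if (boundary_inclusive) info < min_info else info <= min_info)
  drop <- low | (is_missing & missing_action == "drop")
  if (any(is_missing) && missing_action == "retain" && !quiet)
    message("filter_by_info: ", sum(is_missing),
            " SNP(s) with missing info retained")
  reason <- ifelse(low, "low-info", "missing-info")
  drops <- rbind(attr(set, "drops"),
                 data.frame(snp_id = set$snp_id[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE))
  out <- set[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  class(out) <- c("mr_data", "data.frame")
  out
}

#' Read / write a square LD r-squared matrix
#'
#' Tab-delimited square matrix with snp ids as both the header row and the
#' first column.
#'
#' @param path File path.
#' @return For `read_ld_matrix`, an `"ld_matrix"` matrix.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("LD matrix must be square with matching row/column snp ids")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric")
  if (any(m < 0 | m > 1 + 1e-12)) stop("r2 values must lie in [0, 1]")
  class(m) <- c("ld_matrix", class(m))
  m
}

#' @rdname read_ld_matrix
#' @param ld An r² matrix with snp-id dimnames.
#' @export
write_ld_matrix <- function(ld, path) {
  m <- unclass(ld)
  df <- data.frame(snp_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix (individuals x SNPs)
#'
#' Tab-delimited with a header row of snp ids; values are allele dosages
#' in \[0, 2\].
#'
#' @param path File path.
#' @return Numeric matrix, individuals as rows.
#' @export
read_genotypes <- function(path) {
  as.matrix(utils::read.delim(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}
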