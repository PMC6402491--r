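#' Canonical summary-statistic column names
#'
#' The column vocabulary used throughout the package for per-SNP GWAS
#' summary associations: variant identifier, effect and other allele,
#' effect-allele frequency, log-odds effect estimate, its standard error,
#' the association p-value and the imputation quality (info) score.
#'
#' @return Character vector of the eight canonical column names.
#' @export
sumstats_columns <- function() {
  c("snp_id", "effect_allele", "other_allele", "eaf",
    "beta", "se", "pvalue", "info")
}

.VALID_ALLELES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary-association file (optionally gzipped) into a
#' validated data frame with the canonical columns of [sumstats_columns()].
#' Rows that cannot serve as instruments are rejected with a recorded reason:
#' non-positive standard errors, p-values outside (0, 1], and alleles that are
#' not single A/C/G/T bases (indels, multi-allelic codes). Rejections are
#' reported via `message()` and kept in the `"rejected"` attribute.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (names of the vector) to the column names used in the file, e.g.
#'   `c(beta = "logOR")`. Unmapped canonical names are looked up as-is.
#'   `eaf` and `info` are optional columns; all others must be present.
#' @param quiet Suppress per-row rejection messages.
#' @return A `data.frame` of class `"gwas_sumstats"` with canonical columns,
#'   one row per retained variant, input order preserved. Attribute
#'   `"rejected"` holds a data frame with columns `line`, `snp_id`, `reason`.
#' @export
read_summary_stats <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "."))
  canon <- sumstats_columns()
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canon)
    if (length(bad) > 0)
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  optional <- c("eaf", "info")
  for (cn in canon) {
    if (!(map[[cn]] %in% names(raw))) {
      if (cn %in% optional) next
      stop("required column '", map[[cn]], "' (", cn,
           ") not found in ", path)
    }
  }

  n <- nrow(raw)
  out <- data.frame(
    snp_id = as.character(raw[[map[["snp_id"]]]]),
    effect_allele = toupper(as.character(raw[[map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[map[["other_allele"]]]])),
    eaf = .num_col(raw, map[["eaf"]], n, path),
    beta = .num_col(raw, map[["beta"]], n, path),
    se = .num_col(raw, map[["se"]], n, path),
    pvalue = .num_col(raw, map[["pvalue"]], n, path),
    info = .num_col(raw, map[["info"]], n, path),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n)
  snp_ok <- out$effect_allele %in% .VALID_ALLELES &
    out$other_allele %in% .VALID_ALLELES &
    out$effect_allele != out$other_allele
  reason[!snp_ok] <- "non-SNP or identical alleles"
  bad_se <- is.na(reason) & (is.na(out$se) | out$se <= 0)
  reason[bad_se] <- "non-positive or missing SE"
  bad_p <- is.na(reason) & (is.na(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1)
  reason[bad_p] <- "p-value outside (0, 1]"
  bad_beta <- is.na(reason) & is.na(out$beta)
  reason[bad_beta] <- "missing beta"

  rejected <- data.frame(line = which(!is.na(reason)) + 1L,
                         snp_id = out$snp_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0 && !quiet)
    message("read_summary_stats: rejected ", nrow(rejected), " row(s): ",
            paste(sprintf("%s (%s)", rejected$snp_id, rejected$reason),
                  collapse = "; "))
  out <- out[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

# parse one numeric column; NA introduced by coercion of a non-missing token
# is a row-level format error naming the 1-based file line
.num_col <- function(raw, name, n, path) {
  if (!(name %in% names(raw))) return(rep(NA_real_, n))
  x <- raw[[name]]
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "")
  if (length(bad) > 0)
    stop("unparseable numeric value '", x[bad[1]], "' in column '", name,
         "' at line ", bad[1] + 1L, " of ", path)
  v
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_stats()]: writes the canonical columns as
#' tab-delimited text with a header row.
#'
#' @param x A `gwas_sumstats` data frame (or any data frame with the
#'   canonical columns).
#' @param path Output file path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  cols <- intersect(sumstats_columns(), names(x))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Places paired exposure/outcome associations on a common effect-allele
#' orientation, following the two-sample MR convention: every instrument is
#' first oriented so its exposure effect is positive (the effect allele is
#' the exposure-risk-increasing allele), then the outcome record is aligned
#' to that allele, attempting a strand flip (A<->T, C<->G) before declaring an
#' allele mismatch. Palindromic variants (A/T or C/G pairs), whose strand
#' cannot be resolved from allele labels, are handled per `palindrome_policy`.
#'
#' @param exposure,outcome Data frames with the canonical columns of
#'   [sumstats_columns()] (e.g. from [read_summary_stats()]). `snp_id` must
#'   be unique within each.
#' @param palindrome_policy One of `"infer_by_eaf"` (orient palindromic SNPs
#'   by comparing effect-allele frequencies against 0.5, dropping those whose
#'   frequency on either side is too close to 0.5 to call, or missing),
#'   `"drop_ambiguous"` (drop all palindromic SNPs), or `"keep"` (align by
#'   allele labels alone, ignoring the strand ambiguity).
#' @param eaf_ambiguity_window Half-width of the frequency window around 0.5
#'   inside which a palindromic SNP is considered unresolvable under
#'   `"infer_by_eaf"` (default 0.08, i.e. drop when eaf is in (0.42, 0.58)).
#' @return An object of class `"mr_data"`: a data frame with columns
#'   `snp_id`, `gamma`, `se_gamma`, `beta`, `se_beta`, `eaf`, `info`
#'   (outcome info score) and attribute `"drops"` recording every excluded
#'   SNP with its reason.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop_ambiguous",
                                            "keep"),
                      eaf_ambiguity_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (nm in c("exposure", "outcome")) {
    df <- get(nm)
    dup <- df$snp_id[duplicated(df$snp_id)]
    if (length(dup) > 0)
      stop("duplicate snp_id in ", nm, ": ", paste(unique(dup), collapse = ", "))
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) stop("no shared instruments")

  drops <- data.frame(snp_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  only_exp <- setdiff(exposure$snp_id, shared)
  only_out <- setdiff(outcome$snp_id, shared)
  if (length(only_exp) + length(only_out) > 0)
    drops <- rbind(drops, data.frame(snp_id = c(only_exp, only_out),
                                     reason = "unmatched",
                                     stringsAsFactors = FALSE))

  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  # orient exposure so gamma >= 0 (effect allele = risk-increasing allele)
  flip <- !is.na(ex$beta) & ex$beta < 0
  ex$beta[flip] <- -ex$beta[flip]
  ex$eaf[flip] <- 1 - ex$eaf[flip]
  tmp <- ex$effect_allele[flip]
  ex$effect_allele[flip] <- ex$other_allele[flip]
  ex$other_allele[flip] <- tmp

  n <- length(shared)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  is_palin <- .COMPLEMENT[ex$effect_allele] == ex$other_allele

  for (i in seq_len(n)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    oea <- ou$effect_allele[i]; ooa <- ou$other_allele[i]

    if (is_palin[i]) {
      if (palindrome_policy == "drop_ambiguous") {
        keep[i] <- FALSE; reason[i] <- "palindromic"; next
      }
      # letters alone cannot distinguish same-strand from flipped-strand
      if (!((oea == ea && ooa == oa) || (oea == oa && ooa == ea))) {
        keep[i] <- FALSE; reason[i] <- "allele-mismatch"; next
      }
      aligned_beta <- if (oea == ea) ou$beta[i] else -ou$beta[i]
      aligned_eaf <- if (oea == ea) ou$eaf[i] else 1 - ou$eaf[i]
      if (palindrome_policy == "keep") {
        beta_out[i] <- aligned_beta; eaf_out[i] <- aligned_eaf; next
      }
      # infer_by_eaf: both frequencies must be informative and outside the
      # ambiguity window around 0.5
      if (is.na(ex$eaf[i]) || is.na(aligned_eaf) ||
          abs(ex$eaf[i] - 0.5) < eaf_ambiguity_window ||
          abs(aligned_eaf - 0.5) < eaf_ambiguity_window) {
        keep[i] <- FALSE; reason[i] <- "palindromic-ambiguous"; next
      }
      if (sign(ex$eaf[i] - 0.5) != sign(aligned_eaf - 0.5)) {
        # frequencies disagree: the outcome record is on the other strand
        aligned_beta <- -aligned_beta
        aligned_eaf <- 1 - aligned_eaf
      }
      beta_out[i] <- aligned_beta; eaf_out[i] <- aligned_eaf
      next
    }

    if (oea == ea && ooa == oa) {
      # already aligned
    } else if (oea == oa && ooa == ea) {
      beta_out[i] <- -ou$beta[i]; eaf_out[i] <- 1 - ou$eaf[i]
    } else {
      cea <- .COMPLEMENT[[oea]]; coa <- .COMPLEMENT[[ooa]]
      if (cea == ea && coa == oa) {
        # strand flip only
      } else if (cea == oa && coa == ea) {
        beta_out[i] <- -ou$beta[i]; eaf_out[i] <- 1 - ou$eaf[i]
      } else {
        keep[i] <- FALSE; reason[i] <- "allele-mismatch"
      }
    }
  }

  if (any(!keep))
    drops <- rbind(drops, data.frame(snp_id = shared[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE))
  mr_data(
    snp_id = shared[keep],
    gamma = ex$beta[keep],
    se_gamma = ex$se[keep],
    beta = beta_out[keep],
    se_beta = ou$se[keep],
    eaf = ex$eaf[keep],
    info = ou$info[keep],
    drops = drops
  )
}

#' Construct a harmonized instrument set
#'
#' Validated container for paired exposure/outcome effects on a common
#' effect-allele orientation; the unit of data every estimator in the
#' package consumes.
#'
#' @param snp_id Character vector of variant identifiers (unique).
#' @param gamma,se_gamma Exposure (instrument-exposure) log-odds effects and
#'   standard errors; `gamma` must be non-negative under the
#'   exposure-increasing orientation convention.
#' @param beta,se_beta Outcome (instrument-outcome) log-odds effects and
#'   standard errors.
#' @param eaf,info Optional effect-allele frequency and outcome imputation
#'   info score per SNP.
#' @param drops Optional data frame (`snp_id`, `reason`) of excluded SNPs.
#' @return A data frame of class `"mr_data"`.
#' @export
mr_data <- function(snp_id, gamma, se_gamma, beta, se_beta,
                    eaf = NA_real_, info = NA_real_, drops = NULL) {
  x <- data.frame(snp_id = as.character(snp_id),
                  gamma = as.numeric(gamma),
                  se_gamma = as.numeric(se_gamma),
                  beta = as.numeric(beta),
                  se_beta = as.numeric(se_beta),
                  eaf = as.numeric(eaf),
                  info = as.numeric(info),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$snp_id))
    stop("duplicate snp_id in harmonized set: ",
         x$snp_id[duplicated(x$snp_id)][1])
  if (any(is.na(x$gamma) | is.na(x$beta)))
    stop("gamma and beta must be non-missing")
  if (any(x$se_gamma <= 0 | x$se_beta <= 0, na.rm = TRUE) ||
      any(is.na(x$se_gamma) | is.na(x$se_beta)))
    stop("standard errors must be positive")
  if (any(x$gamma < 0))
    stop("gamma must be >= 0 under the exposure-increasing orientation")
  if (is.null(drops))
    drops <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  attr(x, "drops") <- drops
  class(x) <- c("mr_data", "data.frame")
  x
}

#' @export
print.mr_data <- function(x, ...) {
  cat("Harmonized two-sample MR instrument set:", nrow(x), "SNPs\n")
  drops <- attr(x, "drops")
  if (!is.null(drops) && nrow(drops) > 0) {
    tab <- table(drops$reason)
    cat("Dropped", nrow(drops), "SNP(s):",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write a harmonized set as tab-delimited text
#'
#' Emits one row per SNP (retained and dropped) with columns `snp_id`,
#' `gamma`, `se_gamma`, `beta`, `se_beta`, `drop_reason` (empty for retained
#' SNPs, whose numeric fields are populated).
#'
#' @param x An `mr_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_data <- function(x, path) {
  main <- data.frame(snp_id = x$snp_id, gamma = x$gamma,
                     se_gamma = x$se_gamma, beta = x$beta,
                     se_beta = x$se_beta, drop_reason = "",
                     stringsAsFactors = FALSE)
  drops <- attr(x, "drops")
  if (!is.null(drops) && nrow(drops) > 0)
    main <- rbind(main,
                  data.frame(snp_id = drops$snp_id, gamma = NA_real_,
                             se_gamma = NA_real_, beta = NA_real_,
                             se_beta = NA_real_, drop_reason = drops$reason,
                             stringsAsFactors = FALSE))
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a harmonized set written by [write_mr_data()]
#'
#' @param path Path to the tab-delimited file.
#' @return An `mr_data` object (dropped rows restored into the `"drops"`
#'   attribute).
#' @export
read_mr_data <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (is.null(df$drop_reason)) df$drop_reason <- NA_character_
  dropped <- !is.na(df$drop_reason) & df$drop_reason != ""
  mr_data(snp_id = df$snp_id[!dropped],
          gamma = df$gamma[!dropped],
          se_gamma = df$se_gamma[!dropped],
          beta = df$beta[!dropped],
          se_beta = df$se_beta[!dropped],
          drops = data.frame(snp_id = df$snp_id[dropped],
                             reason = df$drop_reason[dropped],
                             stringsAsFactors = FALSE))
}
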