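#' Run the full two-sample MR pipeline
#'
#' Orchestrates the complete analysis from a configuration: significance
#' filtering of the exposure GWAS, optional greedy LD pruning, per-stratum
#' harmonization against each outcome table, MR-PRESSO outlier exclusion,
#' IVW (random-effects) and weighted-median estimation with heterogeneity
#' diagnostics, and an optional imputation-quality sensitivity re-analysis.
#' Every excluded SNP is logged exactly once with its stage and reason.
#'
#' The configuration is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{exposure_path}{Exposure summary-statistics TSV.}
#'   \item{outcome_paths}{Named list/vector: stratum label -> outcome TSV
#'     (e.g. `overall`, `er_positive`, `er_negative`).}
#'   \item{ld_source}{Optional list with one of `genotypes` (dosage-matrix
#'     path) or `r2_matrix` (square r² matrix path); omit to skip pruning.}
#'   \item{p_threshold}{Instrument significance threshold (default 5e-8).}
#'   \item{ld_r2_threshold}{Pruning threshold (default 0.1).}
#'   \item{min_info}{Optional info-score cutoff for the sensitivity
#'     re-analysis (e.g. 0.8); omit to skip.}
#'   \item{palindrome_policy, eaf_ambiguity_window}{Passed to
#'     [harmonize()].}
#'   \item{presso}{List: `n_sim` (default 5000), `seed` (required),
#'     `alpha_level` (default 0.05), `per_stratum` (default `FALSE`: the
#'     exclusion list is computed once on the first stratum — the overall
#'     outcome — and applied to all strata), `skip` (default `FALSE`).}
#'   \item{estimator}{List: `n_boot` (default 1000), `seed` (required for
#'     the weighted median).}
#'   \item{output_dir}{Optional; when set, [render_report()] is called.}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @return Object of class `"mr_report"`: per-stratum fits, heterogeneity,
#'   the PRESSO report, stage-by-stage instrument counts (checked to be
#'   non-increasing) and the exclusion log.
#' @export
mr_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .pipeline_defaults(config)

  exposure <- read_summary_stats(cfg$exposure_path, cfg$exposure_column_map,
                                 quiet = TRUE)
  n_initial <- nrow(exposure)
  exclusions <- .excl(attr(exposure, "rejected")$snp_id, "read",
                      attr(exposure, "rejected")$reason)

  exposure <- filter_by_pvalue(exposure, cfg$p_threshold)
  if (nrow(exposure) == 0) stop("pipeline stage 'significance': empty instrument set")
  n_significant <- nrow(exposure)

  if (!is.null(cfg$ld_source)) {
    ld <- if (!is.null(cfg$ld_source$r2_matrix)) {
      read_ld_matrix(cfg$ld_source$r2_matrix)
    } else if (!is.null(cfg$ld_source$genotypes)) {
      compute_ld_r2(read_genotypes(cfg$ld_source$genotypes))
    } else stop("pipeline stage 'ld': ld_source needs 'genotypes' or 'r2_matrix'")
    exposure <- ld_prune(exposure, ld, cfg$ld_r2_threshold)
    pr <- attr(exposure, "pruned")
    exclusions <- rbind(exclusions,
                        .excl(pr$snp_id, "ld_prune",
                              paste0("r2>", cfg$ld_r2_threshold, " with ",
                                     pr$index_snp)))
  }
  n_post_ld <- nrow(exposure)
  if (n_post_ld == 0) stop("pipeline stage 'ld': empty instrument set")

  strata <- names(cfg$outcome_paths)
  harmonized <- list()
  for (s in strata) {
    outcome <- read_summary_stats(cfg$outcome_paths[[s]],
                                  cfg$outcome_column_map, quiet = TRUE)
    h <- harmonize(exposure, outcome,
                   palindrome_policy = cfg$palindrome_policy,
                   eaf_ambiguity_window = cfg$eaf_ambiguity_window)
    if (nrow(h) == 0) stop("pipeline stage 'harmonize': empty instrument set (", s, ")")
    harmonized[[s]] <- h
    if (s == strata[1]) {
      d <- attr(h, "drops")
      d <- d[d$reason != "unmatched" | d$snp_id %in% exposure$snp_id, ,
             drop = FALSE]
      exclusions <- rbind(exclusions, .excl(d$snp_id, "harmonize", d$reason))
    }
  }

  n_harmonized <- vapply(harmonized, nrow, integer(1))

  presso_reports <- list()
  if (!isTRUE(cfg$presso$skip)) {
    presso_on <- if (isTRUE(cfg$presso$per_stratum)) strata else strata[1]
    for (s in presso_on)
      presso_reports[[s]] <- mr_presso(harmonized[[s]],
                                       n_sim = cfg$presso$n_sim,
                                       seed = cfg$presso$seed,
                                       alpha_level = cfg$presso$alpha_level)
    shared_outliers <- presso_reports[[strata[1]]]$outlier_ids
    exclusions <- rbind(exclusions,
                        .excl(shared_outliers, "presso",
                              "horizontally pleiotropic outlier"))
    for (s in strata) {
      excl_ids <- if (isTRUE(cfg$presso$per_stratum))
        presso_reports[[s]]$outlier_ids else shared_outliers
      h <- harmonized[[s]]
      keep <- !(h$snp_id %in% excl_ids)
      hh <- h[keep, , drop = FALSE]
      attr(hh, "drops") <- attr(h, "drops")
      class(hh) <- class(h)
      harmonized[[s]] <- hh
    }
  }

  results <- list()
  for (s in strata) {
    h <- harmonized[[s]]
    res <- .estimate_stratum(h, cfg)
    res$counts <- c(initial = n_initial, significant = n_significant,
                    post_ld = n_post_ld,
                    harmonized = n_harmonized[[s]],
                    post_presso = nrow(h))
    if (!is.null(cfg$min_info)) {
      h_info <- filter_by_info(h, cfg$min_info, quiet = TRUE)
      d <- attr(h_info, "drops")
      d <- d[d$reason %in% c("low-info", "missing-info"), , drop = FALSE]
      if (s == strata[1])
        exclusions <- rbind(exclusions, .excl(d$snp_id, "info_filter",
                                              d$reason))
      res$sensitivity <- .estimate_stratum(h_info, cfg)
      res$counts <- c(res$counts, post_info = nrow(h_info))
    }
    stopifnot(all(diff(res$counts[-1]) <= 0))  # stage-count monotonicity
    results[[s]] <- res
  }

  report <- structure(list(strata = results, presso = presso_reports,
                           exclusions = exclusions, config = cfg),
                      class = "mr_report")
  if (!is.null(cfg$output_dir)) render_report(report, cfg$output_dir)
  report
}

.estimate_stratum <- function(h, cfg) {
  ivw <- mr_fit(h, method = "ivw_random")
  wm <- if (nrow(h) >= 3)
    mr_fit(h, method = "weighted_median", n_boot = cfg$estimator$n_boot,
           seed = cfg$estimator$seed) else NULL
  list(ivw_random = ivw, weighted_median = wm,
       heterogeneity = ivw$heterogeneity)
}

.pipeline_defaults <- function(config) {
  cfg <- utils::modifyList(
    list(p_threshold = 5e-8, ld_r2_threshold = 0.1, min_info = NULL,
         palindrome_policy = "infer_by_eaf", eaf_ambiguity_window = 0.08,
         ld_source = NULL, output_dir = NULL,
         exposure_column_map = NULL, outcome_column_map = NULL,
         presso = list(), estimator = list()),
    config)
  cfg$presso <- utils::modifyList(
    list(n_sim = 5000, seed = NULL, alpha_level = 0.05,
         per_stratum = FALSE, skip = FALSE), cfg$presso)
  cfg$estimator <- utils::modifyList(
    list(n_boot = 1000, seed = NULL), cfg$estimator)
  if (is.null(cfg$exposure_path) || is.null(cfg$outcome_paths))
    stop("config requires exposure_path and outcome_paths")
  if (is.null(names(cfg$outcome_paths)))
    names(cfg$outcome_paths) <- paste0("stratum", seq_along(cfg$outcome_paths))
  if (!isTRUE(cfg$presso$skip) && is.null(cfg$presso$seed))
    stop("config requires presso$seed")
  if (is.null(cfg$estimator$seed))
    stop("config requires estimator$seed")
  cfg
}

.excl <- function(ids, stage, reason) {
  if (length(ids) == 0)
    return(data.frame(snp_id = character(), stage = character(),
                      reason = character(), stringsAsFactors = FALSE))
  data.frame(snp_id = ids, stage = stage, reason = reason,
             stringsAsFactors = FALSE)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR analysis report\n")
  for (s in names(x$strata)) {
    cat("\n== Stratum:", s, "==\n")
    print(x$strata[[s]]$ivw_random)
    if (!is.null(x$strata[[s]]$weighted_median))
      print(x$strata[[s]]$weighted_median)
    print(x$strata[[s]]$heterogeneity)
    cat("Instrument counts:",
        paste(names(x$strata[[s]]$counts), x$strata[[s]]$counts,
              sep = "=", collapse = ", "), "\n")
  }
  if (length(x$presso) > 0) {
    cat("\n")
    print(x$presso[[1]])
  }
  invisible(x)
}

#' Render an analysis report to files
#'
#' Writes, under `dir`: one results table per stratum and a combined table
#' (`results_<stratum>.tsv`, `results_combined.tsv`) with columns
#' `stratum`, `analysis`, `method`, `n_snps`, `or`, `or_ci_low`,
#' `or_ci_high`, `or_display` (OR rounded to 2 decimals with its CI),
#' `pvalue` (2 significant figures in the display column, full precision in
#' `pvalue`), `p_het` and `i2_percent`; the exclusion log
#' (`exclusions.tsv`); and a machine-readable `report.json`.
#'
#' @param report An `mr_report` object.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (default) or `"text"` for a fixed-width table
#'   printed alongside the TSVs.
#' @return Named vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, format = c("tsv", "text")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in names(report$strata)) {
    st <- report$strata[[s]]
    rows[[length(rows) + 1]] <- .report_row(s, "main", st)
    if (!is.null(st$sensitivity))
      rows[[length(rows) + 1]] <- .report_row(s, "info_sensitivity",
                                              st$sensitivity)
  }
  tab <- do.call(rbind, rows)
  paths <- c(combined = file.path(dir, "results_combined.tsv"))
  utils::write.table(tab, paths["combined"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in unique(tab$stratum)) {
    p <- file.path(dir, paste0("results_", s, ".tsv"))
    utils::write.table(tab[tab$stratum == s, , drop = FALSE], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[s] <- p
  }
  paths["exclusions"] <- file.path(dir, "exclusions.tsv")
  utils::write.table(report$exclusions, paths["exclusions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["json"] <- file.path(dir, "report.json")
  json <- list()
  for (s in names(report$strata)) {
    st <- report$strata[[s]]
    json[[s]] <- list(
      ivw_random = .fit_kv(st$ivw_random),
      weighted_median = if (!is.null(st$weighted_median))
        .fit_kv(st$weighted_median) else NULL,
      heterogeneity = unclass(st$heterogeneity)[c("q", "df", "p_het", "i2")],
      counts = as.list(st$counts))
    if (!is.null(st$sensitivity))
      json[[s]]$info_sensitivity <- list(
        ivw_random = .fit_kv(st$sensitivity$ivw_random),
        weighted_median = if (!is.null(st$sensitivity$weighted_median))
          .fit_kv(st$sensitivity$weighted_median) else NULL,
        heterogeneity = unclass(st$sensitivity$heterogeneity)[c("q", "df",
                                                               "p_het", "i2")])
  }
  if (length(report$presso) > 0)
    json$presso <- lapply(report$presso, function(p)
      list(global_rss = p$global_rss_obs, global_p = p$global_p,
           outliers = as.list(p$outlier_ids), distortion_p = p$distortion_p,
           n_sim = p$n_sim, seed = p$seed))
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (format == "text") {
    paths["text"] <- file.path(dir, "results_combined.txt")
    writeLines(utils::capture.output(print(tab, row.names = FALSE)),
               paths["text"])
  }
  invisible(paths)
}

.report_row <- function(stratum, analysis, st) {
  row1 <- .method_row(stratum, analysis, st$ivw_random, st$heterogeneity)
  row2 <- if (!is.null(st$weighted_median)) {
    .method_row(stratum, analysis, st$weighted_median, NULL)
  } else {
    data.frame(stratum = stratum, analysis = analysis,
               method = "weighted_median", n_snps = NA_integer_,
               or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
               or_display = "-", pvalue = NA_real_, p_display = "-",
               p_het = NA_real_, i2_percent = NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(row1, row2)
}

.method_row <- function(stratum, analysis, fit, het) {
  or <- odds_ratios(fit)
  data.frame(
    stratum = stratum, analysis = analysis, method = fit$method,
    n_snps = fit$n_snps, or = or$or, or_ci_low = or$ci_low,
    or_ci_high = or$ci_high,
    or_display = sprintf("%.2f (%.2f-%.2f)", or$rounded["or"],
                         or$rounded["ci_low"], or$rounded["ci_high"]),
    pvalue = fit$pvalue, p_display = format(signif(fit$pvalue, 2)),
    p_het = if (!is.null(het)) het$p_het else NA_real_,
    i2_percent = if (!is.null(het)) het$i2 else NA_real_,
    stringsAsFactors = FALSE)
}

.fit_kv <- function(fit) {
  or <- odds_ratios(fit)
  list(alpha = fit$alpha, se = fit$se_alpha, ci_low = fit$ci_low,
       ci_high = fit$ci_high, pvalue = fit$pvalue, n_snps = fit$n_snps,
       or = or$or, or_ci_low = or$ci_low, or_ci_high = or$ci_high)
}
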