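# shared fixtures, built in code

# a small well-formed summary-stats data frame
make_sumstats <- function(n = 3, beta = seq(0.05, by = 0.01, length.out = n),
                          se = rep(0.01, n), pvalue = rep(1e-10, n),
                          ea = rep("A", n), oa = rep("G", n),
                          eaf = rep(0.3, n), info = rep(0.95, n),
                          ids = sprintf("rs%d", seq_len(n))) {
  data.frame(snp_id = ids, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, info = info,
             stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# harmonized set straight from numbers
make_mr_data <- function(gamma, beta, se_gamma = 0.01, se_beta = 0.002,
                         ids = sprintf("rs%d", seq_along(gamma))) {
  mr_data(snp_id = ids, gamma = gamma,
          se_gamma = rep_len(se_gamma, length(gamma)),
          beta = beta, se_beta = rep_len(se_beta, length(gamma)))
}

# independent brute-force IVW oracle: plain loops over the printed formulas
oracle_ivw <- function(gamma, se_gamma, beta, se_beta) {
  n <- length(gamma)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    a_i <- beta[i] / gamma[i]
    v_i <- (se_beta[i] / gamma[i])^2
    w_i <- 1 / v_i
    num <- num + a_i * w_i
    den <- den + w_i
  }
  alpha <- num / den
  q <- 0
  for (i in seq_len(n)) {
    a_i <- beta[i] / gamma[i]
    w_i <- (gamma[i] / se_beta[i])^2
    q <- q + w_i * (a_i - alpha)^2
  }
  list(alpha = alpha, se = den^(-1 / 2), q = q)
}

# independent unweighted/weighted median oracle via cumulative-weight scan
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  for (j in 2:length(r))
    if (s[j] >= 0.5)
      return(r[j - 1] + (r[j] - r[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1]))
  r[length(r)]
}
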