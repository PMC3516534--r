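#' Orient summary statistics to the risk direction
#'
#' Flips effect/other allele labels and negates the effect size wherever
#' needed so that every record's effect allele is the risk-increasing (or,
#' with `risk_direction = "decreasing"`, risk-decreasing) allele. Records
#' with an effect of exactly zero have no defined direction; they are kept
#' unchanged and flagged in the `zero_effect` column.
#'
#' @param records Summary-statistic data.frame (see [read_sumstats()]).
#' @param risk_direction `"increasing"` (default) or `"decreasing"`.
#' @return The records with all effects oriented (`beta >= 0` for
#'   `"increasing"`), plus a logical `zero_effect` column.
#' @export
orient_to_risk <- function(records, risk_direction = c("increasing",
                                                       "decreasing")) {
  risk_direction <- match.arg(risk_direction)
  flip <- if (risk_direction == "increasing") records$beta < 0
          else records$beta > 0
  a1 <- ifelse(flip, records$other_allele, records$effect_allele)
  a2 <- ifelse(flip, records$effect_allele, records$other_allele)
  records$effect_allele <- a1
  records$other_allele <- a2
  records$beta <- ifelse(flip, -records$beta, records$beta)
  records$zero_effect <- records$beta == 0
  records
}

#' Pooled effect of an unweighted multi-SNP risk score
#'
#' Estimates the per-risk-allele effect of an unweighted genetic risk score
#' (an individual's count of risk alleles over the SNP panel) on a
#' quantitative trait using only per-SNP summary statistics, assuming
#' linkage equilibrium between the SNPs (caller's responsibility). With
#' weights `w_j`, the pooled effect is
#' `beta_score = sum(w_j * beta_j) / sum(w_j)` with standard error
#' `sqrt(sum(w_j^2 * se_j^2)) / sum(w_j)`; significance comes from
#' `z = beta_score / se_score` against the standard normal.
#'
#' Two weighting conventions are exposed: inverse-variance `w_j = 1/se_j^2`
#' (the default, under which the pooled estimate matches the individual-
#' level regression of the trait on the allele-count score under linkage
#' equilibrium, and `se_score = 1/sqrt(sum(1/se_j^2))`), and `w_j = 1/se_j`.
#'
#' @param records Summary statistics oriented to the risk direction (see
#'   [orient_to_risk()]); at least one record, all `se > 0`.
#' @param weighting `"ivw"` (inverse variance, default) or `"inv_se"`.
#' @return Object of class `risk_score`: list with `n_snps`, `beta_score`,
#'   `se_score`, `z`, `p` (two-sided normal), `weighting`.
#' @export
score_effect <- function(records, weighting = c("ivw", "inv_se")) {
  weighting <- match.arg(weighting)
  if (nrow(records) < 1L) stop("no SNP records", call. = FALSE)
  if (any(!(records$se > 0))) stop("all se must be > 0", call. = FALSE)
  w <- if (weighting == "ivw") 1 / records$se^2 else 1 / records$se
  beta <- sum(w * records$beta) / sum(w)
  se <- sqrt(sum(w^2 * records$se^2)) / sum(w)
  z <- beta / se
  structure(list(n_snps = nrow(records), beta_score = beta, se_score = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)), weighting = weighting),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat("Multi-SNP risk score (", x$n_snps, " SNPs, ", x$weighting,
      " weights)\n", sep = "")
  cat("  effect ", format(x$beta_score, digits = 4), " (se ",
      format(x$se_score, digits = 4), "), z = ", format(x$z, digits = 4),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Risk-score test for a gene set's best SNPs
#'
#' Looks up one best SNP per gene region in a trait's summary statistics
#' (duplicated SNP ids are pooled once), orients all effects to the
#' risk-increasing direction, and pools them with [score_effect()]. SNPs
#' absent from the trait file are dropped with a message.
#'
#' @param best_snps Character vector of SNP ids (one per gene region).
#' @param trait_sumstats Summary statistics for the trait (see
#'   [read_sumstats()]).
#' @param weighting Passed to [score_effect()].
#' @return A `risk_score` object.
#' @export
score_test_for_gene_set <- function(best_snps, trait_sumstats,
                                    weighting = "ivw") {
  snps <- unique(best_snps)
  found <- snps %in% trait_sumstats$snp
  if (any(!found))
    message(sum(!found), " SNP(s) missing from trait summary statistics")
  snps <- snps[found]
  if (length(snps) == 0L)
    stop("no risk-score SNPs found in trait summary statistics",
         call. = FALSE)
  rec <- trait_sumstats[match(snps, trait_sumstats$snp), , drop = FALSE]
  score_effect(orient_to_risk(rec), weighting = weighting)
}
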