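#' Fit the Sloan neutral community model
#'
#' The neutral community model (NCM) predicts the occurrence frequency of a
#' taxon across a metacommunity from its mean relative abundance:
#'
#'   Freq_i = 1 - BetaCDF(1/N; N m p_i, N m (1 - p_i))
#'
#' where N is the number of individuals per community (the common
#' rarefaction depth), m the immigration rate, and p_i the taxon's mean
#' relative abundance. m is fitted by bounded nonlinear least squares of
#' observed occupancy on predicted frequency; R^2 = 1 - SS_err / SS_total
#' and may be negative when the data fit the neutral expectation worse than
#' a constant (dominance of deterministic processes) — no lower clamp is
#' applied.
#'
#' @param table a `community_table` rarefied to a common depth (all column
#'   sums equal; unequal depths are rejected)
#' @param level confidence level for the occurrence-frequency prediction
#'   bounds (Wilson score interval; default 0.95)
#' @return object of class `ncm_fit`: list with `m`, `N`, `r_squared`,
#'   `n_taxa`, `n_samples`, and `taxa` (data.frame: `taxon_id`, `p`,
#'   `freq_obs`, `freq_pred`, `pred_lwr`, `pred_upr`, `class`)
#' @export
ncm_fit <- function(table, level = 0.95) {
  m_counts <- unclass(table)
  totals <- colSums(m_counts)
  if (length(unique(totals)) != 1)
    stop("sample depths unequal (", min(totals), "-", max(totals),
         "): rarefy() the table first")
  N <- unname(totals[1])
  keep <- rowSums(m_counts) > 0
  m_counts <- m_counts[keep, , drop = FALSE]
  if (nrow(m_counts) < 10) stop("need >= 10 taxa with nonzero totals")
  n_samples <- ncol(m_counts)

  occ <- occupancy(community_table_keep(m_counts))
  fit <- ncm_fit_points(occ$mean_rel_abund, occ$occupancy, N,
                        n_samples = n_samples, taxon_ids = occ$taxon_id)
  ncm_bounds(fit, n_samples = n_samples, level = level)
}

#' Fit the Sloan model to (abundance, occupancy) points
#'
#' The fitting core of [ncm_fit()], exposed for use on pre-computed
#' occupancy curves.
#'
#' @param p mean relative abundance per taxon
#' @param freq_obs observed occurrence frequency per taxon, in `[0, 1]`
#' @param N individuals (reads) per community
#' @param n_samples number of sites the frequencies were observed over
#' @param taxon_ids optional taxon labels
#' @return an `ncm_fit` (without prediction bounds; see [ncm_bounds()])
#' @export
ncm_fit_points <- function(p, freq_obs, N, n_samples = NA_integer_,
                           taxon_ids = NULL) {
  if (length(p) != length(freq_obs)) stop("p and freq_obs lengths differ")
  pred <- function(m) ncm_freq_pred(p, m, N)
  sse <- function(m) sum((freq_obs - pred(m))^2)
  opt <- optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  m_hat <- opt$minimum
  freq_pred <- pred(m_hat)
  ss_err <- sum((freq_obs - freq_pred)^2)
  ss_tot <- sum((freq_obs - mean(freq_obs))^2)
  if (is.null(taxon_ids)) taxon_ids <- sprintf("taxon_%04d", seq_along(p))
  structure(list(m = m_hat, N = N, r_squared = 1 - ss_err / ss_tot,
                 n_taxa = length(p), n_samples = n_samples,
                 taxa = data.frame(taxon_id = taxon_ids, p = p,
                                   freq_obs = freq_obs,
                                   freq_pred = freq_pred,
                                   stringsAsFactors = FALSE)),
            class = "ncm_fit")
}

#' Sloan model occurrence-frequency prediction
#'
#' `1 - BetaCDF(1/N; N m p, N m (1 - p))`: the probability that a taxon of
#' mean relative abundance `p` exceeds the one-individual detection
#' threshold in a community of `N` individuals under immigration rate `m`.
#'
#' @param p mean relative abundance
#' @param m immigration rate
#' @param N individuals per community
#' @return predicted occurrence frequency
#' @export
ncm_freq_pred <- function(p, m, N) {
  1 - pbeta(1 / N, N * m * p, N * m * (1 - p))
}

#' Prediction bounds and taxon classification for an NCM fit
#'
#' Wilson score interval for a binomial proportion with success probability
#' `freq_pred` observed over `n_samples` sites. Taxa with observed
#' occupancy above the upper bound occur more frequently than the neutral
#' prediction ("above"), below the lower bound less frequently ("below").
#'
#' @param fit an `ncm_fit`
#' @param n_samples number of sites the occupancy was observed over
#' @param level confidence level in (0, 1)
#' @return the `ncm_fit` with `pred_lwr`, `pred_upr`, `class` columns
#'   updated in `fit$taxa`
#' @export
ncm_bounds <- function(fit, n_samples = fit$n_samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  p_hat <- fit$taxa$freq_pred
  n <- n_samples
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) /
    (1 + z^2 / n)
  lwr <- pmax(0, centre - half)
  upr <- pmin(1, centre + half)
  # degenerate prediction pins the corresponding bound
  lwr[p_hat == 0] <- 0
  upr[p_hat == 1] <- 1
  cls <- ifelse(fit$taxa$freq_obs > upr, "above",
                ifelse(fit$taxa$freq_obs < lwr, "below", "within"))
  fit$taxa$pred_lwr <- lwr
  fit$taxa$pred_upr <- upr
  fit$taxa$class <- cls
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("ncm_fit: m = ", signif(x$m, 4), ", N = ", x$N, ", R^2 = ",
      signif(x$r_squared, 4), " (", x$n_taxa, " taxa, ", x$n_samples,
      " samples)\n", sep = "")
  if (!is.null(x$taxa$class))
    cat("  taxa above/within/below prediction: ",
        paste(table(factor(x$taxa$class,
                           levels = c("above", "within", "below"))),
              collapse = "/"), "\n", sep = "")
  invisible(x)
}
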