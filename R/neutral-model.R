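#' Per-taxon occurrence statistics for the neutral model
#'
#' For each taxon computes p, its mean relative abundance across samples
#' (its share of the regional pool), and f_obs, the fraction of samples in
#' which it is detected. These two vectors are what the Sloan neutral model
#' relates.
#'
#' @param table A rarefied [community_table()] (equal row sums, at least two
#'   samples). Taxa with zero total are excluded with a warning.
#' @param check_rarefied Enforce the equal-row-sum contract (default TRUE);
#'   clade-level fits disable it and supply `N` explicitly.
#' @return data.frame(taxon_id, p, f_obs) with attributes `n_samples` (S)
#'   and `N` (reads per sample).
#' @export
occurrence_stats <- function(table, check_rarefied = TRUE) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (nrow(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  totals <- rowSums(counts)
  if (check_rarefied && length(unique(totals)) != 1)
    stop("table must be rarefied (unequal row sums)", call. = FALSE)
  if (any(totals == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  col_tot <- colSums(counts)
  if (any(col_tot == 0)) {
    warning("excluding ", sum(col_tot == 0), " zero-total taxa", call. = FALSE)
    counts <- counts[, col_tot > 0, drop = FALSE]
  }
  rel <- counts / totals
  out <- data.frame(taxon_id = colnames(counts),
                    p = colMeans(rel),
                    f_obs = colMeans(counts > 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_samples") <- nrow(counts)
  attr(out, "N") <- round(mean(totals))
  out
}

#' Sloan neutral model predicted occurrence frequency
#'
#' Under the Sloan model a taxon with regional mean relative abundance p is
#' detected (local abundance above the detection limit d) with probability
#' `1 - pbeta(d, Nm * p, Nm * (1 - p))`, i.e. the upper tail of a Beta
#' distribution whose concentration is the immigration parameter Nm.
#'
#' @param p Regional mean relative abundance(s), strictly inside (0, 1).
#' @param Nm Immigration parameter (community size x migration rate), > 0.
#' @param d Detection limit in (0, 1), conventionally 1/N.
#' @return Predicted detection frequency, same length as `p`.
#' @export
ncm_predict <- function(p, Nm, d) {
  stopifnot(Nm > 0, d > 0, d < 1)
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1) (degenerate beta otherwise)",
         call. = FALSE)
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

# Wilson score interval for a binomial proportion phat with n trials, widened
# by the half-count continuity correction 1/(2n): observed frequencies move in
# steps of 1/n, and without the correction a predicted frequency within a
# fraction of a count of 0 or 1 yields a band that flags near-certain
# observations (e.g. f_pred = 0.9995, S = 33, f_obs = 1).
wilson_interval <- function(phat, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, center - half - 1 / (2 * n)),
        high = pmin(1, center + half + 1 / (2 * n)))
}

#' Fit the Sloan neutral community model
#'
#' Finds the migration rate m minimizing the sum of squared differences
#' between observed and predicted occurrence frequencies over m in
#' (1e-7, 1], by bounded least squares with multi-start; reports Nm = N * m,
#' R-squared, and a per-taxon partition against the Wilson score prediction
#' band: taxa above the band occur more often than neutrally expected, taxa
#' below less often.
#'
#' @param stats Output of [occurrence_stats()] (or any data.frame with
#'   columns p and f_obs).
#' @param N Reads per sample after rarefaction; defaults to the attribute
#'   carried by `stats`. The detection limit is d = 1/N.
#' @param ci_level Level of the prediction band (default 0.95).
#' @return An object of class `ncm_fit`: m, N, Nm, d, r_squared, n_samples,
#'   and `per_taxon` (taxon_id, p, f_obs, f_pred, ci_low, ci_high,
#'   partition).
#' @export
ncm_fit <- function(stats, N = attr(stats, "N"), ci_level = 0.95) {
  if (is.null(N)) stop("N (reads per sample) must be supplied", call. = FALSE)
  S <- attr(stats, "n_samples")
  if (is.null(S)) stop("stats must carry an n_samples attribute", call. = FALSE)
  keep <- stats$p > 0 & stats$p < 1 & stats$f_obs > 0
  st <- stats[keep, , drop = FALSE]
  if (nrow(st) < 10)
    stop("need at least 10 taxa with 0 < p < 1 to fit", call. = FALSE)
  d <- 1 / N
  sst <- sum((st$f_obs - mean(st$f_obs))^2)
  if (sst == 0) stop("constant occurrence", call. = FALSE)

  sse_of <- function(log_m) {
    m <- exp(log_m)
    sum((st$f_obs - ncm_predict(st$p, N * m, d))^2)
  }
  starts <- log(c(0.001, 0.01, 0.1, 0.5))
  fits <- lapply(starts, function(s0) {
    tryCatch(optim(s0, sse_of, method = "L-BFGS-B",
                   lower = log(1e-7), upper = 0),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("neutral model fit did not converge from any start", call. = FALSE)
  fits <- fits[ok]
  sses <- vapply(fits, `[[`, numeric(1), "value")
  ms <- exp(vapply(fits, `[[`, numeric(1), "par"))
  # ties (within numerical noise) broken toward smaller m
  best_sse <- min(sses)
  cand <- which(sses <= best_sse + 1e-12)
  best <- cand[which.min(ms[cand])]
  m <- ms[best]
  sse <- sses[best]

  f_pred <- ncm_predict(st$p, N * m, d)
  band <- wilson_interval(f_pred, S, ci_level)
  partition <- ifelse(st$f_obs > band[, "high"], "above",
                      ifelse(st$f_obs < band[, "low"], "below", "neutral"))
  per_taxon <- data.frame(taxon_id = st$taxon_id, p = st$p, f_obs = st$f_obs,
                          f_pred = f_pred, ci_low = band[, "low"],
                          ci_high = band[, "high"], partition = partition,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(m = m, N = N, Nm = N * m, d = d,
                 r_squared = 1 - sse / sst, n_samples = S,
                 ci_level = ci_level, per_taxon = per_taxon),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  frac <- ncm_partition_summary(x)
  cat(sprintf(
    "Sloan neutral model: Nm = %.4g (m = %.3g, N = %d), R2 = %.3f, S = %d\n",
    x$Nm, x$m, x$N, x$r_squared, x$n_samples))
  cat(sprintf("  partition: below %.1f%%, neutral %.1f%%, above %.1f%% of %d taxa\n",
              100 * frac["below"], 100 * frac["neutral"], 100 * frac["above"],
              nrow(x$per_taxon)))
  invisible(x)
}

#' Fractions of taxa below, inside and above the neutral prediction band
#'
#' @param fit An [ncm_fit()] result.
#' @return Named numeric vector (below, neutral, above) summing to 1.
#' @export
ncm_partition_summary <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  tab <- table(factor(fit$per_taxon$partition,
                      levels = c("below", "neutral", "above")))
  setNames(as.vector(tab / sum(tab)), c("below", "neutral", "above"))
}

#' Fit the neutral model independently within each clade
#'
#' @param table A rarefied [community_table()] with a taxonomy.
#' @param rank Taxonomy rank defining clades (e.g. `"class"`).
#' @param min_taxa Clades with fewer taxa (nonzero total) are skipped with a
#'   warning (default 20).
#' @param ci_level Passed to [ncm_fit()].
#' @return Named list of `ncm_fit` objects, one per retained clade.
#' @export
ncm_fit_by_clade <- function(table, rank, min_taxa = 20, ci_level = 0.95) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$taxonomy)) stop("table has no taxonomy", call. = FALSE)
  if (!rank %in% colnames(table$taxonomy))
    stop("rank '", rank, "' absent from taxonomy", call. = FALSE)
  clades <- sort(unique(stats::na.omit(table$taxonomy[[rank]])))
  out <- list()
  for (cl in clades) {
    sub <- suppressWarnings(subset_by_rank(table, rank, cl))
    n_nonzero <- sum(colSums(sub$counts) > 0)
    if (n_nonzero < min_taxa) {
      warning("clade '", cl, "' skipped: ", n_nonzero, " taxa < min_taxa (",
              min_taxa, ")", call. = FALSE)
      next
    }
    st <- suppressWarnings(occurrence_stats(sub, check_rarefied = FALSE))
    out[[cl]] <- tryCatch(ncm_fit(st, ci_level = ci_level),
                          error = function(e) {
                            warning("clade '", cl, "' fit failed: ",
                                    conditionMessage(e), call. = FALSE)
                            NULL
                          })
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Diagnostic plot of a neutral model fit
#'
#' Observed occurrence frequency against log10 mean relative abundance with
#' the fitted Sloan curve and its prediction band.
#'
#' @param x An [ncm_fit()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ncm_fit <- function(x, ...) {
  pt <- x$per_taxon
  cols <- c(below = "#d95f02", neutral = "grey40", above = "#1b9e77")
  graphics::plot(log10(pt$p), pt$f_obs, pch = 16, cex = 0.5,
                 col = cols[pt$partition],
                 xlab = "log10 mean relative abundance",
                 ylab = "occurrence frequency", ...)
  o <- order(pt$p)
  graphics::lines(log10(pt$p[o]), pt$f_pred[o], lwd = 2)
  graphics::lines(log10(pt$p[o]), pt$ci_low[o], lty = 2)
  graphics::lines(log10(pt$p[o]), pt$ci_high[o], lty = 2)
  invisible(x)
}
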