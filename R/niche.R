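#' Levins' niche breadth
#'
#' B = 1 / sum(P^2) where P are a taxon's abundance shares across samples
#' (the taxon's abundance vector normalized by its own total). B equals 1
#' for a single-sample endemic and the number of samples for perfectly even
#' occupancy.
#'
#' @param distribution Non-negative abundance (or share) vector of one taxon
#'   across samples; normalized internally to sum to 1.
#' @return Levins' B, or `NA` (with a warning) for a zero-total taxon.
#' @export
levins_b <- function(distribution) {
  if (any(distribution < 0, na.rm = TRUE))
    stop("shares must be non-negative", call. = FALSE)
  tot <- sum(distribution)
  if (!is.finite(tot) || tot == 0) {
    warning("zero-total taxon: niche breadth undefined", call. = FALSE)
    return(NA_real_)
  }
  p <- distribution / tot
  1 / sum(p^2)
}

#' Levins' B for every taxon of a community table
#'
#' @param table A [community_table()].
#' @return Named numeric vector of B values (`NA` for zero-total taxa).
#' @export
taxon_breadths <- function(table) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  tot <- colSums(counts)
  b <- rep(NA_real_, ncol(counts))
  nz <- tot > 0
  if (any(nz)) {
    p <- sweep(counts[, nz, drop = FALSE], 2, tot[nz], "/")
    b[nz] <- 1 / colSums(p^2)
  }
  setNames(b, colnames(counts))
}

#' Community-level niche breadth (Bcom)
#'
#' Bcom of a sample is the unweighted mean of Levins' B over the taxa
#' present (count > 0) in that sample.
#'
#' @param table A [community_table()].
#' @param b_values Named per-taxon B values covering all taxa with nonzero
#'   totals; defaults to [taxon_breadths()] of the table.
#' @return Named numeric vector of per-sample Bcom (`NA` with a warning for
#'   empty samples).
#' @export
community_breadth <- function(table, b_values = taxon_breadths(table)) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  nz <- colSums(counts) > 0
  missing_b <- colnames(counts)[nz & !(colnames(counts) %in%
                                         names(b_values)[!is.na(b_values)])]
  if (length(missing_b))
    stop("b_values missing for taxa: ",
         paste(head(missing_b, 5), collapse = ", "), call. = FALSE)
  out <- vapply(seq_len(nrow(counts)), function(i) {
    present <- counts[i, ] > 0
    if (!any(present)) return(NA_real_)
    mean(b_values[colnames(counts)[present]])
  }, numeric(1))
  if (anyNA(out))
    warning("empty sample(s): ",
            paste(rownames(counts)[is.na(out)], collapse = ", "),
            call. = FALSE)
  setNames(out, rownames(counts))
}

#' Classify habitat specialists and generalists by randomization
#'
#' Tests each taxon's observed Levins' B against a redistributional null:
#' in each randomization the taxon's total count is reallocated across
#' samples by a multinomial draw with probabilities proportional to the
#' observed sample totals (the generalist expectation), and B is recomputed.
#' Taxa whose observed B falls below the alpha/2 null quantile are habitat
#' specialists, above the 1 - alpha/2 quantile generalists; the rest are
#' non-significant. A plain permutation of counts among samples would leave
#' B unchanged, which is why a redistributional null is required.
#'
#' @param table A [community_table()] with at least 3 samples.
#' @param n_randomizations Null draws per taxon (default 999).
#' @param seed Optional integer seed.
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `niche_breadth_result`: `per_taxon`
#'   (taxon_id, B, null_low, null_high, label), `per_sample_bcom`,
#'   `n_randomizations`, `seed`, `alpha`.
#' @export
classify_specialists <- function(table, n_randomizations = 999, seed = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (nrow(counts) < 3) stop("need at least 3 samples", call. = FALSE)
  if (n_randomizations < 99)
    stop("n_randomizations must be at least 99", call. = FALSE)
  totals <- colSums(counts)
  sample_prob <- rowSums(counts) / sum(rowSums(counts))
  b_obs <- taxon_breadths(table)
  nz <- which(totals > 0)
  null_low <- null_high <- rep(NA_real_, ncol(counts))
  label <- rep(NA_character_, ncol(counts))
  singletons <- character(0)
  with_seed(seed, {
    for (j in nz) {
      if (totals[j] == 1) {
        # a single read cannot be spread: the null is degenerate at B = 1
        null_low[j] <- null_high[j] <- 1
        label[j] <- "non-significant"
        singletons <- c(singletons, colnames(counts)[j])
        next
      }
      draws <- rmultinom(n_randomizations, totals[j], sample_prob)
      shares <- draws / as.numeric(totals[j])
      b_null <- 1 / colSums(shares^2)
      q <- quantile(b_null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      null_low[j] <- q[1]
      null_high[j] <- q[2]
      label[j] <- if (b_obs[j] < q[1]) "specialist"
                  else if (b_obs[j] > q[2]) "generalist"
                  else "non-significant"
    }
  })
  if (length(singletons))
    warning(length(singletons),
            " single-read taxa forced non-significant (degenerate null)",
            call. = FALSE)
  per_taxon <- data.frame(taxon_id = colnames(counts), B = unname(b_obs),
                          null_low = null_low, null_high = null_high,
                          label = label, row.names = NULL,
                          stringsAsFactors = FALSE)
  per_taxon <- per_taxon[!is.na(per_taxon$B), , drop = FALSE]
  structure(list(per_taxon = per_taxon,
                 per_sample_bcom = suppressWarnings(
                   community_breadth(table, b_obs)),
                 n_randomizations = n_randomizations, seed = seed,
                 alpha = alpha),
            class = "niche_breadth_result")
}

#' @export
print.niche_breadth_result <- function(x, ...) {
  cat(sprintf(
    "niche breadth: %d taxa; specialists %d, generalists %d (alpha = %.2f, %d randomizations)\n",
    nrow(x$per_taxon), sum(x$per_taxon$label == "specialist"),
    sum(x$per_taxon$label == "generalist"), x$alpha, x$n_randomizations))
  cat(sprintf("  mean community breadth (Bcom) = %.2f\n",
              mean(x$per_sample_bcom, na.rm = TRUE)))
  invisible(x)
}
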