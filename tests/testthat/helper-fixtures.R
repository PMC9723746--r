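# Build a community_table from a plain matrix, inventing ids when absent.
make_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  community_table(counts, taxonomy = taxonomy)
}

# Minimal valid metadata for a set of sample ids.
make_meta <- function(sample_ids, types = NULL, lon = NULL, lat = NULL) {
  n <- length(sample_ids)
  types <- types %||% rep_len(c("urban", "suburban", "forest"), n)
  sample_metadata(data.frame(
    sample_id = sample_ids,
    site_id = paste0("site_", seq_len(n)),
    ecosystem_type = types,
    longitude = lon %||% seq(118, 118.2, length.out = n),
    latitude = lat %||% rep(24.5, n),
    pH = seq(5, 7, length.out = n),
    TOC = seq(10, 30, length.out = n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- exhaustive Raup-Crick oracle -----------------------------------------
# Enumerates ordered sequential weighted draws without replacement (the same
# law the sampler implements) and returns the exact probability of every
# richness-k subset of the pool.
rc_subset_probs <- function(w, k) {
  n <- length(w)
  probs <- new.env(parent = emptyenv())
  rec <- function(remaining, chosen, pr) {
    if (length(chosen) == k) {
      key <- paste(sort(chosen), collapse = ",")
      prev <- if (!is.null(probs[[key]])) probs[[key]] else 0
      probs[[key]] <- prev + pr
      return(invisible())
    }
    wsum <- sum(w[remaining])
    for (i in remaining)
      rec(setdiff(remaining, i), c(chosen, i), pr * w[i] / wsum)
  }
  rec(seq_len(n), integer(0), 1)
  as.list(probs)
}

# Exact null-deviation value for a sample pair by full enumeration of both
# null communities.
rc_exact <- function(pa_i, pa_j, w) {
  ss_obs <- sum(pa_i & pa_j)
  pi_ <- rc_subset_probs(w, sum(pa_i))
  pj_ <- rc_subset_probs(w, sum(pa_j))
  p_gt <- p_eq <- 0
  for (ki in names(pi_)) {
    si <- as.integer(strsplit(ki, ",", fixed = TRUE)[[1]])
    for (kj in names(pj_)) {
      sj <- as.integer(strsplit(kj, ",", fixed = TRUE)[[1]])
      ss <- length(intersect(si, sj))
      pr <- pi_[[ki]] * pj_[[kj]]
      if (ss > ss_obs) p_gt <- p_gt + pr
      else if (ss == ss_obs) p_eq <- p_eq + pr
    }
  }
  ((p_gt + 0.5 * p_eq) - 0.5) * 2
}

# All permutations of 1..n (n small), for exhaustive Mantel enumeration.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1))
    for (k in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}
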