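#' Construct a labelled distance/similarity matrix
#'
#' Thin wrapper around a symmetric matrix that records the metric and whether
#' entries are similarities, dissimilarities or distances; all pairwise-matrix
#' stages exchange this object.
#'
#' @param values Symmetric numeric matrix with sample ids as dimnames.
#' @param metric Metric name (e.g. `"bray_curtis"`).
#' @param kind One of `"similarity"`, `"dissimilarity"`, `"distance"`.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric,
                        kind = c("dissimilarity", "similarity", "distance")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    stop("dist_matrix needs sample ids as dimnames", call. = FALSE)
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("matrix is not symmetric", call. = FALSE)
  diag(values) <- if (kind == "similarity") 1 else 0
  structure(list(values = values, ids = rownames(values),
                 metric = metric, kind = kind),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %s (%s), %d samples\n",
              x$metric, x$kind, length(x$ids)))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

lower_tri <- function(x) x$values[lower.tri(x$values)]

#' Write a dist_matrix as square TSV with an id header row/column
#'
#' @param x A [dist_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(sample_id = x$ids, x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_community_rows <- function(table) {
  if (nrow(table$counts) < 2) stop("need at least 2 samples", call. = FALSE)
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
}

#' Bray-Curtis dissimilarity or similarity
#'
#' d(x, y) = sum|x - y| / sum(x + y) on counts; similarity is 1 - d.
#'
#' @param table A [community_table()] with positive row sums.
#' @param as Return `"dissimilarity"` (default) or `"similarity"`.
#' @return A [dist_matrix()].
#' @export
bray_curtis <- function(table, as = c("dissimilarity", "similarity")) {
  as <- match.arg(as)
  check_community_rows(table)
  d <- as.matrix(vegan::vegdist(table$counts, method = "bray"))
  if (as == "similarity") d <- 1 - d
  dist_matrix(d, "bray_curtis", kind = as)
}

#' Jaccard (presence/absence) dissimilarity
#'
#' Binary Jaccard dissimilarity 1 - |A intersect B| / |A union B|.
#'
#' @inheritParams bray_curtis
#' @return A [dist_matrix()] of kind dissimilarity.
#' @export
jaccard <- function(table) {
  check_community_rows(table)
  d <- as.matrix(vegan::vegdist(table$counts, method = "jaccard",
                                binary = TRUE))
  dist_matrix(d, "jaccard", kind = "dissimilarity")
}

#' Great-circle distance matrix between samples
#'
#' Haversine distance in km with Earth radius 6371 km.
#'
#' @param meta A [sample_metadata()] table with coordinates for every sample.
#' @return A [dist_matrix()] of kind distance (km).
#' @export
geographic_distance <- function(meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  miss <- meta$sample_id[!is.finite(meta$longitude) | !is.finite(meta$latitude)]
  if (length(miss))
    stop("missing coordinate(s) for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lat <- meta$latitude * pi / 180
  lon <- meta$longitude * pi / 180
  n <- nrow(meta)
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  d <- 2 * 6371 * asin(pmin(sqrt(a), 1))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  dist_matrix(d, "haversine_km", kind = "distance")
}

#' Euclidean environmental distance matrix
#'
#' All variables enter as ln(x + 1) except pH, which is used untransformed
#' (soil pH is already a log scale). Single-variable calls are supported for
#' per-variable community-environment tests.
#'
#' @param meta A [sample_metadata()] table.
#' @param variables Environmental column names to use; defaults to every
#'   recognized environmental column present.
#' @return A [dist_matrix()] of kind distance.
#' @export
environment_distance <- function(meta, variables = NULL) {
  stopifnot(inherits(meta, "sample_metadata"))
  variables <- variables %||% attr(meta, "env_vars")
  miss <- setdiff(variables, names(meta))
  if (length(miss))
    stop("environmental variable(s) not in metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(meta[, variables, drop = FALSE])
  for (v in variables) {
    if (v == "pH") next
    if (any(x[, v] < 0, na.rm = TRUE))
      stop("negative value in '", v, "' cannot be log(x+1) transformed",
           call. = FALSE)
    x[, v] <- log1p(x[, v])
  }
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  dist_matrix(d, paste0("euclidean_env[", paste(variables, collapse = ","), "]"),
              kind = "distance")
}

#' Mantel permutation test
#'
#' Correlates the lower triangles of two pairwise matrices and assesses
#' significance by simultaneous row/column permutation of one matrix;
#' p = (1 + number of permuted statistics as or more extreme) /
#' (1 + n_permutations).
#'
#' @param a,b [dist_matrix()] objects over the same sample ids.
#' @param method Correlation: `"spearman"` (default) or `"pearson"`.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @param tail `"auto"` (one-sided in the direction of the observed sign,
#'   the default), `"one-sided-greater"`, `"one-sided-less"` or
#'   `"two-sided"`.
#' @return An object of class `mantel_result`: list(r, p_value,
#'   n_permutations, method, tail, seed).
#' @export
mantel_test <- function(a, b, method = c("spearman", "pearson"),
                        n_permutations = 999, seed = NULL,
                        tail = c("auto", "one-sided-greater",
                                 "one-sided-less", "two-sided")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  stopifnot(inherits(a, "dist_matrix"), inherits(b, "dist_matrix"))
  if (n_permutations < 99)
    stop("n_permutations must be at least 99", call. = FALSE)
  if (!identical(a$ids, b$ids)) {
    if (!setequal(a$ids, b$ids))
      stop("sample ids differ between matrices", call. = FALSE)
    b <- dist_matrix(b$values[a$ids, a$ids], b$metric, b$kind)
  }
  n <- length(a$ids)
  va <- lower_tri(a)
  if (sd(va) == 0 || sd(lower_tri(b)) == 0)
    stop("zero variance in lower triangle", call. = FALSE)
  # ranks placed back into matrix form so spearman permutations need no
  # re-ranking (row/column permutation permutes the off-diagonal multiset)
  bm <- b$values
  if (method == "spearman") {
    va <- rank(va)
    rb <- matrix(0, n, n)
    rb[lower.tri(rb)] <- rank(bm[lower.tri(bm)])
    bm <- rb + t(rb)
  }
  lt <- lower.tri(bm)
  r_obs <- cor(va, bm[lt])
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      cor(va, bm[p, p][lt])
    }, numeric(1))
  })
  if (tail == "auto")
    tail <- if (r_obs >= 0) "one-sided-greater" else "one-sided-less"
  k <- switch(tail,
              "one-sided-greater" = sum(perm_r >= r_obs),
              "one-sided-less" = sum(perm_r <= r_obs),
              "two-sided" = sum(abs(perm_r) >= abs(r_obs)))
  structure(list(r = r_obs, p_value = (1 + k) / (1 + n_permutations),
                 n_permutations = n_permutations, method = method,
                 tail = tail, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s, %s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$tail, x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' Distance-decay regression of community similarity on distance
#'
#' Ordinary least squares of (optionally natural-log-transformed) pairwise
#' similarity on pairwise geographic distance over the lower triangle. The
#' correlation r and its p-value come from the companion Mantel test; the
#' slope and intercept from the regression. Pairs with similarity 0 are
#' excluded from the log-scale fit and their count reported.
#'
#' @param community A [dist_matrix()] of kind similarity.
#' @param space A [dist_matrix()] of distances (km).
#' @param transform `"log"` (natural log, default) or `"none"`.
#' @param ... Passed to [mantel_test()] (e.g. `seed`, `n_permutations`).
#' @return An object of class `decay_fit`: list(slope, intercept, r,
#'   p_value, transform, log_base, n_pairs, n_excluded).
#' @export
distance_decay <- function(community, space, transform = c("log", "none"),
                           ...) {
  transform <- match.arg(transform)
  stopifnot(inherits(community, "dist_matrix"), inherits(space, "dist_matrix"))
  if (community$kind != "similarity")
    stop("community matrix must be a similarity matrix", call. = FALSE)
  if (!identical(community$ids, space$ids))
    stop("sample ids differ between matrices", call. = FALSE)
  y <- lower_tri(community)
  x <- lower_tri(space)
  if (sd(x) == 0) stop("all pairwise distances are equal", call. = FALSE)
  n_excluded <- 0L
  if (transform == "log") {
    keep <- y > 0
    n_excluded <- sum(!keep)
    x <- x[keep]
    y <- log(y[keep])
  }
  fit <- lm(y ~ x)
  mt <- mantel_test(community, space, ...)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = mt$r, p_value = mt$p_value,
                 transform = transform, log_base = "natural",
                 n_pairs = length(y), n_excluded = n_excluded),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "distance-decay: slope = %.5g per km (%s scale), r = %.4f, p = %.4g\n",
    x$slope, x$transform, x$r, x$p_value))
  if (x$n_excluded > 0)
    cat(sprintf("  %d zero-similarity pair(s) excluded from the log fit\n",
                x$n_excluded))
  invisible(x)
}
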