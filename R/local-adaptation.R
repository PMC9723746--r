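#' Intersect the neutral-model and niche-breadth filters
#'
#' Locally-adapted candidates are taxa that are simultaneously outside the
#' neutral prediction band (partition above or below) and significantly
#' narrow-niche (habitat specialists). Both results must come from the same
#' community table.
#'
#' @param ncm An [ncm_fit()] result.
#' @param niche A [classify_specialists()] result.
#' @return Character vector of taxon ids.
#' @export
intersect_filters <- function(ncm, niche) {
  stopifnot(inherits(ncm, "ncm_fit"), inherits(niche, "niche_breadth_result"))
  u1 <- ncm$per_taxon$taxon_id
  u2 <- niche$per_taxon$taxon_id
  if (!setequal(u1, u2)) {
    diff <- c(setdiff(u1, u2), setdiff(u2, u1))
    stop("taxon universes differ between the two results; symmetric difference: ",
         paste(head(diff, 10), collapse = ", "),
         if (length(diff) > 10) " ..." else "", call. = FALSE)
  }
  non_neutral <- u1[ncm$per_taxon$partition != "neutral"]
  specialists <- u2[niche$per_taxon$label == "specialist"]
  sort(intersect(non_neutral, specialists))
}

#' Assign locally-adapted taxa to ecosystem types
#'
#' Each taxon is assigned to the ecosystem type in which its mean relative
#' abundance (over that type's samples) is highest; ties break to the type
#' with more occupied samples, then lexicographically with a warning.
#'
#' @param taxa Character vector of locally-adapted taxon ids (from
#'   [intersect_filters()]).
#' @param table The [community_table()] both filters were computed on.
#' @param meta A [sample_metadata()] table covering the table's samples.
#' @param ncm Optional [ncm_fit()] supplying the partition column and the
#'   regional-pool denominator for the headline percentage; defaults to the
#'   taxa entering `table` with nonzero totals.
#' @param niche Optional [classify_specialists()] result (B column).
#' @return An object of class `local_adaptation_result`: `taxa` (data.frame
#'   with per-type mean relative abundance, assignment, lineage when
#'   available), `counts_by_ecosystem`, `n_pool`, `percent_of_pool`.
#' @export
assign_ecosystem <- function(taxa, table, meta, ncm = NULL, niche = NULL) {
  stopifnot(inherits(table, "community_table"),
            inherits(meta, "sample_metadata"))
  counts <- table$counts
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for sample(s): ",
         paste(setdiff(rownames(counts), meta$sample_id), collapse = ", "),
         call. = FALSE)
  types <- ecosystem_levels
  n_by_type <- table(factor(meta$ecosystem_type, levels = types))
  if (any(n_by_type == 0))
    stop("ecosystem type(s) with zero samples: ",
         paste(types[n_by_type == 0], collapse = ", "), call. = FALSE)
  rel <- counts / rowSums(counts)
  mean_ra <- sapply(types, function(ty) {
    colMeans(rel[meta$ecosystem_type == ty, , drop = FALSE])
  })
  occ <- sapply(types, function(ty) {
    colSums(counts[meta$ecosystem_type == ty, , drop = FALSE] > 0)
  })
  missing <- setdiff(taxa, colnames(counts))
  if (length(missing))
    stop("taxa not in table: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  assigned <- character(length(taxa))
  tie <- FALSE
  for (k in seq_along(taxa)) {
    ra <- mean_ra[taxa[k], ]
    best <- which(ra == max(ra))
    if (length(best) > 1) {
      oc <- occ[taxa[k], best]
      best <- best[oc == max(oc)]
      if (length(best) > 1) tie <- TRUE
      best <- best[order(names(best))][1]
    }
    assigned[k] <- types[best]
  }
  if (tie)
    warning("tie(s) in ecosystem assignment broken lexicographically",
            call. = FALSE)
  df <- data.frame(taxon_id = taxa, assigned_ecosystem = assigned,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mean_ra[taxa, , drop = FALSE],
                                row.names = NULL) |>
                setNames(paste0("mean_ra_", types)))
  if (!is.null(ncm))
    df$ncm_partition <- ncm$per_taxon$partition[
      match(taxa, ncm$per_taxon$taxon_id)]
  if (!is.null(niche))
    df$B <- niche$per_taxon$B[match(taxa, niche$per_taxon$taxon_id)]
  if (!is.null(table$taxonomy)) {
    idx <- match(taxa, rownames(table$taxonomy))
    df$lineage <- apply(table$taxonomy[idx, , drop = FALSE], 1, function(r)
      paste(stats::na.omit(r), collapse = ";"))
  }
  n_pool <- if (!is.null(ncm)) nrow(ncm$per_taxon) else sum(colSums(counts) > 0)
  structure(list(
    taxa = df,
    counts_by_ecosystem = table(factor(assigned, levels = types)),
    n_pool = n_pool,
    percent_of_pool = 100 * length(taxa) / n_pool),
    class = "local_adaptation_result")
}

#' @export
print.local_adaptation_result <- function(x, ...) {
  cat(sprintf(
    "locally-adapted taxa: %d (%.2f%% of the %d-taxon regional pool)\n",
    nrow(x$taxa), x$percent_of_pool, x$n_pool))
  print(x$counts_by_ecosystem)
  invisible(x)
}

#' Correlate per-group filter counts
#'
#' Across taxonomic groups, correlates the number (and percentage) of taxa
#' outside the neutral band with the number (and percentage) of habitat
#' specialists.
#'
#' @param ncm_fits Named list (>= 3 groups) of [ncm_fit()] results.
#' @param niche_results Named list of [classify_specialists()] results with
#'   the same names.
#' @return data.frame with one row per measure (counts, percentages) giving
#'   Pearson r and p.
#' @export
counts_regression <- function(ncm_fits, niche_results) {
  groups <- names(ncm_fits)
  if (length(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (!setequal(groups, names(niche_results)))
    stop("group names differ between lists", call. = FALSE)
  nn <- vapply(ncm_fits, function(f)
    sum(f$per_taxon$partition != "neutral"), numeric(1))
  ntot <- vapply(ncm_fits, function(f) nrow(f$per_taxon), numeric(1))
  sp <- vapply(niche_results[groups], function(r)
    sum(r$per_taxon$label == "specialist"), numeric(1))
  stot <- vapply(niche_results[groups], function(r)
    nrow(r$per_taxon), numeric(1))
  ct1 <- cor.test(nn, sp)
  ct2 <- cor.test(100 * nn / ntot, 100 * sp / stot)
  data.frame(measure = c("counts", "percentages"),
             r = c(unname(ct1$estimate), unname(ct2$estimate)),
             p_value = c(ct1$p.value, ct2$p.value),
             n_groups = length(groups), stringsAsFactors = FALSE)
}
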