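#' Construct a community table
#'
#' A community table holds non-negative integer ASV/taxon counts with samples
#' as rows and taxa as columns, plus an optional ranked taxonomy. It is the
#' object every downstream stage (dissimilarity, neutral model, null
#' deviation, niche breadth) consumes.
#'
#' @param counts Numeric matrix of non-negative integer counts, samples as
#'   rows and taxa as columns, with unique row and column names.
#' @param taxonomy Optional data.frame of ranked lineages (columns are ranks
#'   such as kingdom..species, rows named by taxon id). Every row name must be
#'   a taxon id of `counts`; missing ranks are `NA`.
#' @return An object of class `community_table` with elements `counts`
#'   (integer matrix) and `taxonomy` (data.frame or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' community_table(m)
#' @export
community_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0) stop("no samples", call. = FALSE)
  sample_ids <- rownames(counts)
  taxon_ids <- colnames(counts)
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == ""))
    stop("counts must have non-empty sample (row) names", call. = FALSE)
  if (ncol(counts) > 0 && (is.null(taxon_ids) || anyNA(taxon_ids) || any(taxon_ids == "")))
    stop("counts must have non-empty taxon (column) names", call. = FALSE)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(taxon_ids[duplicated(taxon_ids)])
  if (length(dup))
    stop("duplicate taxon id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell at sample '%s', taxon '%s' (value %s)",
      sample_ids[i[1]], taxon_ids[i[2]], format(counts[bad[1]])), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    extra <- setdiff(rownames(taxonomy), taxon_ids)
    if (length(extra))
      stop("taxonomy contains unknown taxon id(s): ",
           paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy: %d taxa, ranks: %s\n", nrow(x$taxonomy),
                paste(colnames(x$taxonomy), collapse = ", ")))
  rar <- attr(x, "rarefaction")
  if (!is.null(rar))
    cat(sprintf("  rarefied to depth %d (seed %s, %d sample(s) dropped)\n",
                rar$depth, format(rar$seed), length(rar$dropped)))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

default_ranks <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")

#' Split semicolon-separated lineage strings into a ranked taxonomy table
#'
#' @param lineages Named character vector (names are taxon ids) of
#'   semicolon-separated lineages, e.g. `"Bacteria;Proteobacteria;..."`.
#'   Rank prefixes in the QIIME style (`k__`, `p__`, ...) are stripped.
#' @param ranks Rank names to assign, outermost first.
#' @return data.frame with one column per rank, rows named by taxon id.
#' @export
parse_lineages <- function(lineages, ranks = default_ranks) {
  if (is.null(names(lineages)) || anyNA(names(lineages)))
    stop("lineages must be named by taxon id", call. = FALSE)
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(parts), ncol = length(ranks),
                dimnames = list(names(lineages), ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    k <- min(length(p), length(ranks))
    out[i, seq_len(k)] <- p[seq_len(k)]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Read a TSV allowing the QIIME2 feature-table export dialect: any leading
# '#'-comment lines, with the last one doubling as the header row.
read_tsv_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no samples: '", path, "' is empty", call. = FALSE)
  first_data <- 1
  while (first_data <= length(lines) && startsWith(lines[first_data], "#"))
    first_data <- first_data + 1
  if (first_data > 1) {
    header <- sub("^#\\s?", "", lines[first_data - 1])
    body <- lines[seq(first_data, length.out = length(lines) - first_data + 1)]
    lines <- c(header, body)
  }
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
}

#' Read a community table from TSV
#'
#' Accepts plain TSV (one header row, one id column, numeric body) and the
#' QIIME2 feature-table export dialect (optional leading `#` comment lines).
#' A lineage column (named `taxonomy`, `taxon` or `lineage`, case
#' insensitive) is split into ranks when the input is taxa-as-rows.
#'
#' @param path Path to a tab-separated file.
#' @param orientation `"taxa-as-rows"` (QIIME2 convention, default) or
#'   `"samples-as-rows"`.
#' @return A validated [community_table()] in samples-by-taxa orientation.
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa-as-rows",
                                                 "samples-as-rows")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_dialect(path)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("no samples: '", path, "' has a header but no data", call. = FALSE)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate id(s) in '", path, "': ", paste(dup, collapse = ", "),
         call. = FALSE)
  body <- df[-1]
  taxonomy <- NULL
  tax_col <- which(tolower(names(body)) %in% c("taxonomy", "taxon", "lineage"))
  if (length(tax_col)) {
    if (orientation == "taxa-as-rows")
      taxonomy <- parse_lineages(setNames(body[[tax_col[1]]], ids))
    body <- body[-tax_col]
  }
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer count in '%s' at row id '%s', column '%s' (value '%s')",
      path, ids[bad[1, 1]], names(body)[bad[1, 2]],
      body[[bad[1, 2]]][bad[1, 1]]), call. = FALSE)
  }
  rownames(num) <- ids
  if (orientation == "taxa-as-rows") num <- t(num)
  community_table(num, taxonomy = taxonomy)
}

#' Read a two-column taxonomy TSV (taxon id, semicolon lineage)
#'
#' @param path Path to a TSV with taxon ids in column 1 and lineages in
#'   column 2.
#' @inheritParams parse_lineages
#' @return data.frame of ranks, rows named by taxon id.
#' @export
read_taxonomy <- function(path, ranks = default_ranks) {
  df <- read_tsv_dialect(path)
  if (ncol(df) < 2) stop("taxonomy file needs two columns", call. = FALSE)
  parse_lineages(setNames(df[[2]], df[[1]]), ranks = ranks)
}

#' Write a community table (samples as rows) to TSV
#'
#' If the table carries rarefaction metadata (see [rarefy_table()]) a JSON
#' sidecar `<path>.json` recording depth, seed and dropped samples is written
#' alongside.
#'
#' @param table A [community_table()].
#' @param path Output TSV path.
#' @param sidecar Write the rarefaction JSON sidecar when available.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(sample_id = rownames(table$counts),
                   table$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rar <- attr(table, "rarefaction")
  if (sidecar && !is.null(rar)) {
    jsonlite::write_json(rar, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped and reported; taxon columns that become all-zero are
#' retained so taxon indices stay aligned across tables.
#'
#' @param table A [community_table()].
#' @param depth Target reads per sample (default 20000, the conventional
#'   amplicon cut-off).
#' @param seed Integer seed; identical (table, depth, seed) gives identical
#'   output. `NULL` uses the current RNG stream.
#' @return A `community_table` whose row sums all equal `depth`, with an
#'   attribute `rarefaction` = list(depth, seed, dropped).
#' @export
rarefy_table <- function(table, depth = 20000, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 ||
      depth != round(depth))
    stop("depth must be a positive integer", call. = FALSE)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("no samples at requested depth ", depth, call. = FALSE)
  dropped <- rownames(table$counts)[!keep]
  if (length(dropped))
    warning("dropped ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "), call. = FALSE)
  counts <- table$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    exact <- rowSums(counts) == depth
    sub <- counts
    if (any(!exact)) {
      # rrarefy heuristically warns whenever the smallest nonzero count
      # exceeds 1; that is routine for deep amplicon tables
      sub[!exact, ] <- withCallingHandlers(
        vegan::rrarefy(counts[!exact, , drop = FALSE], depth),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
    sub
  })
  res <- community_table(out, taxonomy = table$taxonomy)
  attr(res, "rarefaction") <- list(depth = as.integer(depth), seed = seed,
                                   dropped = as.list(dropped))
  res
}

#' Relative abundance matrix
#'
#' @param table A [community_table()] with positive row sums.
#' @return Real matrix whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "community_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  table$counts / totals
}

#' Subset a community table by taxonomy rank
#'
#' Restricts the taxon columns to those whose lineage matches `name` at
#' `rank`; the sample set is unchanged.
#'
#' @param table A [community_table()] carrying a taxonomy.
#' @param rank A rank name present in the taxonomy (e.g. `"class"`).
#' @param name Lineage value to match at that rank.
#' @return A `community_table` restricted to the matching taxa (possibly
#'   zero taxa, with a warning).
#' @export
subset_by_rank <- function(table, rank, name) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$taxonomy))
    stop("table has no taxonomy", call. = FALSE)
  if (!rank %in% colnames(table$taxonomy))
    stop("rank '", rank, "' absent from taxonomy (have: ",
         paste(colnames(table$taxonomy), collapse = ", "), ")", call. = FALSE)
  hit <- rownames(table$taxonomy)[
    !is.na(table$taxonomy[[rank]]) & table$taxonomy[[rank]] == name]
  keep <- intersect(colnames(table$counts), hit)
  if (!length(keep))
    warning("no taxa match ", rank, " == '", name, "'", call. = FALSE)
  community_table(table$counts[, keep, drop = FALSE],
                  taxonomy = table$taxonomy[keep, , drop = FALSE])
}
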