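ecosystem_levels <- c("urban", "suburban", "forest")
known_env_vars <- c("pH", "moisture", "TOC", "TN", "TC", "C:N", "TP", "TS")

#' Validate a sample metadata table
#'
#' Sample metadata carries, per sample: the site id, the ecosystem type
#' (urban / suburban / forest), decimal-degree coordinates, and any subset of
#' the soil chemistry variables pH, moisture, TOC, TN, TC, C:N, TP, TS.
#'
#' @param df data.frame with columns `sample_id`, `site_id`,
#'   `ecosystem_type`, `longitude`, `latitude` and optional environmental
#'   columns. Extra columns are kept.
#' @return The validated data.frame, classed `sample_metadata`, with an
#'   attribute `env_vars` naming the environmental columns present.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "ecosystem_type", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$ecosystem_type), ecosystem_levels)
  if (length(bad))
    stop("ecosystem_type must be one of ",
         paste(ecosystem_levels, collapse = "/"), "; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$latitude) | abs(df$latitude) > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(!is.finite(df$longitude) | abs(df$longitude) > 180))
    stop("longitude out of [-180, 180]", call. = FALSE)
  attr(df, "env_vars") <- intersect(known_env_vars, names(df))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path TSV path with one row per sample; see [sample_metadata()] for
#'   the required columns.
#' @return A validated `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}
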