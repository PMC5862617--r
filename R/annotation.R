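#' Probe annotation manifests
#'
#' A manifest is a data frame with one row per array probe giving its
#' genomic placement and CpG-island/gene membership. Columns:
#' `probe_id`, `chromosome` ("1".."22", "X", "Y"), `position` (1-based,
#' Illumina manifest convention), `island_id` (NA when the probe is not
#' on a CpG island), `gene` (NA allowed), `region_class` (one of
#' `r paste(REGION_CLASSES, collapse = ", ")`), and `platform`
#' (`"P27K"` or `"P450K"`).
#'
#' @name manifest
NULL

REGION_CLASSES <- c("TSS_proximal", "gene_body", "upstream", "downstream",
                    "intergenic")
PLATFORMS <- c("P27K", "P450K")

#' Validate a probe-annotation manifest
#'
#' @param df data frame with the manifest columns (see [manifest]).
#' @return The validated data frame with character/integer column types
#'   normalized, invisibly classed `probe_manifest`.
#' @export
as_probe_manifest <- function(df) {
  need <- c("probe_id", "chromosome", "position", "island_id", "gene",
            "region_class", "platform")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- sub("^chr", "", as.character(df$chromosome))
  df$position <- as.integer(df$position)
  df$island_id <- as.character(df$island_id)
  df$island_id[df$island_id %in% c("", "NA")] <- NA_character_
  df$gene <- as.character(df$gene)
  df$gene[df$gene %in% c("", "NA")] <- NA_character_
  if (any(is.na(df$position) | df$position < 1))
    stop("manifest positions must be integers >= 1")
  if (!all(df$region_class %in% REGION_CLASSES))
    stop("unknown region_class: ",
         paste(setdiff(unique(df$region_class), REGION_CLASSES), collapse = ", "))
  if (!all(df$platform %in% PLATFORMS))
    stop("unknown platform: ",
         paste(setdiff(unique(df$platform), PLATFORMS), collapse = ", "))
  for (pl in unique(df$platform)) {
    ids <- df$probe_id[df$platform == pl]
    if (anyDuplicated(ids))
      stop("duplicate probe id within platform ", pl, ": ",
           ids[duplicated(ids)][1])
  }
  class(df) <- unique(c("probe_manifest", class(df)))
  df
}

#' Read a probe manifest from a tab-separated file
#' @param path path to a TSV with the manifest columns (see [manifest]).
#' @return A validated manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_probe_manifest(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")))
}

#' Write a probe manifest to a tab-separated file
#' @param df a manifest data frame.
#' @param path output path.
#' @return `df`, invisibly.
#' @export
write_manifest <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
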