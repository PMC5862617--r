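#' Sample sheets and clinical tables
#'
#' The sample sheet drives the two stratifications used throughout the
#' package: the topographic criterion (supratentorial vs infratentorial
#' tumor location) and the age-of-onset criterion (onset at or before a
#' cutoff age, default 3 years, vs after).
#'
#' @name sample_sheet
NULL

# Bare anatomical names -> brain compartment, used when the location label
# carries no explicit "(S)"/"(I)" token.
.COMPARTMENT_LOOKUP <- c(
  "cerebellum"          = "infratentorial",
  "brainstem"           = "infratentorial",
  "brain stem"          = "infratentorial",
  "pons"                = "infratentorial",
  "medulla"             = "infratentorial",
  "fourth ventricle"    = "infratentorial",
  "frontal lobe"        = "supratentorial",
  "temporal lobe"       = "supratentorial",
  "parietal lobe"       = "supratentorial",
  "occipital lobe"      = "supratentorial",
  "cerebral hemisphere" = "supratentorial",
  "optic chiasm"        = "supratentorial",
  "optic pathway"       = "supratentorial",
  "optic nerve"         = "supratentorial",
  "hypothalamus"        = "supratentorial",
  "thalamus"            = "supratentorial"
)

#' Resolve brain compartment from a tumor-location label
#'
#' A trailing "(S)" or "(I)" token is authoritative; otherwise the bare
#' anatomical name is matched (case-insensitively) against a lookup table
#' of common sites. Unresolvable labels give NA.
#'
#' @param label character vector of location labels, e.g. "Cerebellum (I)".
#' @return Character vector: "supratentorial", "infratentorial" or NA.
#' @export
parse_compartment <- function(label) {
  out <- rep(NA_character_, length(label))
  tok <- regmatches(label, regexpr("\\(([SI])\\)\\s*$", label))
  has_tok <- lengths(regmatches(label, gregexpr("\\(([SI])\\)\\s*$", label))) > 0
  out[has_tok] <- ifelse(grepl("S", tok), "supratentorial", "infratentorial")
  bare <- trimws(tolower(sub("\\(([SI])\\)\\s*$", "", label[!has_tok])))
  out[!has_tok] <- unname(.COMPARTMENT_LOOKUP[bare])
  out
}

#' Coerce and validate a sample sheet
#'
#' @param df data frame with columns `sample_id`, `diagnosis`
#'   ("PA"/"normal"), `location`, `sex` and `age` (years). A
#'   `compartment` column is derived from `location`.
#' @return Validated data frame classed `sample_sheet`.
#' @export
as_sample_sheet <- function(df) {
  need <- c("sample_id", "diagnosis", "location", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ", df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$diagnosis %in% c("PA", "normal")))
    stop("diagnosis must be 'PA' or 'normal'")
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age < 0)) stop("ages must be non-negative")
  df$compartment <- parse_compartment(df$location)
  class(df) <- unique(c("sample_sheet", class(df)))
  df
}

#' Read a sample sheet from CSV
#' @param path CSV with columns sample_id, diagnosis, location, sex, age.
#' @return A validated sample-sheet data frame (see [as_sample_sheet]).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a sample sheet to CSV
#' @param df sample-sheet data frame.
#' @param path output path.
#' @return `df`, invisibly.
#' @export
write_sample_sheet <- function(df, path) {
  keep <- intersect(c("sample_id", "diagnosis", "location", "sex", "age"), names(df))
  utils::write.csv(df[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Partition tumor samples by brain compartment
#'
#' Applies the topographic criterion to the PA samples of a sample sheet:
#' the partition is disjoint and covers every tumor sample.
#'
#' @param sheet a sample-sheet data frame.
#' @return Named list with character vectors `supratentorial` and
#'   `infratentorial` of sample ids.
#' @export
stratify_by_location <- function(sheet) {
  sheet <- as_sample_sheet(as.data.frame(sheet))
  pa <- sheet[sheet$diagnosis == "PA", , drop = FALSE]
  bad <- is.na(pa$compartment)
  if (any(bad))
    stop("unresolvable tumor location label(s): ",
         paste(unique(pa$location[bad]), collapse = ", "))
  list(supratentorial = pa$sample_id[pa$compartment == "supratentorial"],
       infratentorial = pa$sample_id[pa$compartment == "infratentorial"])
}

#' Partition tumor samples by age of onset
#'
#' The cutoff is inclusive on the young side: `age <= cutoff` lands in
#' `young`.
#'
#' @param sheet a sample-sheet data frame.
#' @param cutoff age cutoff in years (default 3).
#' @return Named list with character vectors `young` (<= cutoff) and
#'   `old` (> cutoff) of PA sample ids.
#' @export
stratify_by_age <- function(sheet, cutoff = 3) {
  sheet <- as_sample_sheet(as.data.frame(sheet))
  pa <- sheet[sheet$diagnosis == "PA", , drop = FALSE]
  if (any(is.na(pa$age))) stop("missing ages for: ",
                               paste(pa$sample_id[is.na(pa$age)], collapse = ", "))
  list(young = pa$sample_id[pa$age <= cutoff],
       old = pa$sample_id[pa$age > cutoff])
}

#' Read a qPCR cycle-threshold table from CSV
#'
#' Columns: `sample_id`, `gene`, `ct`, `is_endogenous_control` (logical).
#' Exactly one endogenous-control gene must be present and all CT values
#' must be positive.
#'
#' @param path CSV path.
#' @return Validated data frame classed `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a CT table
#' @param df data frame with CT-table columns (see [read_ct_table]).
#' @return Validated data frame classed `ct_table`.
#' @export
as_ct_table <- function(df) {
  need <- c("sample_id", "gene", "ct", "is_endogenous_control")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("CT table missing columns: ", paste(miss, collapse = ", "))
  df$is_endogenous_control <- as.logical(df$is_endogenous_control)
  if (any(!is.na(df$ct) & df$ct <= 0)) stop("CT values must be positive")
  ctrl <- unique(df$gene[df$is_endogenous_control])
  if (length(ctrl) != 1)
    stop("expected exactly one endogenous-control gene, found: ",
         if (length(ctrl) == 0) "none" else paste(ctrl, collapse = ", "))
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Write a CT table to CSV
#' @param df CT-table data frame.
#' @param path output path.
#' @return `df`, invisibly.
#' @export
write_ct_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a survival table from CSV
#'
#' Columns: `sample_id`, `time` (days, >= 0), `event` (TRUE when death
#' observed), `expression` (the biomarker's expression value used for the
#' median split).
#'
#' @param path CSV path.
#' @return Validated data frame classed `survival_table`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_survival_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a survival table
#' @param df data frame with survival-table columns (see [read_survival_table]).
#' @return Validated data frame classed `survival_table`.
#' @export
as_survival_table <- function(df) {
  need <- c("sample_id", "time", "event", "expression")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("survival table missing columns: ", paste(miss, collapse = ", "))
  df$time <- as.numeric(df$time)
  df$event <- as.logical(df$event)
  if (any(is.na(df$time) | df$time < 0)) stop("survival times must be >= 0")
  class(df) <- unique(c("survival_table", class(df)))
  df
}

#' Write a survival table to CSV
#' @param df survival-table data frame.
#' @param path output path.
#' @return `df`, invisibly.
#' @export
write_survival_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
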