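#' The fourteen thorax disease labels
#'
#' Label vocabulary of the ChestX-ray14 corpus; an empty label set is written to
#' manifests as the literal token `"No Finding"`.
#'
#' @format Character vector of length 14.
#' @export
chest_diseases <- c(
  "Atelectasis", "Cardiomegaly", "Consolidation", "Edema", "Effusion",
  "Emphysema", "Fibrosis", "Hernia", "Infiltration", "Mass", "Nodule",
  "Pleural_Thickening", "Pneumonia", "Pneumothorax"
)

no_finding_token <- "No Finding"

#' Age bins used for the age-detection task
#'
#' Four bins with closed lower and open upper bounds:
#' `[1, 11)`, `[11, 21)`, `[21, 31)`, `[31, 121)`.
#'
#' @param age_years Integer vector of ages in years.
#' @return Character vector of bin labels (`Age_1-10`, ..., `Age_31-120`).
#' @export
#' @examples
#' age_bin(c(5, 11, 30, 31))
age_bin <- function(age_years) {
  if (any(!is.finite(age_years))) abort("age_years must be finite")
  bins <- cut(age_years,
    breaks = c(1, 11, 21, 31, 121), right = FALSE,
    labels = c("Age_1-10", "Age_11-20", "Age_21-30", "Age_31-120")
  ) |> as.character()
  if (anyNA(bins)) abort("age_years must lie in [1, 121) to map to an age bin")
  bins
}

age_bins <- c("Age_1-10", "Age_11-20", "Age_21-30", "Age_31-120")

serialize_labels <- function(diseases) {
  if (length(diseases) == 0) no_finding_token else paste(sort(diseases), collapse = "|")
}

parse_labels <- function(field) {
  if (is.na(field) || field == no_finding_token || field == "") {
    return(character(0))
  }
  labs <- strsplit(field, "|", fixed = TRUE)[[1]]
  unknown <- setdiff(labs, chest_diseases)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown disease label(s): %s (known: %s)",
      paste(unknown, collapse = ", "), paste(chest_diseases, collapse = ", ")
    ))
  }
  sort(labs)
}

#' Write a label manifest in the ChestX-ray14 CSV dialect
#'
#' Columns written: `Image Index`, `Finding Labels` (pipe-separated, sorted;
#' empty set as `"No Finding"`), `Patient Age`, `Patient Gender` (`M`/`F`).
#' The metadata round-trips losslessly through [read_manifest()].
#'
#' @param records Tibble of records with columns `image_id`, `gender`,
#'   `age_years`, `diseases` (list column of character vectors).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  if (nrow(records) == 0) abort("records must be non-empty")
  if (anyDuplicated(records$image_id)) {
    abort(sprintf(
      "duplicate image_id: %s",
      paste(unique(records$image_id[duplicated(records$image_id)]), collapse = ", ")
    ))
  }
  out <- tibble(
    `Image Index` = records$image_id,
    `Finding Labels` = map_chr(records$diseases, serialize_labels),
    `Patient Age` = as.integer(records$age_years),
    `Patient Gender` = ifelse(records$gender == "Male", "M", "F")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a label manifest in the ChestX-ray14 CSV dialect
#'
#' Parses gender (`M`/`F` or `Male`/`Female`), bins age on load, and splits
#' pipe-separated disease labels; `"No Finding"` becomes the empty set.
#' Unknown disease names are rejected with a listing.
#'
#' @param path CSV path with columns `Image Index`, `Finding Labels`,
#'   `Patient Age`, `Patient Gender`.
#' @return Tibble with columns `image_id`, `gender`, `age_years`, `age_bin`,
#'   `diseases` (list column).
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("Image Index", "Finding Labels", "Patient Age", "Patient Gender")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("manifest is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  gender <- dplyr::case_match(
    as.character(df$`Patient Gender`),
    c("M", "Male") ~ "Male",
    c("F", "Female") ~ "Female",
    .default = NA_character_
  )
  if (anyNA(gender)) abort("Patient Gender must be M/F (or Male/Female)")
  tibble(
    image_id = as.character(df$`Image Index`),
    gender = gender,
    age_years = as.integer(df$`Patient Age`),
    age_bin = age_bin(as.integer(df$`Patient Age`)),
    diseases = map(df$`Finding Labels`, parse_labels)
  )
}

# the single-label stratum used for balancing/stratification of multi-label
# records: first (alphabetically) disease, or the no-finding token
primary_label <- function(diseases) {
  map_chr(diseases, function(d) if (length(d) == 0) no_finding_token else sort(d)[1])
}
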