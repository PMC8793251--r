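# CSV readers/writers for single-arm files and corpus manifests.
# Arm file dialect: one numeric column `psa_change`, optional header,
# UTF-8, '.' decimal separator.

#' Read a single-arm PSA change CSV
#'
#' Reads a one-column CSV of per-patient PSA changes (optional header) and
#' returns a validated [psa_dataset()] on the internal reduction scale.
#'
#' @inheritParams psa_dataset
#' @param path Path to the CSV file.
#' @return A [psa_dataset()].
#' @seealso [write_arm_csv()]
#' @export
read_arm_csv <- function(path, threshold,
                         orientation = c("reduction", "change"),
                         arm_label = NULL, n_clipped = 0L, clip_point = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty arm file: ", path)
  first <- suppressWarnings(as.numeric(lines[1L]))
  has_header <- is.na(first)
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("no data rows in arm file: ", path)
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L] + has_header
    stop("non-numeric value at row ", bad, " of ", path,
         ": '", body[is.na(vals)][1L], "'")
  }
  if (is.null(arm_label))
    arm_label <- tools::file_path_sans_ext(basename(path))
  psa_dataset(vals, threshold, orientation = orientation,
              arm_label = arm_label, n_clipped = n_clipped,
              clip_point = clip_point)
}

#' Write a single-arm PSA change CSV
#'
#' Inverse of [read_arm_csv()]: writes the values as one `psa_change` column.
#'
#' @param dataset A [psa_dataset()].
#' @param path Output file path.
#' @param orientation Convention to write in; `"change"` negates the stored
#'   reduction-scale values (the usual waterfall-plot sign).
#' @return `path`, invisibly.
#' @export
write_arm_csv <- function(dataset, path,
                          orientation = c("reduction", "change")) {
  stopifnot(inherits(dataset, "psa_dataset"))
  orientation <- match.arg(orientation)
  vals <- dataset$values
  if (orientation == "change") vals <- -vals
  writeLines(c("psa_change", format(vals, digits = 15, trim = TRUE,
                                    scientific = FALSE)), path)
  invisible(path)
}

#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `arm_label, path, threshold, orientation,
#' n_clipped, clip_point` describing a directory of arm files. `clip_point`
#' may be empty (NA) for unclipped arms.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the manifest columns; `path` entries are left
#'   as stored (resolve them against the manifest's directory with
#'   [reanalyse_corpus()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm_label", "path", "threshold", "orientation",
            "n_clipped", "clip_point")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  man
}

#' @rdname read_manifest
#' @param manifest Manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}
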