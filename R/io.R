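#' Read the analysis input tables
#'
#' Readers for the headered CSV schemas used throughout the package
#' (UTF-8, "." decimal).  `read_boxes()` accepts either `x`/`y` or
#' `x_m`/`y_m` coordinate column names; `read_pedigree()` treats empty
#' strings, `"NA"`, `"0"` and `"*"` as unknown parents.
#'
#' @param path Path to a CSV file.
#' @return A data frame in the package's canonical column layout.
#' @name readers
NULL

#' @rdname readers
#' @export
read_boxes <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("x_m" %in% names(b)) names(b)[names(b) == "x_m"] <- "x"
  if ("y_m" %in% names(b)) names(b)[names(b) == "y_m"] <- "y"
  b$box_id <- as.character(b$box_id)
  b$patch_id <- as.character(b$patch_id)
  .check_boxes(b)
  b
}

#' @rdname readers
#' @export
read_states <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("box_id", "year", "occupant", "fledglings")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("states file lacks columns: ", paste(miss, collapse = ", "))
  s$box_id <- as.character(s$box_id)
  if (any(s$fledglings < 0, na.rm = TRUE)) stop("negative fledgling counts")
  if (anyDuplicated(s[c("box_id", "year")]))
    stop("more than one state for some (box_id, year)")
  s
}

#' @rdname readers
#' @export
read_events <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "female_id", "male_id", "year", "chosen_box_id",
            "choice_date", "female_status", "male_status",
            "available_box_ids")
  miss <- setdiff(need, names(e))
  if (length(miss)) stop("events file lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("pair_id", "female_id", "male_id", "chosen_box_id"))
    e[[col]] <- as.character(e[[col]])
  e
}

#' @rdname readers
#' @export
read_pedigree <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(p) <- tolower(names(p))
  if (!all(c("id", "dam", "sire") %in% names(p)))
    stop("pedigree file needs columns id, dam, sire")
  as_pedigree(p[c("id", "dam", "sire")])
}

# write a data frame as CSV with numbers at full double precision, so that
# re-reading reproduces the values bit-exactly
.write_csv_exact <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a simulated dataset to CSV files
#'
#' Writes `boxes.csv`, `states.csv`, `events.csv`, `pedigree.csv` and
#' `truth.json` for a [simulate_dataset()] result; identical datasets give
#' byte-identical files.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_exact(sim$boxes, file.path(dir, "boxes.csv"))
  .write_csv_exact(sim$states, file.path(dir, "states.csv"))
  .write_csv_exact(sim$events, file.path(dir, "events.csv"))
  .write_csv_exact(sim$pedigree, file.path(dir, "pedigree.csv"))
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
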