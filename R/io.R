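canonical_columns <- function(outcomes = default_outcomes()) {
  c("animal_id", "lab", "breeder", "design", "cage_id", outcomes)
}

#' Write a phenotype dataset to the canonical CSV schema
#'
#' Columns `animal_id, lab, breeder, design, cage_id` followed by the
#' outcome columns; missing values as empty fields; UTF-8 with header.
#'
#' @param dataset The dataset to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(dataset, path) {
  cols <- intersect(canonical_columns(names(dataset)), names(dataset))
  extra <- setdiff(names(dataset), cols)
  utils::write.csv(dataset[c(cols, extra)], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phenotype dataset from the canonical CSV schema
#'
#' @param path CSV file path.
#' @return A validated data frame with factor design columns.
#' @seealso [validate_dataset()] for the validation report.
#' @export
read_phenotypes <- function(path) {
  res <- validate_dataset(path)
  if (length(res$problems))
    stop("invalid phenotype file:\n  ",
         paste(res$problems, collapse = "\n  "))
  res$data
}

#' Validate a phenotype dataset against the canonical schema
#'
#' Checks the header, column types, design-arm labels, duplicate animal
#' identifiers and cage consistency (cagemates must share laboratory,
#' breeding site and design arm), and builds the accounting summary.
#'
#' @param x A CSV path or a data frame.
#' @param outcomes Expected outcome columns (default: the canonical 14).
#' @return A list with elements `data`, `accounting` and `problems`
#'   (character vector of schema violations, empty when valid).
#' @export
validate_dataset <- function(x, outcomes = default_outcomes()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    if (file.size(x) == 0)
      return(list(data = NULL, accounting = NULL,
                  problems = paste("empty file: missing header",
                                   paste(canonical_columns(outcomes)[1:5],
                                         collapse = ", "))))
    x <- utils::read.csv(x, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  }
  problems <- character(0)
  need <- canonical_columns(outcomes)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    problems <- c(problems,
                  paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  if (length(problems)) return(list(data = x, accounting = NULL,
                                    problems = problems))
  dup <- x$animal_id[duplicated(x$animal_id)]
  if (length(dup))
    problems <- c(problems, paste("duplicate animal_id:",
                                  paste(unique(dup), collapse = ", ")))
  bad_design <- which(!x$design %in% c("STA", "HET"))
  if (length(bad_design))
    problems <- c(problems, paste0("row ", bad_design,
                                   ": design must be STA or HET (got '",
                                   x$design[bad_design], "')"))
  for (v in outcomes) {
    if (!is.numeric(x[[v]])) {
      conv <- suppressWarnings(as.numeric(x[[v]]))
      bad <- which(!is.na(x[[v]]) & is.na(conv))
      if (length(bad))
        problems <- c(problems,
                      paste0("row ", bad, ", column ", v, ": not numeric"))
      else x[[v]] <- conv
    }
  }
  # cagemates share lab, breeder and design
  key <- interaction(x$lab, x$breeder, x$design, drop = TRUE)
  mixed <- tapply(as.integer(key), x$cage_id,
                  function(k) length(unique(k)) > 1L)
  if (any(mixed))
    problems <- c(problems,
                  paste("cage(s) mixing lab/breeder/design:",
                        paste(names(mixed)[mixed], collapse = ", ")))
  x$lab <- factor(x$lab)
  x$breeder <- factor(x$breeder)
  x$design <- factor(x$design, levels = c("STA", "HET"))
  acct <- if (!length(problems)) dataset_accounting(x, outcomes) else NULL
  list(data = x, accounting = acct, problems = problems)
}
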