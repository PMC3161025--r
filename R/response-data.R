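#' Binary item-response data with a missingness mask
#'
#' The central container of the package: an N x J matrix of dichotomous
#' responses coded 0/1 with \code{NA} for item non-response, together with
#' the observation mask and the usual margins (person scores on observed
#' items, per-item positive counts).
#'
#' @param values numeric matrix, entries in \{0, 1, NA\}; one row per
#'   person, one column per item.
#' @param item_labels optional character vector of item names.
#' @return an object of class \code{response_data} with components
#'   \code{values} (the matrix), \code{mask} (1 = observed),
#'   \code{n_persons}, \code{n_items}.
#' @export
response_data <- function(values, item_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ok <- values %in% c(0, 1) | is.na(values)
  if (!all(ok)) stop("responses must be 0, 1 or NA")
  if (ncol(values) < 2) stop("at least two items are required")
  if (is.null(item_labels)) {
    item_labels <- colnames(values)
    if (is.null(item_labels))
      item_labels <- paste0("item", seq_len(ncol(values)))
  }
  colnames(values) <- item_labels
  structure(
    list(values = values,
         mask = 1 - is.na(values) * 1,
         n_persons = nrow(values),
         n_items = ncol(values)),
    class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  miss <- mean(x$mask == 0)
  cat(sprintf("response_data: %d persons x %d items, %.1f%% missing\n",
              x$n_persons, x$n_items, 100 * miss))
  invisible(x)
}

#' Number of observed responses per person
#' @param data a \code{response_data} object.
#' @return integer vector of length N.
#' @export
person_obs_counts <- function(data) rowSums(data$mask)

#' Person scores (positive observed responses per person)
#' @inheritParams person_obs_counts
#' @return integer vector of length N.
#' @export
person_scores <- function(data) rowSums(data$values, na.rm = TRUE)

#' Number of observed responses per item
#' @inheritParams person_obs_counts
#' @return integer vector of length J.
#' @export
item_obs_counts <- function(data) colSums(data$mask)

#' Positive observed responses per item
#' @inheritParams person_obs_counts
#' @return integer vector of length J.
#' @export
item_positive_counts <- function(data) colSums(data$values, na.rm = TRUE)

#' Read an incomplete response matrix from CSV
#'
#' One row per person, one column per item; missing responses encoded as
#' an empty field or the string "NA" (both accepted).  An optional person
#' identifier column is recognised by name.
#'
#' @param path file path.
#' @param id_col optional name of a person-id column to drop from the
#'   response matrix (kept as rownames).
#' @return a \code{response_data} object.
#' @export
read_responses <- function(path, id_col = NULL) {
  df <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(id_col) && id_col %in% names(df)) {
    ids <- df[[id_col]]
    df <- df[setdiff(names(df), id_col)]
    m <- as.matrix(df)
    rownames(m) <- ids
  } else {
    m <- as.matrix(df)
  }
  response_data(m)
}

#' Write a response matrix to CSV
#'
#' Missing cells are written as empty fields, the same convention
#' \code{\link{read_responses}} accepts.
#'
#' @param data a \code{response_data} object.
#' @param path file path.
#' @export
write_responses <- function(data, path) {
  write.csv(as.data.frame(data$values), path, row.names = FALSE, na = "")
  invisible(path)
}
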