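#' Construct a response matrix
#'
#' A `response_matrix` holds one row per completed checklist: an opaque
#' patient identifier, a two-level group label (reference group first), and
#' a fixed set of binary item responses.  Missing responses are stored as
#' `NA`; every non-missing response must be exactly 0 or 1.
#'
#' @param patient_id Character (or coercible) vector of respondent
#'   identifiers.  Repeated identifiers denote repeated checklists from the
#'   same patient; see [select_one_per_patient()].
#' @param group Vector of group labels with at most two distinct values
#'   (e.g. administration modality).
#' @param responses Numeric matrix (rows = checklists, columns = items)
#'   containing 0, 1 or `NA`.
#' @param item_ids Character vector of item names; defaults to the column
#'   names of `responses`.
#' @param reference Name of the reference group.  The reference group is a
#'   declared property of the analysis, never inferred from row order.
#'   Defaults to the first group label encountered.
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `patient_id`, `group` (factor, reference level first), `responses`
#'   (integer matrix) and `item_ids`.
#' @seealso [read_responses()], [filter_complete()],
#'   [select_one_per_patient()]
#' @export
#' @examples
#' rm <- response_matrix(
#'   patient_id = c("p1", "p2", "p3"),
#'   group      = c("clinic", "online", "clinic"),
#'   responses  = rbind(c(1, 0), c(0, 0), c(1, NA)),
#'   item_ids   = c("item_a", "item_b"),
#'   reference  = "clinic"
#' )
#' rm
response_matrix <- function(patient_id, group, responses, item_ids = NULL,
                            reference = NULL) {
  responses <- as.matrix(responses)
  if (is.null(item_ids)) item_ids <- colnames(responses)
  if (is.null(item_ids)) item_ids <- paste0("item_", seq_len(ncol(responses)))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != ncol(responses))
    stop("`item_ids` must name every column of `responses`", call. = FALSE)
  if (length(patient_id) != nrow(responses) || length(group) != nrow(responses))
    stop("`patient_id` and `group` must have one entry per row of `responses`",
         call. = FALSE)
  storage.mode(responses) <- "integer"
  colnames(responses) <- item_ids
  rownames(responses) <- NULL

  bad <- which(!is.na(responses) & responses != 0L & responses != 1L,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary response at row %d, item '%s'",
                 bad[1, 1], item_ids[bad[1, 2]]), call. = FALSE)

  group <- as.character(group)
  if (anyNA(group) || any(!nzchar(group)))
    stop("every row must carry a non-empty group label", call. = FALSE)
  levs <- unique(group)
  if (length(levs) > 2)
    stop(sprintf("at most 2 groups are supported, found %d: %s",
                 length(levs), paste(levs, collapse = ", ")), call. = FALSE)
  if (is.null(reference)) reference <- levs[1]
  if (!reference %in% levs && length(levs) == 2)
    stop(sprintf("reference group '%s' not present in data", reference),
         call. = FALSE)
  levs <- c(reference, setdiff(levs, reference))

  structure(
    list(patient_id = as.character(patient_id),
         group = factor(group, levels = levs),
         responses = responses,
         item_ids = item_ids),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d checklists x %d items\n",
              nrow(x$responses), length(x$item_ids)))
  tab <- table(x$group)
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "),
      "  [reference: ", levels(x$group)[1], "]\n", sep = "")
  nmiss <- sum(is.na(x$responses))
  if (nmiss > 0)
    cat(sprintf("  %d missing responses in %d rows\n", nmiss,
                sum(rowSums(is.na(x$responses)) > 0)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Number of checklists in a response matrix
#' @param x A [response_matrix()].
#' @return Integer row count.
#' @export
n_respondents <- function(x) nrow(x$responses)

group_levels <- function(x) levels(x$group)

#' Read a response matrix from a delimited text file
#'
#' Expects one row per checklist with an identifier column, a group column
#' and one column per item.  Item columns may appear in any order; they are
#' matched by name when `item_ids` is supplied.  Empty cells and the string
#' `NA` are read as missing.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param id_col,group_col Names of the identifier and group columns.
#' @param item_ids Optional character vector selecting and ordering the
#'   item columns; default: every column other than `id_col`/`group_col`,
#'   in file order.
#' @param reference Reference group name (see [response_matrix()]).
#' @param sep Field separator, comma by default.
#' @param quiet Suppress the row/group count message.
#' @return A validated [response_matrix()], preserving row order.
#' @export
read_responses <- function(path, id_col = "patient_id", group_col = "group",
                           item_ids = NULL, reference = NULL, sep = ",",
                           quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, na.strings = NULL)
  for (col in c(id_col, group_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
  if (is.null(item_ids)) item_ids <- setdiff(names(df), c(id_col, group_col))
  missing_items <- setdiff(item_ids, names(df))
  if (length(missing_items) > 0)
    stop(sprintf("item column(s) not found: %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)

  resp <- matrix(NA_integer_, nrow(df), length(item_ids),
                 dimnames = list(NULL, item_ids))
  for (j in seq_along(item_ids)) {
    raw <- trimws(df[[item_ids[j]]])
    is_na <- raw == "" | raw == "NA"
    ok <- is_na | raw == "0" | raw == "1"
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("cannot parse value '%s' at row %d, column '%s' (expected 0, 1 or NA)",
                   raw[i], i, item_ids[j]), call. = FALSE)
    }
    resp[, j] <- ifelse(is_na, NA_integer_, as.integer(raw))
  }
  out <- response_matrix(df[[id_col]], df[[group_col]], resp,
                         item_ids = item_ids, reference = reference)
  if (!quiet) {
    tab <- table(out$group)
    message(sprintf("read %d checklists (%s) from %s", nrow(resp),
                    paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                          collapse = ", "), path))
  }
  out
}

#' Write a response matrix to a delimited text file
#'
#' Inverse of [read_responses()]: the written file round-trips exactly.
#' Missing responses are written as empty cells.
#'
#' @param x A [response_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "response_matrix"))
  df <- data.frame(patient_id = x$patient_id,
                   group = as.character(x$group),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in x$item_ids) df[[j]] <- x$responses[, j]
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Drop checklists with missing items
#'
#' Checklists with one or more missing item responses are excluded from
#' analysis; the number excluded is reported per group.
#'
#' @param x A [response_matrix()].
#' @param quiet Suppress the exclusion-count message.
#' @return A list with elements `data` (the filtered [response_matrix()],
#'   possibly empty) and `excluded` (named integer vector of exclusion
#'   counts per group).
#' @export
filter_complete <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "response_matrix"))
  keep <- rowSums(is.na(x$responses)) == 0
  excluded <- vapply(group_levels(x),
                     function(g) sum(!keep & x$group == g), integer(1))
  out <- subset_rows(x, keep)
  if (!quiet && any(!keep))
    message(sprintf("excluded %d incomplete checklist(s): %s", sum(!keep),
                    paste(sprintf("%s: %d", names(excluded), excluded),
                          collapse = ", ")))
  list(data = out, excluded = excluded)
}

#' Keep a single randomly selected checklist per patient
#'
#' When a patient contributed more than one checklist, one is chosen
#' uniformly at random; the choice is reproducible for a fixed seed.
#' Selection is unstratified (it ignores the group label).
#'
#' @param x A [response_matrix()].
#' @param seed Integer seed governing the random selection.
#' @return A [response_matrix()] with unique `patient_id`s, in original
#'   row order.
#' @export
select_one_per_patient <- function(x, seed) {
  stopifnot(inherits(x, "response_matrix"))
  n <- nrow(x$responses)
  if (n == 0) return(x)
  set.seed(as.integer(seed))
  # random priority per row; lowest priority wins within each patient
  pri <- runif(n)
  ord <- order(x$patient_id, pri)
  first <- !duplicated(x$patient_id[ord])
  keep <- sort(ord[first])
  subset_rows(x, keep)
}

# row-subset helper preserving class and group levels
subset_rows <- function(x, i) {
  structure(
    list(patient_id = x$patient_id[i],
         group = factor(as.character(x$group[i]), levels = group_levels(x)),
         responses = x$responses[i, , drop = FALSE],
         item_ids = x$item_ids),
    class = "response_matrix")
}
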