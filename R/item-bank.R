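#' Construct an item bank
#'
#' An `item_bank` stores the two-parameter logistic (2PL) parameters of a
#' fixed set of items: a discrimination `a > 0` and a severity (location)
#' `b` per item, either shared across groups or group-specific.  Anchor
#' items are items declared DIF-free a priori; their parameters are always
#' shared and they identify the common latent metric in multiple-group
#' estimation.
#'
#' The 2PL item response function used throughout the package is the
#' logistic `P(y = 1 | theta) = 1 / (1 + exp(-a (theta - b)))` with no
#' additional scaling constant (see [irf()]).
#'
#' @param item_ids Character vector of item names.
#' @param a,b Discriminations and severities.  Either vectors (one value
#'   per item, shared by all groups) or matrices with one column per group
#'   (reference column first).
#' @param groups Character vector of group names (reference first).
#'   Defaults to `"group1"` for vector input, or the column names of `a`.
#' @param a_shared,b_shared Logical vectors marking, per item, whether the
#'   parameter is constrained equal across groups.  Defaults: `TRUE`
#'   everywhere for vector input; for matrix input, equality of the
#'   supplied columns.  For shared parameters the reference value is used
#'   for every group.
#' @param anchors Character vector of anchor item ids (must be shared in
#'   both parameters).
#'
#' @return An object of class `item_bank`: a list with elements
#'   `item_ids`, `groups`, `a`, `b` (item x group matrices), `a_shared`,
#'   `b_shared`, `anchors`, `reference`.
#' @seealso [resolve_items()], [set_constraints()], [read_item_bank()],
#'   [asc_item_bank()]
#' @export
#' @examples
#' # two groups; item 2's severity differs between groups
#' bank <- item_bank(
#'   item_ids = c("i1", "i2"),
#'   a = c(1.5, 2.0),
#'   b = cbind(ref = c(0, 0.5), foc = c(0, 0.8)),
#'   groups = c("ref", "foc"),
#'   b_shared = c(TRUE, FALSE),
#'   anchors = "i1"
#' )
#' resolve_items(bank, "foc")
item_bank <- function(item_ids, a, b, groups = NULL,
                      a_shared = NULL, b_shared = NULL,
                      anchors = character()) {
  item_ids <- as.character(item_ids)
  J <- length(item_ids)
  if (anyDuplicated(item_ids))
    stop("duplicated item ids", call. = FALSE)

  expand <- function(x, shared_default) {
    if (is.matrix(x)) {
      if (is.null(groups)) groups <<- colnames(x)
      list(m = unname(x), shared = NULL)
    } else {
      if (is.null(groups)) groups <<- "group1"
      list(m = matrix(rep(as.numeric(x), length(groups)), nrow = J),
           shared = rep(TRUE, J))
    }
  }
  ea <- expand(a); eb <- expand(b)
  groups <- as.character(groups)
  G <- length(groups)
  if (G > 2) stop("at most 2 groups are supported", call. = FALSE)
  am <- ea$m; bm <- eb$m
  if (nrow(am) != J || nrow(bm) != J || ncol(am) != G || ncol(bm) != G)
    stop("`a` and `b` must supply one value per item (and per group)",
         call. = FALSE)
  if (is.null(a_shared))
    a_shared <- if (!is.null(ea$shared)) ea$shared else
      apply(am, 1, function(r) all(r == r[1]))
  if (is.null(b_shared))
    b_shared <- if (!is.null(eb$shared)) eb$shared else
      apply(bm, 1, function(r) all(r == r[1]))
  a_shared <- rep_len(as.logical(a_shared), J)
  b_shared <- rep_len(as.logical(b_shared), J)
  # shared parameters are stored once: reference value propagated
  am[a_shared, ] <- am[a_shared, 1]
  bm[b_shared, ] <- bm[b_shared, 1]
  dimnames(am) <- dimnames(bm) <- list(item_ids, groups)

  if (any(!is.finite(am)) || any(am <= 0)) {
    j <- which(!is.finite(am) | am <= 0, arr.ind = TRUE)[1, 1]
    stop(sprintf("discrimination must be positive and finite (item '%s')",
                 item_ids[j]), call. = FALSE)
  }
  if (any(!is.finite(bm)))
    stop("severities must be finite", call. = FALSE)
  anchors <- as.character(anchors)
  if (!all(anchors %in% item_ids))
    stop("anchors must be a subset of item_ids", call. = FALSE)
  anc <- item_ids %in% anchors
  if (any(anc & (!a_shared | !b_shared)))
    stop(sprintf("anchor item(s) must have both parameters shared: %s",
                 paste(item_ids[anc & (!a_shared | !b_shared)],
                       collapse = ", ")), call. = FALSE)

  structure(
    list(item_ids = item_ids, groups = groups, a = am, b = bm,
         a_shared = a_shared, b_shared = b_shared,
         anchors = anchors, reference = groups[1]),
    class = "item_bank")
}

#' @export
print.item_bank <- function(x, digits = 3, ...) {
  J <- length(x$item_ids)
  cat(sprintf("<item_bank> %d items, group(s): %s\n", J,
              paste(x$groups, collapse = ", ")))
  df <- data.frame(item = x$item_ids, stringsAsFactors = FALSE)
  df$a <- round(x$a[, 1], digits)
  df$b <- round(x$b[, 1], digits)
  if (length(x$groups) == 2) {
    fmt <- function(v, shared) ifelse(shared, "-", format(round(v, digits)))
    df[[paste0("a.", x$groups[2])]] <- fmt(x$a[, 2], x$a_shared)
    df[[paste0("b.", x$groups[2])]] <- fmt(x$b[, 2], x$b_shared)
  }
  df$anchor <- ifelse(x$item_ids %in% x$anchors, "*", "")
  print(df, row.names = FALSE)
  if (length(x$groups) == 2)
    cat("('-' = parameter fixed equal across groups; '*' = anchor)\n")
  invisible(x)
}

#' Resolve item parameters for one group
#'
#' Shared parameters are stored once and resolved on access: for a shared
#' parameter the reference-group value applies to every group.
#'
#' @param bank An [item_bank()].
#' @param group Group name.
#' @return A data frame with columns `item_id`, `a`, `b`.
#' @export
resolve_items <- function(bank, group) {
  stopifnot(inherits(bank, "item_bank"))
  g <- match(group, bank$groups)
  if (is.na(g))
    stop(sprintf("group '%s' not in item bank (groups: %s)", group,
                 paste(bank$groups, collapse = ", ")), call. = FALSE)
  data.frame(item_id = bank$item_ids, a = bank$a[, g], b = bank$b[, g],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Change the equality-constraint pattern of an item bank
#'
#' Marks parameters as shared (equal across groups) or group-specific.
#' Newly shared parameters collapse to the reference-group value; newly
#' freed parameters start from the shared value until re-estimated.
#'
#' @param bank A two-group [item_bank()].
#' @param a_shared,b_shared Logical vectors (one per item), or `NULL` to
#'   keep the current pattern.
#' @return The modified [item_bank()].
#' @export
set_constraints <- function(bank, a_shared = NULL, b_shared = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.null(a_shared)) a_shared <- bank$a_shared
  if (is.null(b_shared)) b_shared <- bank$b_shared
  item_bank(bank$item_ids, bank$a, bank$b, groups = bank$groups,
            a_shared = a_shared, b_shared = b_shared,
            anchors = bank$anchors)
}

#' Read an item bank from a delimited text file
#'
#' Expects columns `item_id`, `group`, `a`, `b`, `anchor`.  For a
#' two-group bank the reference group's rows carry the full parameter set;
#' rows of the second group carry values only for group-specific
#' parameters, with shared parameters left blank (empty, `NA`, `-` or an
#' em-dash), mirroring the dash convention of published DIF tables.
#'
#' @param path Path to the file.
#' @param reference Reference group name; default: group of the first row.
#' @param sep Field separator.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path, reference = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, na.strings = NULL)
  need <- c("item_id", "group", "a", "b")
  if (!all(need %in% names(df)))
    stop(sprintf("item bank file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  shared_mark <- function(x) trimws(x) %in% c("", "NA", "-", "—")
  num <- function(x) ifelse(shared_mark(x), NA_real_, as.numeric(x))

  if (is.null(reference)) reference <- df$group[1]
  groups <- c(reference, setdiff(unique(df$group), reference))
  ref <- df[df$group == reference, , drop = FALSE]
  if (nrow(ref) == 0)
    stop(sprintf("reference group '%s' not present in %s", reference, path),
         call. = FALSE)
  item_ids <- ref$item_id
  a_ref <- num(ref$a); b_ref <- num(ref$b)
  if (anyNA(a_ref) || anyNA(b_ref))
    stop("reference-group rows must provide both a and b for every item",
         call. = FALSE)
  anchors <- if ("anchor" %in% names(df))
    item_ids[tolower(trimws(ref$anchor)) %in% c("1", "true", "yes", "*")]
  else character()

  if (length(groups) == 1) {
    return(item_bank(item_ids, a_ref, b_ref, groups = groups,
                     anchors = anchors))
  }
  if (length(groups) > 2)
    stop("at most 2 groups are supported", call. = FALSE)
  foc <- df[df$group == groups[2], , drop = FALSE]
  idx <- match(item_ids, foc$item_id)
  a_foc <- rep(NA_real_, length(item_ids))
  b_foc <- rep(NA_real_, length(item_ids))
  a_foc[!is.na(idx)] <- num(foc$a)[idx[!is.na(idx)]]
  b_foc[!is.na(idx)] <- num(foc$b)[idx[!is.na(idx)]]
  a_shared <- is.na(a_foc); b_shared <- is.na(b_foc)
  a_foc[a_shared] <- a_ref[a_shared]
  b_foc[b_shared] <- b_ref[b_shared]
  item_bank(item_ids, cbind(a_ref, a_foc), cbind(b_ref, b_foc),
            groups = groups, a_shared = a_shared, b_shared = b_shared,
            anchors = anchors)
}

#' Write an item bank to a delimited text file
#'
#' Inverse of [read_item_bank()]; numeric values are written with enough
#' digits to round-trip exactly.
#'
#' @param bank An [item_bank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  # shortest decimal form that still round-trips exactly
  fmt1 <- function(x) {
    if (is.na(x)) return("")
    s <- sprintf("%.15g", x)
    if (as.numeric(s) == x) s else sprintf("%.17g", x)
  }
  fmt <- function(x) vapply(x, fmt1, character(1))
  anchor <- as.integer(bank$item_ids %in% bank$anchors)
  rows <- data.frame(item_id = bank$item_ids, group = bank$groups[1],
                     a = fmt(bank$a[, 1]), b = fmt(bank$b[, 1]),
                     anchor = anchor, stringsAsFactors = FALSE)
  if (length(bank$groups) == 2) {
    rows2 <- data.frame(
      item_id = bank$item_ids, group = bank$groups[2],
      a = ifelse(bank$a_shared, "", fmt(bank$a[, 2])),
      b = ifelse(bank$b_shared, "", fmt(bank$b[, 2])),
      anchor = anchor, stringsAsFactors = FALSE)
    rows <- rbind(rows, rows2)
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a latent trait distribution
#'
#' Group-specific normal distributions for the latent trait.  The
#' reference group is fixed to mean 0 and variance 1 (it defines the
#' latent metric); other groups may have free moments.
#'
#' @param groups Character vector of group names (reference first).
#' @param mean,variance Numeric vectors, one value per group.
#' @param reference Name of the reference group; defaults to `groups[1]`.
#' @return An object of class `latent_distribution`.
#' @export
#' @examples
#' latent_distribution(c("clinic", "online"), mean = c(0, -0.05),
#'                     variance = c(1, 0.90))
latent_distribution <- function(groups, mean = 0, variance = 1,
                                reference = groups[1]) {
  groups <- as.character(groups)
  G <- length(groups)
  mean <- rep_len(as.numeric(mean), G)
  variance <- rep_len(as.numeric(variance), G)
  if (!reference %in% groups)
    stop("`reference` must be one of `groups`", call. = FALSE)
  # reference first
  ord <- order(groups != reference)
  groups <- groups[ord]; mean <- mean[ord]; variance <- variance[ord]
  if (mean[1] != 0 || variance[1] != 1)
    stop("reference group must have mean 0 and variance 1 exactly",
         call. = FALSE)
  if (any(variance <= 0) || any(!is.finite(variance)) || any(!is.finite(mean)))
    stop("latent variances must be positive and moments finite", call. = FALSE)
  structure(
    list(groups = groups, mean = setNames(mean, groups),
         variance = setNames(variance, groups), reference = reference),
    class = "latent_distribution")
}

#' @export
print.latent_distribution <- function(x, digits = 3, ...) {
  cat("<latent_distribution>\n")
  print(data.frame(group = x$groups, mean = round(x$mean, digits),
                   variance = round(x$variance, digits),
                   row.names = NULL))
  cat("(reference: ", x$reference, ", fixed at 0/1)\n", sep = "")
  invisible(x)
}
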