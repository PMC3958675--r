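#' Construct a rating-scale item bank
#'
#' An item bank holds everything the Andrich rating scale model needs to
#' score a polytomous instrument: one overall difficulty \eqn{\delta_i}
#' (in logits) per item and a single ordered set of category step
#' difficulties \eqn{\tau_1, \ldots, \tau_{K-1}} (Andrich thresholds,
#' also in logits) shared by all items. Responses use external category
#' labels (by default \code{1:K}, the NAQ-R frequency categories
#' 1=never \ldots 5=daily); internally the model works with scores
#' \code{0:(K-1)}.
#'
#' @param delta numeric vector of item difficulties in logits.
#' @param thresholds numeric vector of length \code{K - 1} of step
#'   difficulties shared by all items. \code{thresholds[j]} is the step
#'   from internal category \code{j - 1} to \code{j}.
#' @param item_ids character vector of item labels; defaults to
#'   \code{"item1"}, \code{"item2"}, \ldots in bank order.
#' @param n_categories integer number of response categories \code{K};
#'   defaults to \code{length(thresholds) + 1}.
#' @param category_labels numeric external scores attached to the
#'   categories, defaults to \code{1:K}.
#'
#' @return An object of class \code{"item_bank"}: a list with elements
#'   \code{item_ids}, \code{delta} (named by item), \code{thresholds},
#'   \code{n_categories} and \code{category_labels}.
#'
#' @examples
#' bank <- item_bank(delta = c(-1, 0, 1), thresholds = c(-1.5, 0, 1.5))
#' bank
#'
#' @seealso [naqr_bank()] for the published 22-item NAQ-R bank,
#'   [read_item_bank()] / [write_item_bank()] for JSON and CSV I/O.
#' @export
item_bank <- function(delta, thresholds, item_ids = NULL,
                      n_categories = length(thresholds) + 1L,
                      category_labels = seq_len(n_categories)) {
  delta <- as.numeric(delta)
  thresholds <- as.numeric(thresholds)
  if (length(delta) < 1L)
    stop("an item bank needs at least one item")
  if (!all(is.finite(delta)) || !all(is.finite(thresholds)))
    stop("item difficulties and thresholds must be finite")
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L)
    stop("n_categories must be at least 2")
  if (length(thresholds) != n_categories - 1L)
    stop("thresholds must have exactly n_categories - 1 entries, got ",
         length(thresholds))
  if (length(category_labels) != n_categories)
    stop("category_labels must have one entry per category")
  if (is.null(item_ids)) item_ids <- paste0("item", seq_along(delta))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != length(delta))
    stop("item_ids and delta lengths differ")
  if (anyDuplicated(item_ids))
    stop("item_ids must be unique")
  names(delta) <- item_ids
  structure(
    list(item_ids = item_ids, delta = delta, thresholds = thresholds,
         n_categories = n_categories,
         category_labels = as.numeric(category_labels)),
    class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Rating scale item bank: ", length(x$item_ids), " items, ",
      x$n_categories, " categories\n", sep = "")
  cat("  delta range: [", round(min(x$delta), 3), ", ",
      round(max(x$delta), 3), "] logits (mean ",
      round(mean(x$delta), 4), ")\n", sep = "")
  cat("  thresholds: ", paste(round(x$thresholds, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.item_bank <- function(x) length(x$item_ids)

resolve_items <- function(bank, items) {
  if (is.null(items)) return(seq_along(bank$item_ids))
  if (is.character(items)) {
    idx <- match(items, bank$item_ids)
    if (anyNA(idx)) stop("unknown item id(s): ",
                         paste(items[is.na(idx)], collapse = ", "))
    return(idx)
  }
  items <- as.integer(items)
  if (any(items < 1L) || any(items > length(bank$item_ids)))
    stop("item index out of range")
  items
}

#' The published NAQ-R item bank
#'
#' Builds the 22-item Negative Acts Questionnaire-Revised bank with the
#' published rating-scale calibration: per-item overall difficulties
#' ranging from -2.21 (item 1, withholding information) to 2.56
#' (item 22, threats of violence) and the shared monotonically
#' increasing Andrich thresholds (-3.39, -0.55, 1.11, 2.83 logits) for
#' the five frequency categories (1=never, 2=occasionally, 3=monthly,
#' 4=weekly, 5=daily).
#'
#' @return An [item_bank] with 22 items (ids \code{"naq1"} ..
#'   \code{"naq22"}) and \code{n_categories = 5}.
#' @examples
#' bank <- naqr_bank()
#' range(bank$delta)
#' bank$thresholds
#' @export
naqr_bank <- function() {
  delta <- c(
    naq1  = -2.21, naq2  = -0.79, naq3  = -0.24, naq4  = -0.09,
    naq5  = -0.90, naq6  =  0.61, naq7  = -0.19, naq8  = -1.50,
    naq9  =  1.35, naq10 =  1.65, naq11 = -0.68, naq12 = -0.57,
    naq13 = -0.33, naq14 = -0.61, naq15 =  0.46, naq16 =  0.04,
    naq17 =  0.20, naq18 = -0.41, naq19 =  0.37, naq20 =  1.09,
    naq21 =  0.18, naq22 =  2.56)
  item_bank(delta = unname(delta), thresholds = c(-3.39, -0.55, 1.11, 2.83),
            item_ids = names(delta), n_categories = 5L)
}

#' Check ordering of the category structure
#'
#' A usable rating scale should have strictly increasing Andrich
#' thresholds: each successive category must peak further up the latent
#' continuum. Disordered (or tied) thresholds indicate that a category
#' is never modal and that categories may need collapsing.
#'
#' @param bank an [item_bank].
#' @return A list with \code{ordered} (logical), \code{deltas}
#'   (successive threshold differences) and \code{disordered_pairs}
#'   (integer matrix of offending adjacent threshold indices, 0 rows
#'   when ordered).
#' @examples
#' check_category_structure(naqr_bank())$ordered   # TRUE
#' @export
check_category_structure <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  d <- diff(bank$thresholds)
  bad <- which(d <= 0)
  pairs <- cbind(first = bad, second = bad + 1L)
  list(ordered = length(bad) == 0L, deltas = d, disordered_pairs = pairs)
}

#' Read and write item banks
#'
#' Item banks are serialized either as JSON
#' (\code{{"items":[{"id":..,"delta":..},...],
#' "thresholds":[...], "n_categories":K}}) or as CSV with one row per
#' item (\code{id,delta}) preceded by comment-style header lines
#' \code{#thresholds} and \code{#n_categories}.
#'
#' @param path file to read from / write to; format chosen by file
#'   extension (\code{.json} or \code{.csv}).
#' @param bank an [item_bank].
#' @return \code{read_item_bank} returns an [item_bank];
#'   \code{write_item_bank} returns \code{path} invisibly.
#' @export
read_item_bank <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    item_bank(delta = x$items$delta, thresholds = x$thresholds,
              item_ids = x$items$id,
              n_categories = x$n_categories %||% (length(x$thresholds) + 1L))
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    thr <- hdr[grepl("^#thresholds", hdr)]
    if (length(thr) != 1L) stop("CSV bank must carry a '#thresholds' line")
    thresholds <- as.numeric(strsplit(sub("^#thresholds[:,]?\\s*", "", thr),
                                      "[,;\\s]+")[[1]])
    ncat <- hdr[grepl("^#n_categories", hdr)]
    K <- if (length(ncat)) as.integer(sub("^#n_categories[:,]?\\s*", "", ncat))
         else length(thresholds) + 1L
    tab <- utils::read.csv(textConnection(grep("^#", lines,
                                               invert = TRUE, value = TRUE)))
    item_bank(delta = tab$delta, thresholds = thresholds,
              item_ids = tab$id, n_categories = K)
  }
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(items = data.frame(id = bank$item_ids,
                              delta = unname(bank$delta)),
           thresholds = bank$thresholds,
           n_categories = bank$n_categories),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#thresholds: ",
                        paste(bank$thresholds, collapse = ",")),
                 paste0("#n_categories: ", bank$n_categories),
                 "id,delta",
                 paste(bank$item_ids, unname(bank$delta), sep = ",")), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
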