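# Ordinal response container, CSV i/o and cutpoint estimation.

#' Ordinal item-response data
#'
#' Validates an n x d matrix of ordinal responses and relabels each
#' item's observed categories to a dense 0-based range.  Input coded
#' 1..K (no zeros anywhere) is shifted down automatically; gaps in the
#' observed categories of an item are collapsed with a message, since
#' unobserved categories carry zero-width cutpoints that the Markov-tree
#' part of the model cannot divide by.  Missing values are rejected.
#'
#' @param y integer matrix or data frame of item responses.
#' @param labels optional item labels (defaults to column names).
#' @return object of class `"ordinal_data"`: the relabelled integer
#'   matrix with attributes `K` (per-item category counts) and `labels`.
#' @export
ordinal_data <- function(y, labels = NULL) {
  if (inherits(y, "ordinal_data")) return(y)
  y <- as.matrix(y)
  if (any(is.na(y)))
    stop("missing values are not supported; remove incomplete rows",
         call. = FALSE)
  if (!is.numeric(y) || any(y != round(y)))
    stop("responses must be integers", call. = FALSE)
  storage.mode(y) <- "integer"
  if (is.null(labels))
    labels <- if (!is.null(colnames(y))) colnames(y)
              else paste0("item", seq_len(ncol(y)))
  if (min(y) >= 1L) {
    message("input coded 1..K detected; shifting to 0-based categories")
    y <- y - 1L
  }
  if (min(y) < 0L) stop("categories must be coded 0, 1, 2, ...",
                        call. = FALSE)
  K <- integer(ncol(y))
  for (j in seq_len(ncol(y))) {
    lev <- sort(unique(y[, j]))
    if (length(lev) < 2L)
      stop("item ", j, " has a single observed category", call. = FALSE)
    if (!identical(lev, seq_along(lev) - 1L)) {
      message("item ", j, ": collapsing unobserved categories (",
              paste(setdiff(0:max(lev), lev), collapse = ", "), ")")
      y[, j] <- match(y[, j], lev) - 1L
    }
    K[j] <- length(lev)
  }
  structure(y, K = K, labels = labels, class = c("ordinal_data", "matrix"))
}

#' @export
print.ordinal_data <- function(x, ...) {
  cat(sprintf("ordinal_data: n = %d rows, d = %d items, categories %s\n",
              nrow(x), ncol(x),
              paste(range(attr(x, "K")), collapse = "-")))
  print(head(unclass(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Read ordinal responses from a CSV file
#'
#' Comma-separated values, one row per respondent, one column per item.
#' A header row is auto-detected (non-numeric first line).  Categories
#' are validated and relabelled through [ordinal_data()].
#'
#' @param path file path.
#' @param sep field separator.
#' @return an [ordinal_data()] object.
#' @export
read_ordinal_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- all(is.na(suppressWarnings(as.numeric(first))))
  df <- read.table(path, sep = sep, header = has_header,
                   stringsAsFactors = FALSE)
  for (cc in seq_along(df)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) |
                   df[[cc]] == "")
    if (length(bad))
      stop("non-numeric or empty cell at row ", bad[1], ", column ", cc,
           " of ", path, call. = FALSE)
  }
  ordinal_data(as.matrix(df))
}

#' Write ordinal responses to a CSV file
#'
#' @param data an [ordinal_data()] object or integer matrix.
#' @param path file path.
#' @export
write_ordinal_csv <- function(data, path) {
  y <- unclass(ordinal_data(data))
  attributes(y) <- attributes(y)["dim"]
  colnames(y) <- attr(ordinal_data(data), "labels")
  write.table(y, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Estimate cutpoints from univariate sample proportions
#'
#' First step of the IFM method: the uniform-scale cutpoints of item j
#' are the cumulative sample proportions `a_{j,k} = sum_{y<=k} p_{j,y}`,
#' with `a_{j,0} = 0` and `a_{j,K} = 1` fixed.  Normal-scale images
#' `alpha = qnorm(a)` are attached.
#'
#' @param data an [ordinal_data()] object or matrix coercible to one.
#' @return object of class `"cutpoints"`: list with `a` (list of numeric
#'   vectors of length K_j + 1), `alpha`, and `K`.
#' @export
estimate_cutpoints <- function(data) {
  y <- ordinal_data(data)
  K <- attr(y, "K")
  a <- lapply(seq_len(ncol(y)), function(j) {
    p <- tabulate(y[, j] + 1L, nbins = K[j]) / nrow(y)
    c(0, cumsum(p)[-K[j]], 1)
  })
  new_cutpoints(a)
}

#' Construct cutpoints from uniform-scale thresholds
#'
#' @param a list (one element per item) of interior cutpoints in (0, 1),
#'   strictly increasing; the endpoints 0 and 1 may be included or are
#'   added.
#' @return a `"cutpoints"` object.
#' @export
cutpoints <- function(a) {
  a <- lapply(a, function(aj) {
    aj <- as.numeric(aj)
    if (length(aj) && aj[1] != 0) aj <- c(0, aj)
    if (aj[length(aj)] != 1) aj <- c(aj, 1)
    aj
  })
  new_cutpoints(a)
}

new_cutpoints <- function(a) {
  for (j in seq_along(a)) {
    aj <- a[[j]]
    if (aj[1] != 0 || aj[length(aj)] != 1)
      stop("cutpoints of item ", j, " must start at 0 and end at 1",
           call. = FALSE)
    if (any(diff(aj) <= 0))
      stop("cutpoints of item ", j, " must be strictly increasing ",
           "(collapse zero-frequency categories first)", call. = FALSE)
  }
  structure(list(a = a,
                 alpha = lapply(a, qnorm),
                 K = vapply(a, function(x) length(x) - 1L, 1L)),
            class = "cutpoints")
}

#' @export
print.cutpoints <- function(x, ...) {
  cat("cutpoints for", length(x$a), "items;",
      "categories:", paste(range(x$K), collapse = "-"), "\n")
  invisible(x)
}
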