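#' Ordinal response matrix
#'
#' The pipeline's universal input: a persons-by-items matrix of ordinal
#' category codes. Codes must be consecutive integers starting at 0 up to a
#' per-item maximum `m[i]`; missing responses are `NA`. Instruments whose raw
#' scoring is not consecutive (the CUDIT-R's item 8 is scored 0/2/4) must be
#' mapped to categories first; see [cudit_raw_maps()] and [raw_to_matrix()].
#'
#' @param responses integer matrix (persons x items), entries in `0..m[i]` or
#'   `NA`.
#' @param item_ids character vector of item labels; defaults to column names
#'   or `item_1..item_k`.
#' @param m integer vector of per-item top category indices; defaults to the
#'   observed per-item maximum.
#' @return an object of class `response_matrix` with elements `responses`,
#'   `item_ids`, `m`.
#' @export
response_matrix <- function(responses, item_ids = NULL, m = NULL) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) stop_domain("responses must be numeric category codes")
  storage.mode(responses) <- "double"
  n_items <- ncol(responses)
  item_ids <- item_ids %||% colnames(responses) %||% paste0("item_", seq_len(n_items))
  if (length(item_ids) != n_items) stop_domain("item_ids length must match number of columns")
  obs <- responses[!is.na(responses)]
  if (any(obs != floor(obs))) stop_domain("responses must be integer category codes")
  m <- m %||% apply(responses, 2, function(x) max(x, na.rm = TRUE))
  m <- as.integer(m)
  if (length(m) != n_items) stop_domain("m must give one top category per item")
  if (any(m < 1)) stop_domain("every item needs at least two categories (m >= 1)")
  for (i in seq_len(n_items)) {
    x <- responses[, i]
    bad <- !is.na(x) & (x < 0 | x > m[i])
    if (any(bad)) {
      stop_domain(sprintf("item %s: responses outside 0..%d in rows %s",
                          item_ids[i], m[i],
                          paste(utils::head(which(bad), 5), collapse = ", ")))
    }
  }
  n_persons_obs <- sum(rowSums(!is.na(responses)) > 0)
  n_items_obs <- sum(colSums(!is.na(responses)) > 0)
  if (n_persons_obs < 2 || n_items_obs < 2) {
    stop_domain("need at least 2 persons and 2 items with non-missing data")
  }
  colnames(responses) <- item_ids
  structure(list(responses = responses, item_ids = item_ids, m = m),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items; top categories: %s\n",
              nrow(x$responses), length(x$item_ids),
              paste(x$m, collapse = "/")))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Raw-code to category maps for the CUDIT-R layout
#'
#' Items 1-7 are scored 0-4 and map to themselves; item 8 is scored 0/2/4 and
#' maps to categories 0/1/2. Each map is a data frame with columns `raw` and
#' `category`.
#'
#' @return named list of 8 maps.
#' @export
cudit_raw_maps <- function() {
  maps <- c(
    lapply(1:7, function(i) data.frame(raw = 0:4, category = 0:4)),
    list(data.frame(raw = c(0, 2, 4), category = 0:2))
  )
  names(maps) <- paste0("item_", 1:8)
  maps
}

#' Map raw instrument codes to consecutive categories
#'
#' @param raw data frame or matrix of raw codes, one column per item, columns
#'   named as in `maps`.
#' @param maps named list of raw/category maps as from [cudit_raw_maps()].
#' @return a [response_matrix()] on the category scale.
#' @export
raw_to_matrix <- function(raw, maps = cudit_raw_maps()) {
  raw <- as.data.frame(raw)
  missing_cols <- setdiff(names(maps), names(raw))
  if (length(missing_cols)) {
    stop_domain("raw data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow(raw), length(maps),
                dimnames = list(NULL, names(maps)))
  for (j in names(maps)) {
    map <- maps[[j]]
    x <- raw[[j]]
    idx <- match(x, map$raw)
    bad <- !is.na(x) & is.na(idx)
    if (any(bad)) {
      stop_domain(sprintf("%s: invalid raw code(s) %s (allowed: %s)", j,
                          paste(unique(x[bad]), collapse = ", "),
                          paste(map$raw, collapse = "/")))
    }
    out[, j] <- map$category[idx]
  }
  response_matrix(out, item_ids = names(maps),
                  m = vapply(maps, function(mp) max(mp$category), numeric(1)))
}

#' Map category codes back to raw instrument codes
#'
#' @param mat a [response_matrix()] on the category scale.
#' @param maps named list of raw/category maps.
#' @return data frame of raw codes.
#' @export
matrix_to_raw <- function(mat, maps = cudit_raw_maps()) {
  stopifnot(inherits(mat, "response_matrix"))
  out <- as.data.frame(mat$responses)
  for (j in intersect(names(maps), names(out))) {
    map <- maps[[j]]
    out[[j]] <- map$raw[match(out[[j]], map$category)]
  }
  out
}
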