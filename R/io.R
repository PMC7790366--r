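#' Write a cohort of choice datasets as tabular text
#'
#' One long CSV (comma default; tab accepted on read), UTF-8, header
#' required, fixed column registry: `participant`, `trial`, `block`,
#' `left`, `right`, `chosen`, `rt` (seconds, empty when absent). When
#' datasets carry ground-truth provenance a JSON sidecar
#' `<path>.provenance.json` records the generating model, parameters and
#' seed per participant.
#'
#' @param cohort A `cbl_data` data frame or list of them.
#' @param path Output file path.
#' @param sidecar Write the provenance sidecar if any provenance exists.
#' @return Invisibly, `path`.
#' @export
write_choice_data <- function(cohort, path, sidecar = TRUE) {
  if (is.data.frame(cohort)) cohort <- list(cohort)
  cols <- c("participant", "trial", "block", "left", "right", "chosen", "rt")
  long <- do.call(rbind, lapply(cohort, function(d) {
    if (!"rt" %in% names(d)) d$rt <- NA_real_
    if (!"block" %in% names(d)) d$block <- NA_integer_
    as.data.frame(d)[cols]
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  prov <- lapply(cohort, attr, "provenance")
  names(prov) <- vapply(cohort, function(d)
    as.character(d$participant[1]), character(1))
  prov <- prov[!vapply(prov, is.null, logical(1))]
  if (sidecar && length(prov)) {
    jsonlite::write_json(
      lapply(prov, function(p)
        list(model = p$model, params = as.list(p$params), seed = p$seed)),
      paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort of choice datasets from tabular text
#'
#' Parses the format written by [write_choice_data()] into one validated
#' `cbl_data` per participant. Rows violating the invariants — chosen
#' item not on screen, non-positive RT, non-increasing trial index — are
#' reported with their file line numbers.
#'
#' @param path CSV/TSV file with the documented columns.
#' @param n_items Number of items; inferred from the data when `NULL`.
#' @return Named list of `cbl_data`, one per participant.
#' @export
read_choice_data <- function(path, n_items = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("participant", "trial", "left", "right", "chosen")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  if (!"block" %in% names(df)) df$block <- NA_integer_
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- df$chosen != df$left & df$chosen != df$right
  if (any(bad))
    stop("chosen item not on screen at line(s): ",
         paste(utils::head(line[bad], 10L), collapse = ", "),
         call. = FALSE)
  bad_rt <- !is.na(df$rt) & df$rt <= 0
  if (any(bad_rt))
    stop("non-positive rt at line(s): ",
         paste(utils::head(line[bad_rt], 10L), collapse = ", "),
         call. = FALSE)
  if (is.null(n_items)) n_items <- max(df$left, df$right)
  out <- lapply(split(df, factor(df$participant,
                                 levels = unique(df$participant))),
                function(d) {
    if (any(diff(d$trial) <= 0))
      stop("trial indices not strictly increasing for participant ",
           d$participant[1], call. = FALSE)
    rownames(d) <- NULL
    attr(d, "n_items") <- as.integer(n_items)
    class(d) <- c("cbl_data", "data.frame")
    d
  })
  out
}

#' Write / read per-item ratings as tabular text
#'
#' Columns `participant`, `item`, `rating` (integers 1-5).
#'
#' @param ratings Data frame (or list of them) with the rating columns.
#' @param path File path.
#' @return `read_ratings` returns one long data frame.
#' @export
write_ratings <- function(ratings, path) {
  if (!is.data.frame(ratings)) ratings <- do.call(rbind, ratings)
  utils::write.csv(ratings[c("participant", "item", "rating")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path)
  need <- c("participant", "item", "rating")
  if (!all(need %in% names(df)))
    stop("ratings file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!df$rating %in% 1:5))
    stop("ratings must be integers in 1..5", call. = FALSE)
  df[need]
}
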