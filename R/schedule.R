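#' Build a round-robin preference-judgment trial schedule
#'
#' Enumerates every unordered pair of `n_items` stimuli exactly once,
#' shuffles the trial order uniformly, randomizes which member appears on
#' the left vs right of the screen independently per trial, and assigns
#' sequential block indices. With the default design of 15 items and
#' 21-trial blocks this yields the canonical 105-trial, 5-block session
#' in which every item appears 14 times.
#'
#' @param n_items Number of stimuli (>= 2).
#' @param block_size Trials per block. If the pair count is not divisible
#'   by `block_size` the final block is short and a warning is issued.
#' @param seed Optional integer seed; each simulated participant should
#'   draw a fresh schedule (order and sides were randomized across
#'   participants in the design this mirrors).
#' @return A data frame of class `cbl_schedule` with columns `trial`,
#'   `block`, `left`, `right` and attribute `n_items`.
#' @export
#' @examples
#' sch <- build_schedule(15, 21, seed = 1)
#' nrow(sch)           # 105
#' max(sch$block)      # 5
build_schedule <- function(n_items, block_size = 21, seed = NULL) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2)
    stop("invalid design: n_items must be >= 2", call. = FALSE)
  n_items <- as.integer(n_items)
  pairs <- utils::combn(n_items, 2)
  n_pairs <- ncol(pairs)
  if (n_pairs %% block_size != 0)
    warning("pair count ", n_pairs, " not divisible by block_size ",
            block_size, "; final block is short", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n_pairs)
  flip <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  a <- pairs[1, ord]
  b <- pairs[2, ord]
  left <- ifelse(flip, b, a)
  right <- ifelse(flip, a, b)
  out <- data.frame(
    trial = seq_len(n_pairs),
    block = ceiling(seq_len(n_pairs) / block_size),
    left = as.integer(left),
    right = as.integer(right))
  attr(out, "n_items") <- n_items
  class(out) <- c("cbl_schedule", "data.frame")
  out
}

#' Check a trial schedule against the design invariants
#'
#' Report-only diagnostics: complete single coverage of all unordered
#' pairs, no self-pairs, per-item presentation counts (each item should
#' appear `n_items - 1` times), and left/right side balance.
#'
#' @param schedule A `cbl_schedule` or data frame with columns `left`,
#'   `right` (and optionally attribute `n_items`).
#' @return A list with logical `ok`, character `problems`, integer
#'   `item_counts`, `n_trials`, `n_expected_pairs`, and a `side_balance`
#'   summary (per-item left-appearance proportion).
#' @export
validate_schedule <- function(schedule) {
  left <- schedule$left
  right <- schedule$right
  n_items <- attr(schedule, "n_items")
  if (is.null(n_items)) n_items <- max(left, right)
  problems <- character(0)
  if (any(left == right))
    problems <- c(problems, "self-paired trials present")
  key <- paste(pmin(left, right), pmax(left, right))
  if (anyDuplicated(key))
    problems <- c(problems, "duplicated pairs present")
  n_expected <- n_items * (n_items - 1L) / 2L
  if (length(unique(key)) != n_expected)
    problems <- c(problems, sprintf(
      "pair coverage incomplete: %d unique pairs of %d expected",
      length(unique(key)), n_expected))
  if (length(key) != n_expected)
    problems <- c(problems, sprintf(
      "trial count %d differs from expected %d", length(key), n_expected))
  counts <- tabulate(c(left, right), nbins = n_items)
  if (any(counts != n_items - 1L))
    problems <- c(problems, "per-item presentation counts unequal")
  lefts <- tabulate(left, nbins = n_items)
  list(ok = length(problems) == 0L,
       problems = problems,
       item_counts = counts,
       n_trials = length(key),
       n_expected_pairs = n_expected,
       side_balance = ifelse(counts > 0, lefts / counts, NA_real_))
}

#' Write / read a schedule as tabular text
#'
#' One row per trial with fixed columns `trial`, `block`, `left`,
#' `right`; comma-separated, header required.
#'
#' @param schedule A `cbl_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `cbl_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[c("trial", "block", "left", "right")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "block", "left", "right")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  attr(df, "n_items") <- max(df$left, df$right)
  class(df) <- c("cbl_schedule", "data.frame")
  df
}
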