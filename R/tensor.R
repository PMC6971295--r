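#' Labeled three-way data tensor
#'
#' Container for an `S x T x K` array of locomotion data: `S` channels
#' (joint angles or muscles), `T` time frames of the normalized gait cycle,
#' and `K` tasks, where a task is one (subject, speed) combination. Task
#' metadata travels with the array as a tibble so downstream statistics can
#' refer to speeds and movement modes by name.
#'
#' @param x numeric 3-d array, `channels x frames x tasks`. No missing values.
#' @param channels character vector of channel labels (length `dim(x)[1]`),
#'   or `NULL` for automatic `ch1..chS` labels.
#' @param tasks tibble/data.frame of task descriptors with one row per task
#'   (columns typically `subject`, `speed`, `mode`, optionally `speed_bin`),
#'   or `NULL` for a bare index.
#' @param nonneg logical; declare the tensor non-negative (checked).
#'
#' @return An object of class `data_tensor`: the array with `channels`,
#'   `tasks` and `nonneg` attributes.
#' @export
#' @examples
#' x <- array(runif(6 * 20 * 4), dim = c(6, 20, 4))
#' dt <- data_tensor(x, nonneg = TRUE)
#' dim(dt)
data_tensor <- function(x, channels = NULL, tasks = NULL, nonneg = FALSE) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("`x` must be a 3-d array (channels x frames x tasks)", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("data tensor contains missing or non-finite values", call. = FALSE)
  }
  d <- dim(x)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[1]))
  if (length(channels) != d[1]) {
    stop("`channels` must have length ", d[1], call. = FALSE)
  }
  if (is.null(tasks)) {
    tasks <- tibble::tibble(task = seq_len(d[3]))
  } else {
    tasks <- tibble::as_tibble(tasks)
    if (nrow(tasks) != d[3]) {
      stop("`tasks` must have one row per task (", d[3], ")", call. = FALSE)
    }
  }
  if (nonneg && any(x < 0)) {
    stop("tensor flagged non-negative but has negative entries", call. = FALSE)
  }
  structure(unclass(x),
    dim = d,
    channels = as.character(channels),
    tasks = tasks,
    nonneg = isTRUE(nonneg),
    class = "data_tensor"
  )
}

#' @export
print.data_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<data_tensor> %d channels x %d frames x %d tasks%s\n",
    d[1], d[2], d[3], if (attr(x, "nonneg")) " (non-negative)" else ""
  ))
  invisible(x)
}

#' @rdname data_tensor
#' @param dt a `data_tensor`.
#' @export
task_table <- function(dt) attr(dt, "tasks")

#' @rdname data_tensor
#' @export
channel_labels <- function(dt) attr(dt, "channels")

is_nonneg_tensor <- function(dt) isTRUE(attr(dt, "nonneg"))

as_plain_array <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

# Mode-n unfolding, Kolda-Bader convention: mode-n fibers become rows and the
# remaining modes vary with the earlier one fastest.
unfold_tensor <- function(x, mode) {
  x <- as_plain_array(x)
  d <- dim(x)
  switch(mode,
    `1` = { dim(x) <- c(d[1], d[2] * d[3]); x },
    `2` = { x <- aperm(x, c(2L, 1L, 3L)); dim(x) <- c(d[2], d[1] * d[3]); x },
    `3` = { x <- aperm(x, c(3L, 1L, 2L)); dim(x) <- c(d[3], d[1] * d[2]); x },
    stop("mode must be 1, 2 or 3", call. = FALSE)
  )
}

# Column-wise Khatri-Rao product: column r is kronecker(A[, r], B[, r]), so
# the row index of B varies fastest -- matching unfold_tensor().
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' Stack a tensor into the channel-by-(time x task) matrix
#'
#' Rearranges an `S x T x K` tensor as the `S x (T*K)` matrix used by the
#' matrix-decomposition baselines: columns are ordered task-major, i.e. the
#' `T` frames of task 1, then the `T` frames of task 2, and so on. The
#' operation is lossless; [unstack_temporal()] splits a stacked temporal
#' module back into its `K` per-task curves.
#'
#' @param dt a [data_tensor()] (or plain 3-d array).
#' @return An `S x (T*K)` matrix with attributes `n_frames` and `n_tasks`.
#' @export
stack_tasks <- function(dt) {
  d <- dim(dt)
  z <- unfold_tensor(dt, 1L)
  attr(z, "n_frames") <- d[2]
  attr(z, "n_tasks") <- d[3]
  z
}

#' @rdname stack_tasks
#' @param p a stacked temporal module of length `T*K` (one column of the
#'   temporal factor of a matrix model).
#' @param n_frames,n_tasks frame and task counts `T`, `K`.
#' @return `unstack_temporal()`: a `T x K` matrix, column `k` holding the
#'   temporal curve of task `k`.
#' @export
unstack_temporal <- function(p, n_frames, n_tasks) {
  if (length(p) != n_frames * n_tasks) {
    stop("length(p) must equal n_frames * n_tasks", call. = FALSE)
  }
  matrix(p, nrow = n_frames, ncol = n_tasks)
}

#' @rdname stack_tasks
#' @param z an `S x (T*K)` matrix in task-major column order.
#' @param channels,tasks,nonneg passed to [data_tensor()].
#' @return `unstack_tensor()`: the `data_tensor` whose [stack_tasks()] is `z`.
#' @export
unstack_tensor <- function(z, n_frames, n_tasks, channels = NULL,
                           tasks = NULL, nonneg = FALSE) {
  stopifnot(ncol(z) == n_frames * n_tasks)
  x <- array(as.numeric(z), dim = c(nrow(z), n_frames, n_tasks))
  data_tensor(x, channels = channels, tasks = tasks, nonneg = nonneg)
}

#' Write or read a labeled tensor as plain-text files
#'
#' The on-disk container is a pair of text files: `<prefix>.csv` holds the
#' array in long format (`channel`, `frame`, `task`, `value`) and
#' `<prefix>.json` holds the metadata (dimensions, channel labels, task
#' descriptor table, non-negativity flag, and any extra fields supplied via
#' `extra`). The round trip is exact to full double precision.
#'
#' @param dt a [data_tensor()].
#' @param prefix path prefix (without extension) for the two files.
#' @param extra named list of additional metadata (e.g. seed, config echo).
#' @return `write_data_tensor()` returns `prefix` invisibly;
#'   `read_data_tensor()` returns the reconstructed `data_tensor` with the
#'   extra metadata in attribute `meta`.
#' @export
write_data_tensor <- function(dt, prefix, extra = list()) {
  d <- dim(dt)
  long <- data.frame(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    task = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.numeric(dt)
  )
  utils::write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- c(list(
    dim = d,
    channels = channel_labels(dt),
    tasks = as.data.frame(task_table(dt)),
    nonneg = is_nonneg_tensor(dt)
  ), extra)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(prefix)
}

#' @rdname write_data_tensor
#' @export
read_data_tensor <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(prefix, ".csv"))
  d <- as.integer(meta$dim)
  x <- array(0, dim = d)
  x[cbind(long$channel, long$frame, long$task)] <- long$value
  dt <- data_tensor(x,
    channels = meta$channels,
    tasks = tibble::as_tibble(meta$tasks),
    nonneg = isTRUE(meta$nonneg)
  )
  keep <- setdiff(names(meta), c("dim", "channels", "tasks", "nonneg"))
  attr(dt, "meta") <- meta[keep]
  dt
}
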