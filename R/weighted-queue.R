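#' Weighted FIFO queue
#'
#' Fixed-capacity FIFO of recent values with positional weights that grow
#' linearly from 1 at the exit (oldest entry) to the queue length at the
#' entrance (newest entry), so recent observations dominate the weighted
#' mean. The detector uses one such queue per event type for recent stride
#' intervals (to derive the adaptive sleep time) and one for recent accepted
#' peak amplitudes (to derive the adaptive threshold).
#'
#' @param capacity Positive integer maximum number of entries.
#' @param entries Optional initial entries, oldest first; only the most
#'   recent `capacity` are kept.
#' @return An object of class `weighted_queue`.
#' @examples
#' q <- weighted_queue(3, c(30, 60, 90))
#' weighted_mean(q)  # (30*1 + 60*2 + 90*3) / 6 = 70
#' @export
weighted_queue <- function(capacity, entries = numeric(0)) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1) stop("'capacity' must be >= 1")
  entries <- as.numeric(entries)
  if (length(entries) > capacity) {
    entries <- entries[(length(entries) - capacity + 1):length(entries)]
  }
  structure(list(capacity = capacity, entries = entries),
            class = "weighted_queue")
}

#' Push a value into a weighted queue
#'
#' Appends at the entrance; when full, the oldest entry is evicted.
#'
#' @param queue A [weighted_queue].
#' @param x Numeric value(s) to push, in arrival order.
#' @return The updated queue.
#' @export
wq_push <- function(queue, x) {
  stopifnot(inherits(queue, "weighted_queue"))
  e <- c(queue$entries, as.numeric(x))
  if (length(e) > queue$capacity) {
    e <- e[(length(e) - queue$capacity + 1):length(e)]
  }
  queue$entries <- e
  queue
}

#' Positionally weighted mean of a queue
#'
#' `sum(entries[i] * w_i) / sum(w_i)` with `w_i = i` counted from the exit
#' over the currently filled positions, i.e. weights `1..length(entries)`.
#' Both the adaptive sleep time and the adaptive threshold are weighted
#' means of this form.
#'
#' @param queue A [weighted_queue].
#' @param empty Value returned for an empty queue (default `NA_real_`);
#'   callers supply their cold-start fallback here so no division by zero
#'   can occur.
#' @return A single numeric value.
#' @export
weighted_mean <- function(queue, empty = NA_real_) {
  stopifnot(inherits(queue, "weighted_queue"))
  k <- length(queue$entries)
  if (k == 0) return(empty)
  w <- seq_len(k)
  sum(queue$entries * w) / sum(w)
}

#' @export
print.weighted_queue <- function(x, ...) {
  cat(sprintf("<weighted_queue> %d/%d entries: %s\n",
              length(x$entries), x$capacity,
              paste(signif(x$entries, 4), collapse = ", ")))
  invisible(x)
}

#' @export
length.weighted_queue <- function(x) length(x$entries)
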