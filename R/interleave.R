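#' Enumerate admissible orders of a small set of update events
#'
#' An update event is a directed relaxation `from -> to` between adjacent
#' voxels. Given a set of events and optional precedence constraints (a
#' DAG-with-alternatives: event `i` must run before event `j`), returns every
#' admissible total order. Used to replay each interleaving of the
#' block-asynchrony analysis through [apply_events()] and classify which
#' orders would mis-propagate without correction.
#'
#' @param events List of events, each a `list(from = c(x, y, z), to = c(x, y, z))`.
#' @param before Optional 2-column integer matrix of (earlier, later) event
#'   indices that constrain the order.
#' @return List of integer vectors, each a permutation of
#'   `seq_along(events)`. The empty event set yields one empty order.
#' @examples
#' ev <- list(list(from = c(0, 0, 0), to = c(1, 0, 0)),
#'            list(from = c(0, 0, 0), to = c(0, 1, 0)))
#' length(enumerate_interleavings(ev))  # two independent events: 2 orders
#' @export
enumerate_interleavings <- function(events, before = NULL) {
  n <- length(events)
  if (n > 10L) stop("event set too large (> 10 events)")
  if (n == 0L) return(list(integer(0)))
  pred <- vector("list", n)
  if (!is.null(before)) {
    before <- matrix(as.integer(before), ncol = 2L)
    if (any(before < 1L) || any(before > n)) stop("precedence index out of range")
    for (k in seq_len(nrow(before)))
      pred[[before[k, 2]]] <- c(pred[[before[k, 2]]], before[k, 1])
  }
  out <- list()
  used <- logical(n)
  cur <- integer(0)
  rec <- function() {
    if (length(cur) == n) { out[[length(out) + 1L]] <<- cur; return(invisible()) }
    for (i in seq_len(n)) {
      if (used[i]) next
      if (length(pred[[i]]) && !all(used[pred[[i]]])) next
      used[i] <<- TRUE; cur <<- c(cur, i)
      rec()
      used[i] <<- FALSE; cur <<- cur[-length(cur)]
    }
  }
  rec()
  if (length(out) == 0L) stop("precedence constraints are cyclic")
  out
}

#' Replay an explicit sequence of update events
#'
#' Applies relaxation events one by one to a connectivity array: event
#' `from -> to` offers `min(fc[from], mu_k(from, to))` and writes it iff it
#' strictly exceeds `fc[to]`. Each event fires exactly once — a voxel
#' improved *after* its own outgoing event has fired never re-propagates,
#' which is precisely the consumed-flag failure of asynchronous block
#' execution that the correction iterations repair.
#'
#' @param fc 3-D numeric array of initial connectivity values.
#' @param events Event list as for [enumerate_interleavings()].
#' @param order Integer vector: the order in which to fire the events.
#' @inheritParams kfoe_reference
#' @return The final connectivity array.
#' @export
apply_events <- function(fc, events, order, lut, vol) {
  for (i in order) {
    ev <- events[[i]]
    a <- as.integer(ev$from) + 1L
    b <- as.integer(ev$to) + 1L
    mu <- lut_affinity(lut, ev$from, ev$to, vol)
    cand <- min(fc[a[1], a[2], a[3]], mu)
    if (cand > fc[b[1], b[2], b[3]]) fc[b[1], b[2], b[3]] <- cand
  }
  fc
}
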