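# Pending-exam worklist: a priority queue with stable FIFO order inside each
# priority tier and an aging rule that promotes long-waiting exams to a
# dedicated front tier (rank 0).

#' Create an empty worklist
#'
#' A worklist holds pending exams sorted by `(priority_rank, insertion
#' order)`; ties in rank preserve first-in, first-out order.  Promoted exams
#' occupy rank 0 ahead of everything else and are ordered among themselves
#' by acquisition time (oldest first).
#'
#' @return An object of class `worklist`.
#' @export
worklist <- function() {
  structure(list(id = integer(0), acq = numeric(0), rank = integer(0),
                 promoted = logical(0), seq = integer(0), next_seq = 1L),
            class = "worklist")
}

#' @export
length.worklist <- function(x) length(x$id)

#' @export
print.worklist <- function(x, ...) {
  cat(sprintf("<worklist> %d pending exam(s)\n", length(x)))
  if (length(x))
    print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
as.data.frame.worklist <- function(x, ...) {
  data.frame(exam_id = x$id, acquisition_time = x$acq, priority_rank = x$rank,
             promoted = x$promoted)
}

#' Insert an exam by priority
#'
#' The new item is placed after every pending item of equal or more urgent
#' (lower or equal) rank and before every strictly less urgent item, so
#' exams within a tier are read in acquisition order.
#'
#' @param wl a [worklist()].
#' @param id unique exam identifier.
#' @param acq acquisition time in minutes.
#' @param rank priority rank (1 = most urgent; K+1 = normal tier).
#' @return The updated worklist.
#' @export
wl_insert <- function(wl, id, acq, rank) {
  stopifnot(inherits(wl, "worklist"))
  if (id %in% wl$id) stop("duplicate exam_id: ", id)
  rank <- as.integer(rank)
  pos <- sum(wl$rank <= rank)
  wl$id <- append(wl$id, id, after = pos)
  wl$acq <- append(wl$acq, acq, after = pos)
  wl$rank <- append(wl$rank, rank, after = pos)
  wl$promoted <- append(wl$promoted, FALSE, after = pos)
  wl$seq <- append(wl$seq, wl$next_seq, after = pos)
  wl$next_seq <- wl$next_seq + 1L
  wl
}

#' Append an exam in plain first-in, first-out order
#'
#' Equivalent to [wl_insert()] when every exam shares one rank: the item
#' goes to the tail and exams are read strictly in acquisition order.
#'
#' @inheritParams wl_insert
#' @param rank rank recorded on the item (does not affect FIFO order).
#' @export
wl_fifo_insert <- function(wl, id, acq, rank = 1L) {
  stopifnot(inherits(wl, "worklist"))
  if (id %in% wl$id) stop("duplicate exam_id: ", id)
  n <- length(wl$id)
  wl$id <- c(wl$id, id)
  wl$acq <- c(wl$acq, acq)
  wl$rank <- c(wl$rank, as.integer(rank))
  wl$promoted <- c(wl$promoted, FALSE)
  wl$seq <- c(wl$seq, wl$next_seq)
  wl$next_seq <- wl$next_seq + 1L
  wl
}

#' Remove and return the head of the worklist
#'
#' @param wl a non-empty [worklist()].
#' @return `list(item, worklist)`: `item` is a list with `id`, `acq`,
#'   `rank`, `promoted`; `worklist` is the remainder.  An empty worklist is
#'   an error — the simulator checks emptiness and lets the radiologist
#'   idle instead of popping.
#' @export
wl_pop_head <- function(wl) {
  stopifnot(inherits(wl, "worklist"))
  if (!length(wl$id)) stop("empty worklist")
  item <- list(id = wl$id[1L], acq = wl$acq[1L], rank = wl$rank[1L],
               promoted = wl$promoted[1L])
  wl$id <- wl$id[-1L]; wl$acq <- wl$acq[-1L]; wl$rank <- wl$rank[-1L]
  wl$promoted <- wl$promoted[-1L]; wl$seq <- wl$seq[-1L]
  list(item = item, worklist = wl)
}

#' Promote exams that have waited longer than the maximum waiting time
#'
#' Every pending exam whose waiting time `now - acquisition` strictly
#' exceeds `t_max` is assigned rank 0 and moved ahead of all non-promoted
#' exams; promoted exams are ordered among themselves by acquisition time
#' (oldest first).  Calling twice with the same clock is a no-op the second
#' time.
#'
#' @param wl a [worklist()].
#' @param now current time in minutes.
#' @param t_max maximum waiting time in minutes (> 0).
#' @return The updated worklist.
#' @export
wl_promote_overdue <- function(wl, now, t_max) {
  stopifnot(inherits(wl, "worklist"), t_max > 0)
  overdue <- !wl$promoted & (now - wl$acq > t_max)
  if (!any(overdue)) return(wl)
  promoted <- wl$promoted | overdue
  prom_idx <- which(promoted)
  prom_idx <- prom_idx[order(wl$acq[prom_idx])]
  ord <- c(prom_idx, which(!promoted))
  wl$id <- wl$id[ord]; wl$acq <- wl$acq[ord]; wl$rank <- wl$rank[ord]
  wl$promoted <- promoted[ord]; wl$seq <- wl$seq[ord]
  wl$rank[wl$promoted] <- 0L
  wl
}
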