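# Shared test helpers: a reference worklist model that re-sorts the full
# pending set with a stable sort at every step, and histogram constructors.

# Reference worklist: plain record table in insertion order; the queue
# order is recomputed from scratch by a stable sort at each inspection.
ref_worklist <- function() {
  data.frame(id = integer(0), acq = numeric(0), rank = integer(0),
             promoted = logical(0), seq = integer(0))
}

ref_insert <- function(m, id, acq, rank) {
  nxt <- if (nrow(m)) max(m$seq) + 1L else 1L
  rbind(m, data.frame(id = id, acq = acq, rank = as.integer(rank),
                      promoted = FALSE, seq = nxt))
}

ref_order <- function(m) {
  if (!nrow(m)) return(m)
  tier <- ifelse(m$promoted, 0L, m$rank)
  within_tier <- ifelse(m$promoted, m$acq, m$seq)
  m[order(tier, within_tier), , drop = FALSE]
}

ref_pop <- function(m) {
  ord <- ref_order(m)
  list(id = ord$id[1L], rest = m[m$id != ord$id[1L], , drop = FALSE])
}

ref_promote <- function(m, now, t_max) {
  m$promoted <- m$promoted | (now - m$acq > t_max)
  m
}

ref_ids <- function(m) ref_order(m)$id

# Histogram with a single occupied delta bin per listed hour.
hist_const <- function(delta, kind = "arrival", hours = 0:23, count = 1L) {
  counts <- matrix(0L, 24L, 150L)
  counts[hours + 1L, delta] <- count
  tod_histogram(counts, kind)
}
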