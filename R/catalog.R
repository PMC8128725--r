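# Finding catalog: urgency ranking and prevalences, plus ground-truth label
# generation for simulated chest X-rays.

#' Construct a finding catalog
#'
#' A catalog lists the radiographic findings the triage model knows about,
#' ordered by clinical urgency (rank 1 = most urgent, requires the fastest
#' read), together with each finding's prevalence among the institution's
#' chest X-rays.  "Normal" (no findings) is not a catalog row: it is the
#' implicit lowest-priority tier with rank K+1.
#'
#' @param name character vector of finding names.
#' @param rank integer urgency ranks; must be exactly 1..K, unique.
#' @param prevalence per-finding probabilities in [0, 1].
#' @return A data frame of class `finding_catalog` ordered by rank.
#' @export
finding_catalog <- function(name, rank, prevalence) {
  if (length(name) != length(rank) || length(name) != length(prevalence))
    stop("name, rank and prevalence must have equal length")
  rank <- as.integer(rank)
  if (!setequal(rank, seq_along(rank)))
    stop("ranks must be consecutive 1..K and unique")
  if (anyDuplicated(name)) stop("finding names must be unique")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalences must lie in [0, 1]")
  ord <- order(rank)
  structure(data.frame(name = as.character(name)[ord], rank = rank[ord],
                       prevalence = as.numeric(prevalence)[ord],
                       stringsAsFactors = FALSE),
            class = c("finding_catalog", "data.frame"))
}

#' Default finding catalog of the simulated institution
#'
#' Eight findings ranked by urgency as judged by expert radiologists, with
#' prevalences stored as exact fractions of the 600-exam annotation sample
#' (e.g. pneumothorax 23/600) rather than rounded percentages.
#'
#' @return A [finding_catalog()].
#' @export
default_catalog <- function() {
  positives <- c(pneumothorax = 23, congestion = 124, pleural_effusion = 236,
                 infiltrate = 100, atelectasis = 124, cardiomegaly = 117,
                 mass = 38, foreign_object = 298)
  cat <- finding_catalog(names(positives), seq_along(positives), positives / 600)
  attr(cat, "positives") <- unname(positives)
  attr(cat, "total") <- 600L
  cat
}

#' Rank assigned to exams with no positive finding
#' @param catalog a [finding_catalog()].
#' @return Integer K+1, the lowest-priority ("normal") tier.
#' @export
normal_rank <- function(catalog) nrow(catalog) + 1L

#' Read a catalog from CSV
#'
#' Expects columns `name,rank,positives,total`; prevalence is computed as
#' `positives/total` so printed roundings never compound.
#' @param path CSV file path.
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "rank", "positives", "total")
  if (!all(need %in% names(df)))
    stop("catalog CSV must have columns ", paste(need, collapse = ","))
  cat <- finding_catalog(df$name, df$rank, df$positives / df$total)
  attr(cat, "positives") <- df$positives[order(df$rank)]
  attr(cat, "total") <- df$total[order(df$rank)]
  cat
}

#' @rdname read_catalog_csv
#' @param catalog a [finding_catalog()].
#' @export
write_catalog_csv <- function(catalog, path) {
  pos <- attr(catalog, "positives")
  tot <- attr(catalog, "total")
  if (is.null(pos)) {  # fall back to a large denominator preserving prevalence
    tot <- 1e6L
    pos <- round(catalog$prevalence * tot)
  }
  utils::write.csv(data.frame(name = catalog$name, rank = catalog$rank,
                              positives = pos, total = tot),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw ground-truth label vectors
#'
#' Each finding is drawn independently Bernoulli(prevalence); an exam can
#' carry zero (a "normal" exam) up to K findings.  Independence is assumed
#' because only marginal prevalences are available; co-occurrence structure
#' of real exams is not modelled.
#'
#' @param catalog a [finding_catalog()].
#' @param n number of exams.
#' @return Logical n-by-K matrix, columns named and ordered by urgency rank.
#'   Uses the current R random stream.
#' @export
sample_labels <- function(catalog, n = 1L) {
  stopifnot(inherits(catalog, "finding_catalog"), n >= 0)
  K <- nrow(catalog)
  m <- matrix(stats::runif(n * K), n, K) <
    matrix(catalog$prevalence, n, K, byrow = TRUE)
  colnames(m) <- catalog$name
  m
}

#' Urgency rank of label vectors
#'
#' The rank of an exam is the minimum (most urgent) rank among its positive
#' findings; an exam with no positive finding falls in the "normal" tier,
#' rank K+1.  Only presence matters — neither severity nor the number of
#' co-occurring findings changes the rank.
#'
#' @param labels logical vector of length K, or an n-by-K logical matrix
#'   aligned with the catalog order.
#' @param catalog a [finding_catalog()].
#' @return Integer rank(s) in 1..K+1.
#' @export
urgency_rank <- function(labels, catalog) {
  stopifnot(inherits(catalog, "finding_catalog"))
  K <- nrow(catalog)
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1L)
  if (ncol(labels) != K)
    stop("labels length (", ncol(labels), ") does not match catalog size (", K, ")")
  r <- rep.int(K + 1L, nrow(labels))
  for (k in rev(seq_len(K)))       # descending rank: most urgent wins last
    r[labels[, k]] <- catalog$rank[k]
  r
}
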