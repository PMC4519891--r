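# Pareto machinery: dominance sorting, crowding distance, tournament
# selection.  Objectives are always minimized.

# TRUE iff objective vector a dominates b (no worse everywhere, strictly
# better somewhere)
.dominates <- function(a, b) all(a <= b) && any(a < b)

#' Fast non-dominated sort
#'
#' Partitions a set of objective vectors (rows; all objectives minimized)
#' into Pareto fronts: front 1 is the non-dominated set, front 2 is
#' non-dominated once front 1 is removed, and so on.
#'
#' @param objectives Numeric matrix, one row per individual.
#' @return List with `rank` (integer vector, 1 = first front) and `fronts`
#'   (list of integer index vectors).
#' @export
nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) return(list(rank = integer(0), fronts = list()))
  dom_count <- integer(n)            # how many dominate i
  dominated <- vector("list", n)     # whom i dominates
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      if (.dominates(objectives[p, ], objectives[q, ]))
        dominated[[p]] <- c(dominated[[p]], q)
      else if (.dominates(objectives[q, ], objectives[p, ]))
        dom_count[p] <- dom_count[p] + 1L
    }
  }
  rank <- integer(n)
  fronts <- list()
  current <- which(dom_count == 0L)
  f <- 1L
  while (length(current)) {
    rank[current] <- f
    fronts[[f]] <- current
    nxt <- integer(0)
    for (p in current) for (q in dominated[[p]]) {
      dom_count[q] <- dom_count[q] - 1L
      if (dom_count[q] == 0L) nxt <- c(nxt, q)
    }
    current <- sort(unique(nxt))
    f <- f + 1L
  }
  list(rank = rank, fronts = fronts)
}

#' Crowding distance within one front
#'
#' For each objective the front is sorted, boundary individuals get
#' infinite distance, and interior individuals accumulate the normalized
#' gap between their neighbours.  Objectives with zero spread contribute
#' nothing.
#'
#' @param objectives Numeric matrix of the front's objective vectors.
#' @return Numeric vector of distances, in input order.
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- order(objectives[, m])
    rng <- objectives[o[n], m] - objectives[o[1], m]
    d[o[1]] <- d[o[n]] <- Inf
    if (rng > 0)
      for (k in 2:(n - 1))
        d[o[k]] <- d[o[k]] + (objectives[o[k + 1], m] -
                                objectives[o[k - 1], m]) / rng
  }
  d
}

#' Binary tournament selection
#'
#' Draws two distinct individuals uniformly and returns the index of the
#' better one.  With a numeric `fitness`, lower wins (free energies).  With
#' `rank` (and optionally `crowding`), lower rank wins and rank ties go to
#' the larger crowding distance (the NSGA-II crowded comparison); remaining
#' ties go to the first drawn.
#'
#' @param fitness Numeric vector of single-objective fitness, or `NULL`.
#' @param rank Integer vector of dominance ranks (multi-objective mode).
#' @param crowding Optional numeric vector of crowding distances.
#' @return The selected index.
#' @export
tournament_select <- function(fitness = NULL, rank = NULL, crowding = NULL) {
  n <- if (!is.null(fitness)) length(fitness) else length(rank)
  if (n == 0) stop("empty population")
  if (n == 1) return(1L)
  pick <- sample.int(n, 2)
  a <- pick[1]; b <- pick[2]
  if (!is.null(fitness))
    return(if (fitness[b] < fitness[a]) b else a)
  if (rank[a] != rank[b]) return(if (rank[b] < rank[a]) b else a)
  if (!is.null(crowding) && crowding[b] > crowding[a]) return(b)
  a
}
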