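# Evolutionary engines: single-objective GA over a contact energy, and
# multi-objective NSGA / NSGA-II over (contact energy, angle preference
# energy) with the angle feasibility constraint.

#' Evolutionary run configuration
#'
#' Defaults follow the study conditions for lattice folding: population
#' size equal to the sequence length, twice that many generations,
#' crossover rate 0.85, per-individual mutation rate 1/length, mutation
#' window K = 3 and binary tournaments.
#'
#' @param n Sequence length the run will fold.
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_c Crossover probability per parent pair.
#' @param p_m Mutation probability per offspring.
#' @param k_mut Mutation window width (moves).
#' @param tournament_size Tournament size (binary; kept for provenance).
#' @param max_retries Bounded retry count when an operator keeps producing
#'   infeasible offspring.
#' @return A list of class `fold_config`.
#' @export
fold_config <- function(n, pop_size = n, generations = 2L * n, p_c = 0.85,
                        p_m = 1 / n, k_mut = 3L, tournament_size = 2L,
                        max_retries = 30L) {
  stopifnot(n >= 2, pop_size >= 2, generations >= 0, p_c >= 0, p_c <= 1,
            p_m >= 0, p_m <= 1, k_mut >= 1)
  structure(list(n = as.integer(n), pop_size = as.integer(pop_size),
                 generations = as.integer(generations), p_c = p_c, p_m = p_m,
                 k_mut = as.integer(k_mut),
                 tournament_size = as.integer(tournament_size),
                 max_retries = as.integer(max_retries)),
            class = "fold_config")
}

#' Random angle-feasible self-avoiding walk
#'
#' Depth-first backtracking growth of a SAW in which every (kappa, alpha)
#' pair that becomes defined while growing must bin to a strictly positive
#' preference cell.  Used to initialize multi-objective populations so the
#' search starts inside the feasible region.
#'
#' @param n Number of residues (>= 2).
#' @param sequence Optional sequence string (defaults to poly-alanine).
#' @param matrix Preference matrix.
#' @param max_nodes Search-node budget per attempt.
#' @param max_restarts Restart bound; on exhaustion an unconstrained SAW is
#'   returned (flagged via the `feasible` attribute).
#' @return An `fcc_conformation`; attribute `feasible` reports whether the
#'   angle constraint holds.
#' @export
random_feasible_saw <- function(n, sequence = NULL, matrix = ka_preferences(),
                                max_nodes = 20000, max_restarts = 20) {
  if (n < 2) stop("need n >= 2")
  if (is.null(sequence)) sequence <- strrep("A", n)
  coords <- base::matrix(0, n, 3)
  nodes <- 0L
  grow <- function(i) {
    if (i > n) return(TRUE)
    for (d in sample.int(12)) {
      p <- coords[i - 1, ] + .fcc_vec[d, ]
      occupied <- FALSE
      for (j in seq_len(i - 1))
        if (all(p == coords[j, ])) { occupied <- TRUE; break }
      if (occupied) next
      coords[i, ] <<- p
      if (i >= 5) {
        ctr <- i - 2
        k <- kappa_angle(coords[1:i, , drop = FALSE], ctr)
        if (k < 1e-9 || k > 180 - 1e-9) next
        a <- alpha_angle(coords[1:i, , drop = FALSE], ctr)
        if (is.na(a)) next
        b <- bin_angle_pair(k, a)
        if (is.na(b$kappa_bin) ||
            angle_preference(b$kappa_bin, b$alpha_bin, matrix) <= 0) next
      }
      nodes <<- nodes + 1L
      if (nodes > max_nodes) return(FALSE)
      if (grow(i + 1)) return(TRUE)
    }
    FALSE
  }
  for (attempt in seq_len(max_restarts)) {
    nodes <- 0L
    if (grow(2)) {
      conf <- conformation_from_coords(sequence, coords)
      attr(conf, "feasible") <- TRUE
      return(conf)
    }
  }
  conf <- random_saw(n, sequence)
  attr(conf, "feasible") <- check_angle_constraint(conf, matrix)
  conf
}

# one improving pull move (accept if it lowers `energy_fn`, else revert)
.local_search <- function(conf, energy_fn, valid = NULL) {
  cand <- generalized_pull_move(conf, valid = valid)
  if (energy_fn(cand) < energy_fn(conf)) cand else conf
}

# breed one offspring pool of >= pop_size children (single list)
.make_offspring <- function(pop, select_fn, config, energy_fn, valid = NULL) {
  offspring <- list()
  attempts <- 0L
  max_attempts <- 50L * config$pop_size
  while (length(offspring) < config$pop_size && attempts < max_attempts) {
    attempts <- attempts + 1L
    p1 <- pop[[select_fn()]]
    p2 <- pop[[select_fn()]]
    kids <- if (stats::runif(1) < config$p_c)
      rotation_crossover(p1, p2, valid = valid)
    else
      list(p1, p2)
    for (kid in kids) {
      kid <- .local_search(kid, energy_fn, valid = valid)
      if (stats::runif(1) < config$p_m)
        kid <- k_site_mutation(kid, config$k_mut,
                               tries = config$max_retries, valid = valid)
      offspring[[length(offspring) + 1]] <- kid
    }
  }
  offspring
}

.fold_single <- function(sequence, config, energy_fn) {
  n <- nchar(sequence)
  pop <- replicate(config$pop_size, random_saw(n, sequence),
                   simplify = FALSE)
  energies <- vapply(pop, energy_fn, 0)
  history <- data.frame(generation = 0L, best = min(energies),
                        median = stats::median(energies))
  for (gen in seq_len(config$generations)) {
    select_fn <- function() tournament_select(fitness = energies)
    offspring <- .make_offspring(pop, select_fn, config, energy_fn)
    merged <- c(pop, offspring)
    merged_e <- c(energies, vapply(offspring, energy_fn, 0))
    keep <- order(merged_e)[seq_len(config$pop_size)]  # elitist, stable ties
    pop <- merged[keep]
    energies <- merged_e[keep]
    history <- rbind(history,
                     data.frame(generation = gen, best = min(energies),
                                median = stats::median(energies)))
  }
  best <- which.min(energies)
  list(best = pop[[best]], best_energy = energies[best], population = pop,
       energies = energies, history = history)
}

.fold_multi <- function(sequence, config, energy_fn, ka_matrix,
                        use_crowding) {
  n <- nchar(sequence)
  feasible_fn <- function(conf) check_angle_constraint(conf, ka_matrix)
  pop <- replicate(config$pop_size,
                   random_feasible_saw(n, sequence, ka_matrix),
                   simplify = FALSE)
  feas <- vapply(pop, function(cf) isTRUE(attr(cf, "feasible")), TRUE)
  objectives <- t(vapply(pop, function(cf)
    c(energy_fn(cf), ka_energy(cf, ka_matrix)), c(0, 0)))
  colnames(objectives) <- c("energy", "ka")
  rank_pop <- function(obj, fs) {
    # infeasible individuals (possible only from initialization fallback)
    # rank after every feasible front
    rk <- rep.int(NA_integer_, nrow(obj))
    cd <- numeric(nrow(obj))
    if (any(fs)) {
      ns <- nondominated_sort(obj[fs, , drop = FALSE])
      rk[fs] <- ns$rank
      idx <- which(fs)
      for (f in ns$fronts)
        cd[idx[f]] <- crowding_distance(obj[idx[f], , drop = FALSE])
    }
    worst <- if (any(fs)) max(rk, na.rm = TRUE) else 0L
    rk[!fs] <- worst + 1L
    list(rank = rk, crowding = cd)
  }
  rc <- rank_pop(objectives, feas)
  history <- data.frame(generation = 0L, best_energy = min(objectives[, 1]),
                        best_ka = min(objectives[, 2]),
                        front_size = sum(rc$rank == 1L))
  for (gen in seq_len(config$generations)) {
    select_fn <- function()
      tournament_select(rank = rc$rank,
                        crowding = if (use_crowding) rc$crowding else NULL)
    offspring <- .make_offspring(pop, select_fn, config, energy_fn,
                                 valid = feasible_fn)
    if (length(offspring)) {
      off_obj <- t(vapply(offspring, function(cf)
        c(energy_fn(cf), ka_energy(cf, ka_matrix)), c(0, 0)))
      merged <- c(pop, offspring)
      merged_obj <- rbind(objectives, off_obj)
      merged_feas <- c(feas, rep(TRUE, length(offspring)))
    } else {
      merged <- pop; merged_obj <- objectives; merged_feas <- feas
    }
    mrc <- rank_pop(merged_obj, merged_feas)
    # survival: fill by fronts; truncate the split front by crowding
    # (NSGA-II) or at random (NSGA); shuffle first so index ties are
    # rng-driven, not insertion-order artifacts
    shuffle <- sample.int(length(merged))
    key <- if (use_crowding)
      order(mrc$rank[shuffle], -mrc$crowding[shuffle])
    else
      order(mrc$rank[shuffle])
    keep <- shuffle[key][seq_len(config$pop_size)]
    pop <- merged[keep]
    objectives <- merged_obj[keep, , drop = FALSE]
    feas <- merged_feas[keep]
    rc <- rank_pop(objectives, feas)
    history <- rbind(history, data.frame(
      generation = gen, best_energy = min(objectives[, 1]),
      best_ka = min(objectives[, 2]), front_size = sum(rc$rank == 1L)))
  }
  first <- which(rc$rank == 1L & feas)
  list(front = pop[first],
       front_objectives = objectives[first, , drop = FALSE],
       population = pop, objectives = objectives, feasible = feas,
       history = history)
}

#' Fold a sequence on the FCC lattice
#'
#' Runs one of four evolutionary engines over lattice conformations of
#' `sequence`:
#' \describe{
#'   \item{`"ga-hp"`}{single-objective GA minimizing the HP contact energy}
#'   \item{`"ga-cp"`}{single-objective GA minimizing a contact-potential
#'     energy (requires `contact_matrix`)}
#'   \item{`"nsga"`, `"nsga2"`}{multi-objective search minimizing
#'     (E^HP, K^KA) jointly, with the angle feasibility constraint;
#'     survival by dominance rank (NSGA) or rank + crowding (NSGA-II)}
#' }
#' All engines use binary tournament parent selection, rotation-based
#' crossover, one improving pull move of local search per offspring,
#' K-site mutation, and elitist survival over the merged parent+offspring
#' pool.  Runs are deterministic given `seed`.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param mode One of `"ga-hp"`, `"ga-cp"`, `"nsga"`, `"nsga2"`.
#' @param config A [fold_config()]; defaults to the study conditions for
#'   `nchar(sequence)`.
#' @param contact_matrix 20 x 20 contact potential, required for
#'   `"ga-cp"`.
#' @param ka_matrix Angle preference matrix for the multi-objective modes.
#' @param seed Integer seed for the run's single RNG stream.
#' @return For single-objective modes: list with `best`, `best_energy`,
#'   `population`, `energies`, `history`.  For multi-objective modes: list
#'   with `front`, `front_objectives`, `population`, `objectives`,
#'   `feasible`, `history`.
#' @examples
#' \donttest{
#' run <- fold("CPCPCPCPCP", mode = "ga-hp",
#'             config = fold_config(10, generations = 5), seed = 1)
#' run$best_energy
#' }
#' @export
fold <- function(sequence, mode = c("ga-hp", "ga-cp", "nsga", "nsga2"),
                 config = NULL, contact_matrix = NULL,
                 ka_matrix = ka_preferences(), seed = 1L) {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  classify_hp(sequence)  # validates the alphabet
  n <- nchar(sequence)
  if (n < 2) stop("sequence must have at least 2 residues")
  if (is.null(config)) config <- fold_config(n)
  set.seed(seed)
  energy_fn <- switch(mode,
    "ga-cp" = {
      if (is.null(contact_matrix))
        stop("mode 'ga-cp' needs a contact_matrix")
      function(cf) cp_energy(cf, contact_matrix)
    },
    hp_energy)
  if (mode %in% c("ga-hp", "ga-cp"))
    c(.fold_single(sequence, config, energy_fn),
      list(mode = mode, seed = seed, config = config))
  else
    c(.fold_multi(sequence, config, energy_fn, ka_matrix,
                  use_crowding = mode == "nsga2"),
      list(mode = mode, seed = seed, config = config))
}
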