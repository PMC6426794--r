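# Elitist non-dominated sorting genetic algorithm (NSGA-II) over a
# two-variable decision box (sterilant concentration x immersion time),
# written for the surrogate objectives but generic over any
# minimization objective function. Objectives use the minimization
# convention internally; explant viability is negated before entering
# the optimizer.

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` when it is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @examples
#' dominates(c(0, -99.98), c(14.58, -68.65))  # TRUE
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into fronts F1, F2, ...: every member of a
#' front is non-dominated among the members of its own and all later
#' fronts.
#'
#' @param objectives Numeric matrix, one row per individual, one column
#'   per (minimized) objective.
#' @return A list with `ranks` (integer vector, 1 = first front) and
#'   `fronts` (list of row-index vectors).
#' @export
fast_non_dominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty population")
  # dom[i, j] = TRUE iff i dominates j (pairwise, vectorized per column)
  dom <- matrix(FALSE, n, n)
  leq <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(objectives))) {
    fk <- objectives[, k]
    cmp <- outer(fk, fk, "<=")
    leq <- leq & cmp
    lt <- lt | outer(fk, fk, "<")
  }
  dom <- leq & lt
  n_dominators <- colSums(dom)

  ranks <- integer(n)
  fronts <- list()
  remaining <- rep(TRUE, n)
  r <- 0
  while (any(remaining)) {
    r <- r + 1
    current <- which(remaining & n_dominators == 0)
    if (length(current) == 0) stop("cyclic dominance; non-finite objectives?")
    ranks[current] <- r
    fronts[[r]] <- current
    remaining[current] <- FALSE
    # removing the current front releases the individuals it dominated
    if (length(current) == 1) {
      n_dominators <- n_dominators - dom[current, ]
    } else {
      n_dominators <- n_dominators - colSums(dom[current, , drop = FALSE])
    }
  }
  list(ranks = ranks, fronts = fronts)
}

#' Crowding distance within one front
#'
#' For each objective the front is sorted; the two boundary members get
#' infinite distance and each interior member accumulates the normalized
#' gap between its neighbors, `(f[i+1] - f[i-1]) / (fmax - fmin)`.
#' Objectives with zero range contribute nothing. Fronts of one or two
#' members are entirely boundary, hence all infinite. A member whose
#' objective vector duplicates another's sits in a region of zero
#' spread: non-boundary duplicates get distance 0, so truncation drops
#' them first.
#'
#' @param objectives Numeric matrix of the front's objective rows.
#' @return Numeric vector of distances (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty front")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(objectives))) {
    fk <- objectives[, k]
    rng <- max(fk) - min(fk)
    if (rng == 0) next
    ord <- order(fk)
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    interior <- ord[2:(n - 1)]
    d[interior] <- d[interior] + (fk[ord[3:n]] - fk[ord[1:(n - 2)]]) / rng
  }
  dup <- duplicated(objectives) | duplicated(objectives, fromLast = TRUE)
  d[dup & !is.infinite(d)] <- 0
  d
}

# Crowded-comparison winner between two indices: lower rank wins, then
# larger crowding, then the first drawn.
crowded_better <- function(i, j, ranks, crowding) {
  if (ranks[i] < ranks[j]) return(i)
  if (ranks[j] < ranks[i]) return(j)
  if (crowding[i] > crowding[j]) return(i)
  if (crowding[j] > crowding[i]) return(j)
  i
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly and returns the index of the winner
#' under the crowded comparison: lower rank first, larger crowding
#' distance on ties, the first drawn on a full tie.
#'
#' @param ranks Integer vector of front ranks.
#' @param crowding Numeric vector of crowding distances.
#' @return The selected row index.
#' @export
tournament_select <- function(ranks, crowding) {
  n <- length(ranks)
  pair <- if (n >= 2) sample.int(n, 2) else c(1L, 1L)
  crowded_better(pair[1], pair[2], ranks, crowding)
}

#' Simulated binary crossover (SBX)
#'
#' Standard real-coded SBX with distribution index `eta`: with
#' probability `p_c` the pair recombines; each gene then crosses with
#' probability 0.5 using the spread factor drawn from the SBX density.
#' Children are clipped to the bounds.
#'
#' @param p1,p2 Parent decision vectors.
#' @param eta Distribution index (larger = children closer to parents).
#' @param p_c Crossover probability.
#' @param lower,upper Bound vectors.
#' @return List of two child vectors.
#' @export
sbx_crossover <- function(p1, p2, eta = 15, p_c = 0.9, lower, upper) {
  c1 <- p1
  c2 <- p2
  if (stats::runif(1) <= p_c) {
    for (g in seq_along(p1)) {
      if (stats::runif(1) <= 0.5 && abs(p1[g] - p2[g]) > 1e-14) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) {
          (2 * u)^(1 / (eta + 1))
        } else {
          (1 / (2 * (1 - u)))^(1 / (eta + 1))
        }
        c1[g] <- 0.5 * ((1 + beta) * p1[g] + (1 - beta) * p2[g])
        c2[g] <- 0.5 * ((1 - beta) * p1[g] + (1 + beta) * p2[g])
      }
    }
  }
  list(clip(c1, lower, upper), clip(c2, lower, upper))
}

#' Polynomial mutation
#'
#' Bounded polynomial mutation with distribution index `eta`: each gene
#' mutates with probability `p_m`, perturbed within its bounds.
#'
#' @param x Decision vector.
#' @param eta Distribution index.
#' @param p_m Per-gene mutation probability.
#' @param lower,upper Bound vectors.
#' @return Mutated decision vector within bounds.
#' @export
polynomial_mutation <- function(x, eta = 20, p_m = 0.5, lower, upper) {
  for (g in seq_along(x)) {
    if (stats::runif(1) <= p_m) {
      width <- upper[g] - lower[g]
      if (width <= 0) next
      u <- stats::runif(1)
      d1 <- (x[g] - lower[g]) / width
      d2 <- (upper[g] - x[g]) / width
      if (u < 0.5) {
        dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1
      } else {
        dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
      }
      x[g] <- x[g] + dq * width
    }
  }
  clip(x, lower, upper)
}

#' NSGA-II settings
#'
#' @param population_size Even integer >= 4.
#' @param generations Number of generations.
#' @param eta_c,p_c SBX distribution index and probability.
#' @param eta_m,p_m Polynomial-mutation index and per-gene probability.
#' @param seed Integer seed.
#' @return A list of class `nsga_config`.
#' @export
nsga_config <- function(population_size = 100, generations = 100,
                        eta_c = 15, p_c = 0.9, eta_m = 20, p_m = 0.5,
                        seed = 1) {
  stopifnot(population_size >= 4, population_size %% 2 == 0,
            generations >= 1)
  structure(as.list(environment()), class = "nsga_config")
}

# Linear-sweep non-dominated filter for 2 objectives (minimization):
# sort by (f1, f2) and keep rows whose f2 strictly improves the running
# minimum. Used to prune the external archive cheaply; exact duplicates
# collapse to one row, which leaves the hypervolume unchanged.
nd_filter_2d <- function(objectives) {
  ord <- order(objectives[, 1], objectives[, 2])
  sorted <- objectives[ord, , drop = FALSE]
  best2 <- Inf
  keep <- logical(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    if (sorted[i, 2] < best2) {
      keep[i] <- TRUE
      best2 <- sorted[i, 2]
    }
  }
  sorted[keep, , drop = FALSE]
}

# Exact hypervolume of a 2-objective minimization front w.r.t. a
# reference point (component-wise worse than all counted points).
hypervolume_2d <- function(objectives, ref) {
  objectives <- as.matrix(objectives)
  keep <- objectives[, 1] < ref[1] & objectives[, 2] < ref[2]
  pts <- objectives[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(0)
  sorted <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  hv <- 0
  best2 <- Inf
  f1 <- c(sorted[, 1], ref[1])
  for (i in seq_len(nrow(sorted))) {
    best2 <- min(best2, sorted[i, 2])
    hv <- hv + (f1[i + 1] - f1[i]) * (ref[2] - best2)
  }
  hv
}

#' Run the elitist NSGA-II generational loop
#'
#' Initializes a uniform population in the decision box, and each
#' generation creates offspring by binary tournament + SBX + polynomial
#' mutation, merges parents and children, sorts the merged pool into
#' non-dominated fronts and fills the next parent population
#' front-by-front, truncating the split front by descending crowding
#' distance. An external archive of all non-dominated points ever
#' evaluated is maintained; its hypervolume (against the worst point of
#' the initial generation) is recorded per generation.
#'
#' @param objective_fn Function mapping a decision matrix (one row per
#'   point) to an objective matrix of minimized values (one row per
#'   point). A plain 2-vector in / 2-vector out function is also
#'   accepted.
#' @param lower,upper Decision-box bounds (numeric vectors).
#' @param config An [nsga_config()].
#' @return An object of class `pareto_front`: list with `decisions` and
#'   `objectives` matrices of the final rank-1 front, its `crowding`
#'   distances, the `config`, and `hv_history`.
#' @export
nsga2_evolve <- function(objective_fn, lower, upper, config = nsga_config()) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  n_var <- length(lower)
  n_pop <- config$population_size
  eval_fn <- vectorize_objective(objective_fn, n_var)

  with_seed(config$seed, {
    pop <- matrix(stats::runif(n_pop * n_var), ncol = n_var)
    pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
    obj <- eval_fn(pop)
    check_objectives(obj, pop)

    ref <- apply(obj, 2, max) + 1e-9
    archive <- nd_filter_2d(obj)
    hv_history <- hypervolume_2d(archive, ref)

    srt <- fast_non_dominated_sort(obj)
    crowd <- crowding_for_population(obj, srt)

    for (gen in seq_len(config$generations)) {
      children <- matrix(0, n_pop, n_var)
      i <- 1
      while (i < n_pop) {
        a <- tournament_select(srt$ranks, crowd)
        b <- tournament_select(srt$ranks, crowd)
        kids <- sbx_crossover(pop[a, ], pop[b, ], config$eta_c, config$p_c,
                              lower, upper)
        children[i, ] <- polynomial_mutation(kids[[1]], config$eta_m,
                                             config$p_m, lower, upper)
        children[i + 1, ] <- polynomial_mutation(kids[[2]], config$eta_m,
                                                 config$p_m, lower, upper)
        i <- i + 2
      }
      child_obj <- eval_fn(children)
      check_objectives(child_obj, children)

      merged <- rbind(pop, children)
      merged_obj <- rbind(obj, child_obj)
      srt_m <- fast_non_dominated_sort(merged_obj)

      keep <- integer(0)
      for (front in srt_m$fronts) {
        if (length(keep) + length(front) <= n_pop) {
          keep <- c(keep, front)
        } else {
          room <- n_pop - length(keep)
          cd <- crowding_distance(merged_obj[front, , drop = FALSE])
          keep <- c(keep, front[order(cd, decreasing = TRUE)[seq_len(room)]])
          break
        }
      }
      pop <- merged[keep, , drop = FALSE]
      obj <- merged_obj[keep, , drop = FALSE]
      srt <- fast_non_dominated_sort(obj)
      crowd <- crowding_for_population(obj, srt)

      archive <- nd_filter_2d(rbind(archive, child_obj))
      hv_history <- c(hv_history, hypervolume_2d(archive, ref))
    }

    first <- srt$fronts[[1]]
    structure(
      list(
        decisions = pop[first, , drop = FALSE],
        objectives = obj[first, , drop = FALSE],
        crowding = crowding_distance(obj[first, , drop = FALSE]),
        config = config,
        hv_history = hv_history
      ),
      class = "pareto_front"
    )
  })
}

vectorize_objective <- function(objective_fn, n_var) {
  function(decisions) {
    out <- objective_fn(decisions)
    if (is.matrix(out) && nrow(out) == nrow(decisions)) return(out)
    # scalar-style objective: apply row-wise
    t(apply(decisions, 1, function(row) objective_fn(row)))
  }
}

check_objectives <- function(obj, decisions) {
  bad <- which(!apply(obj, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop("objective function returned non-finite values at decision (",
         paste(signif(decisions[bad[1], ], 6), collapse = ", "), ")")
  }
}

crowding_for_population <- function(obj, srt) {
  crowd <- numeric(nrow(obj))
  for (front in srt$fronts) {
    crowd[front] <- crowding_distance(obj[front, , drop = FALSE])
  }
  crowd
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("pareto_front: ", nrow(x$decisions), " rank-1 members, ",
      length(x$hv_history) - 1, " generations\n", sep = "")
  invisible(x)
}

#' Build the surrogate objective function for one experiment
#'
#' Returns the minimization objective used by the optimizer for one
#' sterilant's concentration x time box: a decision `(conc, time)` is
#' embedded into the 7-input vector (chosen sterilant at `conc`, all
#' others 0), both surrogates predict, predictions are clipped to
#' \[0, 100\], and the pair `(CF, -EV)` is returned so that minimizing
#' both components minimizes contamination and maximizes viability.
#'
#' @param cf_model,ev_model Trained `mlp_surrogate`s for contamination
#'   frequency and explant viability.
#' @param sterilant One of `sterilants()`.
#' @return A function mapping a decision matrix (columns conc, time) to
#'   an objective matrix (columns CF, -EV).
#' @export
make_objectives <- function(cf_model, ev_model, sterilant) {
  sterilant <- match.arg(sterilant, sterilants())
  col <- sterilant_column(sterilant)
  function(decisions) {
    if (is.null(dim(decisions))) decisions <- matrix(decisions, ncol = 2)
    x <- matrix(0, nrow(decisions), 7, dimnames = list(NULL, input_names()))
    x[, col] <- decisions[, 1]
    x[, "time_min"] <- decisions[, 2]
    cf <- clip(mlp_predict(cf_model, x))
    ev <- clip(mlp_predict(ev_model, x))
    cbind(cf, -ev, deparse.level = 0)
  }
}
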