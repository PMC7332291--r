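# Two-stage genetic-algorithm search: stage 1 over maximal conductances at
# the control temperature, stage 2 over Q10 temperature sensitivities.

#' Discretized search space
#'
#' Each parameter takes one of `levels` equally spaced values between its
#' bounds; candidates are integer level indices, so every evaluated candidate
#' is exactly representable on the grid.
#'
#' @param name Parameter names.
#' @param lower,upper Bounds.
#' @param levels Number of grid levels (1000 in the study protocol).
#' @param min_level Lowest admissible level index (0-based); used to keep
#'   tauCa strictly positive, where level 0 would make the calcium dynamics
#'   singular.
#' @return A `search_space` data frame.
#' @export
search_space <- function(name, lower, upper, levels = 1000L,
                         min_level = 0L) {
  sp <- data.frame(name = name, lower = lower, upper = upper,
                   levels = as.integer(levels),
                   min_level = as.integer(min_level),
                   stringsAsFactors = FALSE)
  class(sp) <- c("search_space", "data.frame")
  sp
}

#' Stage-1 search space: maximal conductances and calcium time constants
#'
#' Per cell: gNa in [0, 1000] uS, gCaT/gCaS/gA/gKd/gH in [0, 100], gKCa in
#' [0, 1000], gleak in [0, 10], tauCa in (0, 2000] ms; all 7 synaptic
#' conductances in [0, 0.05] uS. tauCa is floored one grid level above 0.
#'
#' @param levels Grid levels per parameter.
#' @return A [search_space()] with 34 parameters (27 intrinsic + 7 synaptic).
#' @export
search_space_conductances <- function(levels = 1000L) {
  ub <- c(gNa = 1000, gCaT = 100, gCaS = 100, gA = 100, gKCa = 1000,
          gKd = 100, gH = 100, gleak = 10, tauCa = 2000)
  nm <- c(paste(rep(.cells, each = 9), rep(names(ub), 3), sep = "."),
          paste0("gsyn.", .syn_names))
  search_space(nm,
               lower = rep(0, 34),
               upper = c(rep(unname(ub), 3), rep(0.05, 7)),
               levels = levels,
               min_level = c(rep(c(rep(0L, 8), 1L), 3), rep(0L, 7)))
}

#' Stage-2 search space: Q10 temperature sensitivities
#'
#' Conductance Q10s in [1, 2]; timescale Q10s (gating, calcium, synaptic) in
#' [1, 4].
#'
#' @param levels Grid levels per parameter.
#' @return A [search_space()] with 24 parameters.
#' @export
search_space_q10 <- function(levels = 1000L) {
  is_g <- .q10_names %in% c(paste0("g", .channels), "gsyn.glut", "gsyn.chol")
  search_space(paste0("q10.", .q10_names),
               lower = rep(1, 24),
               upper = ifelse(is_g, 2, 4),
               levels = levels)
}

#' Decode grid levels to parameter values
#'
#' @param space A [search_space()].
#' @param idx Integer level indices (0-based), one per parameter.
#' @return Named numeric parameter values.
#' @export
decode_levels <- function(space, idx) {
  setNames(space$lower + idx * (space$upper - space$lower) /
             (space$levels - 1), space$name)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study protocol where stated (random initial
#' population on the grid) and standard practice where not: tournament
#' selection of size 3, uniform crossover at rate 0.5, per-gene mutation at
#' rate 1/genes (half uniform resets, half small local steps), elitism of 2,
#' and early stopping once the best score stays below `stop_score` for
#' `patience` generations.
#'
#' @param population Population size.
#' @param generations Maximum generations.
#' @param seed Random seed (mandatory; the search is fully reproducible).
#' @param p_crossover Per-gene probability of taking the second parent's
#'   gene.
#' @param p_mutation Per-gene mutation probability (`NULL` = 1/genes).
#' @param tournament Tournament size.
#' @param elite Number of elites copied unchanged.
#' @param stop_score,patience Early-stopping rule.
#' @param immigrants Fraction of each generation replaced by fresh random
#'   candidates (guards against premature convergence; elites are never
#'   replaced).
#' @param p_block Per-child probability of the block-copy operator when the
#'   search space declares exchangeable blocks (see [ga_minimize()]).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 1000L, generations = 10000L, seed,
                      p_crossover = 0.5, p_mutation = NULL, tournament = 3L,
                      elite = 2L, stop_score = 0.1, patience = 50L,
                      immigrants = 0.05, p_block = 0.1) {
  if (missing(seed)) stop("a random seed is mandatory")
  if (population < 2) stop("population must be at least 2")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 seed = as.integer(seed), p_crossover = p_crossover,
                 p_mutation = p_mutation, tournament = as.integer(tournament),
                 elite = as.integer(elite), stop_score = stop_score,
                 patience = as.integer(patience),
                 immigrants = immigrants, p_block = p_block),
            class = "ga_config")
}

#' Minimize an objective over a discretized space with a genetic algorithm
#'
#' Candidates are vectors of integer grid levels. The objective receives the
#' decoded parameter values and returns a score; errors and non-finite
#' returns are converted to a sentinel score and never abort the search.
#' Elitism makes the best-so-far score non-increasing across generations;
#' with a fixed seed the whole run is reproducible.
#'
#' @param objective `function(values) -> score`.
#' @param space A [search_space()].
#' @param config A [ga_config()].
#' @param blocks Optional list of equal-length index vectors marking
#'   exchangeable parameter blocks (e.g. the three cells' intrinsic
#'   parameters): with probability `p_block` a child copies one random
#'   block over another, which lets a working sub-solution propagate across
#'   blocks instead of being rediscovered.
#' @param init Optional integer matrix of level vectors (rows) seeded into
#'   the initial population ahead of the random draws; lets a search start
#'   from structured candidates while the rest of the population remains
#'   random.
#' @param verbose Print per-generation progress.
#' @return List with `best_values`, `best_levels`, `best_score`, the final
#'   ranked `population` (levels matrix) and `scores`, and the per-generation
#'   `log` (best/mean score).
#' @export
ga_minimize <- function(objective, space, config, blocks = NULL,
                        init = NULL, verbose = FALSE) {
  set.seed(config$seed)
  n_genes <- nrow(space)
  p_mut <- if (is.null(config$p_mutation)) 1 / n_genes else config$p_mutation
  n_imm <- floor(max(config$immigrants, 0) * config$population)
  rand_gene <- function(k, n) {
    # uniform level in [min_level, levels-1]
    space$min_level[k] +
      floor(runif(n) * (space$levels[k] - space$min_level[k]))
  }
  pop <- vapply(seq_len(n_genes), function(k) rand_gene(k, config$population),
                numeric(config$population))
  if (!is.null(init)) {
    k <- min(nrow(init), config$population)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  eval_pop <- function(p) {
    apply(p, 1, function(lv) {
      sc <- tryCatch(objective(decode_levels(space, lv)),
                     error = function(e) NA_real_)
      # failures never abort the search; they score just above the worst
      # structured failure so anything informative outranks them
      if (!is.finite(sc)) .SENTINEL + 10 else sc
    })
  }
  scores <- eval_pop(pop)
  ord <- order(scores)
  pop <- pop[ord, , drop = FALSE]
  scores <- scores[ord]
  log <- data.frame(generation = 0L, best = scores[1], mean = mean(scores))
  below <- 0L
  for (gen in seq_len(config$generations)) {
    n <- config$population
    newpop <- matrix(0, n, n_genes)
    ne <- min(config$elite, n)
    newpop[seq_len(ne), ] <- pop[seq_len(ne), , drop = FALSE]
    for (i in (ne + 1):n) {
      pick <- function() {
        cand <- sample.int(n, config$tournament)
        cand[which.min(scores[cand])]
      }
      pa <- pop[pick(), ]
      pb <- pop[pick(), ]
      child <- ifelse(runif(n_genes) < config$p_crossover, pb, pa)
      mut <- runif(n_genes) < p_mut
      if (any(mut)) {
        w <- which(mut)
        # half the mutations reset the gene to a uniform grid level, half
        # take a small signed step (fine convergence near an optimum)
        child[w] <- vapply(w, function(k) {
          if (runif(1) < 0.5) rand_gene(k, 1)
          else {
            step <- sample(c(-1, 1), 1) * sample.int(5, 1)
            min(max(child[k] + step, space$min_level[k]),
                space$levels[k] - 1)
          }
        }, numeric(1))
      }
      if (!is.null(blocks) && runif(1) < config$p_block) {
        ab <- sample(length(blocks), 2)
        child[blocks[[ab[2]]]] <- child[blocks[[ab[1]]]]
      }
      newpop[i, ] <- child
    }
    if (n_imm > 0) {
      for (i in (n - n_imm + 1):n)
        newpop[i, ] <- vapply(seq_len(n_genes),
                              function(k) rand_gene(k, 1), numeric(1))
    }
    new_scores <- scores
    new_scores[seq_len(ne)] <- scores[seq_len(ne)]
    new_scores[(ne + 1):n] <- eval_pop(newpop[(ne + 1):n, , drop = FALSE])
    ord <- order(new_scores)
    pop <- newpop[ord, , drop = FALSE]
    scores <- new_scores[ord]
    log <- rbind(log, data.frame(generation = gen, best = scores[1],
                                 mean = mean(scores)))
    if (verbose)
      message(sprintf("[%s] gen %d: best %.10g mean %.8g",
                      format(Sys.time(), "%H:%M:%S"), gen, scores[1],
                      mean(scores)))
    below <- if (scores[1] < config$stop_score) below + 1L else 0L
    if (below >= config$patience) break
  }
  list(best_values = decode_levels(space, pop[1, ]),
       best_levels = pop[1, ], best_score = scores[1],
       population = pop, scores = scores, log = log)
}

# assemble a model from decoded stage-1 values
.model_from_values <- function(values, q10 = q10_set(), name = NULL) {
  cell <- function(cl) {
    v <- values[paste(cl, .cell_par_names, sep = ".")]
    setNames(as.numeric(v), .cell_par_names)
  }
  pyloric_model(PD = cell("PD"), LP = cell("LP"), PY = cell("PY"),
                gsyn = setNames(as.numeric(
                  values[paste0("gsyn.", .syn_names)]), .syn_names),
                q10 = q10, name = name)
}

.q10_from_values <- function(values) {
  q <- setNames(as.numeric(values), .q10_names)
  structure(q, class = "q10_set")
}

#' Stage 1: search conductances for a control triphasic rhythm
#'
#' Minimizes the control objective at 10 degC over the 34-parameter
#' conductance space and returns the candidates from the final population
#' that are classified triphasic and pass the stability filter. The GA may
#' rank candidates with a shortened recording protocol for speed; accepted
#' candidates are always re-validated with the full 20 s / 10 s protocol
#' and exact kinetics.
#'
#' @param targets A [target_spec()].
#' @param config A [ga_config()].
#' @param space Search space (default [search_space_conductances()]).
#' @param duration,discard,dt Evaluation protocol during the search
#'   (s, s, ms).
#' @param stride Record stride during the search.
#' @param fast Use tabulated kinetics during the search.
#' @param max_accepted Stop validating candidates after this many accepted.
#' @param verbose Print per-generation GA progress.
#' @return List with `models` (accepted [pyloric_model()]s, best first),
#'   `best_model`, the GA `result`, and `diagnostics` when nothing was found.
#' @export
stage1_find_conductances <- function(targets = target_spec(), config,
                                     space = search_space_conductances(),
                                     duration = 20, discard = 10, dt = 0.05,
                                     stride = 1, fast = TRUE,
                                     max_accepted = 5L, verbose = FALSE) {
  obj <- function(values) {
    m <- .model_from_values(values)
    control_objective(m, targets, temperature = 10, duration = duration,
                      discard = discard, dt = dt, stride = stride,
                      fast = fast)$score
  }
  # the three cells' intrinsic parameter blocks are exchangeable: a cell
  # that bursts can seed the others through the block-copy operator
  blocks <- lapply(0:2, function(c) c * 9 + 1:9)
  res <- ga_minimize(obj, space, config, blocks = blocks, verbose = verbose)
  models <- list()
  for (i in seq_len(nrow(res$population))) {
    if (length(models) >= max_accepted || res$scores[i] >= .SENTINEL) break
    m <- .model_from_values(decode_levels(space, res$population[i, ]))
    tr <- simulate(m, duration = 20, discard = 10, dt = dt,
                   temperature = 10)
    if (is.na(tr$blow_time)) {
      bs <- burst_summary(tr)
      ok <- all(vapply(.cells, function(cl) bs[[cl]]$stable, logical(1))) &&
        classify_network(bs) == "triphasic"
      if (ok) models[[length(models) + 1]] <- m
    }
  }
  list(models = models,
       best_model = if (length(models)) models[[1]] else NULL,
       result = res,
       diagnostics = if (!length(models))
         list(best_score = res$best_score,
              message = "no triphasic candidate in the final population"))
}

#' Stage 2: search Q10 values for temperature robustness
#'
#' Holds the stage-1 conductances fixed and minimizes the thermal objective
#' (scores at 15/20/25 degC plus the 35 degC spike count) over the 24 Q10
#' values, then screens intermediate temperatures with the triphasic
#' classifier.
#'
#' @param model Stage-1 [pyloric_model()].
#' @param targets A [target_spec()].
#' @param config A [ga_config()].
#' @param space Search space (default [search_space_q10()]).
#' @param duration,discard,dt Evaluation protocol during the search.
#' @param stride Record stride during the search.
#' @param fast Use tabulated kinetics during the search.
#' @param screen_temps Grid for the intermediate-temperature screen (run at
#'   the full protocol with exact kinetics).
#' @param max_accepted Cap on validated Q10 sets.
#' @param verbose Print per-generation GA progress.
#' @return List with `models` (accepted, screened models), `best_model`, the
#'   GA `result`, and `diagnostics`.
#' @export
stage2_find_q10 <- function(model, targets = target_spec(), config,
                            space = search_space_q10(),
                            duration = 20, discard = 10, dt = 0.05,
                            stride = 1, fast = TRUE,
                            screen_temps = seq(10, 25, length.out = 16),
                            max_accepted = 3L, verbose = FALSE) {
  obj <- function(values) {
    m <- model
    m$q10 <- .q10_from_values(values)
    thermal_objective(m, targets, duration = duration, discard = discard,
                      dt = dt, stride = stride, fast = fast)$score
  }
  # seed part of the initial population with class-uniform Q10 sets (one
  # value for all conductances, one for all timescales): coordinated
  # sensitivities are the physically coherent starting points for
  # compensation, and the random remainder keeps the search unbiased
  is_g <- space$upper <= 2 + 1e-9
  lvl <- function(val, k) round((val - space$lower[k]) /
                                  (space$upper[k] - space$lower[k]) *
                                  (space$levels[k] - 1))
  combos <- expand.grid(qg = seq(1, 2, length.out = 4),
                        qt = seq(1, 4, length.out = 6))
  init <- t(apply(combos, 1, function(cv) {
    vapply(seq_len(nrow(space)), function(k)
      lvl(if (is_g[k]) cv[["qg"]] else cv[["qt"]], k), numeric(1))
  }))
  res <- ga_minimize(obj, space, config, init = init, verbose = verbose)
  models <- list()
  for (i in seq_len(nrow(res$population))) {
    if (length(models) >= max_accepted || res$scores[i] >= .SENTINEL) break
    m <- model
    m$q10 <- .q10_from_values(decode_levels(space, res$population[i, ]))
    scr <- screen_intermediate_temperatures(m, screen_temps,
                                            duration = 20, discard = 10,
                                            dt = dt)
    if (scr$pass) models[[length(models) + 1]] <- m
  }
  list(models = models,
       best_model = if (length(models)) models[[1]] else NULL,
       result = res,
       diagnostics = if (!length(models))
         list(best_score = res$best_score,
              message = "no screened temperature-robust Q10 set found"))
}
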