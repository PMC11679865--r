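#' Hyperparameter search space
#'
#' @param dims data.frame with columns `name`, `lower`, `upper`, `kind`
#'   (`"integer"` or `"continuous"`). Integer dimensions are searched in
#'   continuous space and rounded only when a position is decoded.
#' @return a `search_space`.
#' @export
search_space <- function(dims) {
  stopifnot(is.data.frame(dims),
            all(c("name", "lower", "upper", "kind") %in% names(dims)),
            all(dims$lower < dims$upper),
            all(dims$kind %in% c("integer", "continuous")))
  structure(dims, class = c("search_space", "data.frame"))
}

#' The default five-dimensional space
#'
#' LSTM units (layers 1 and 2) 1-200, dense units 1-200, dropout rate
#' 0.1-0.9, batch size 1-128.
#'
#' @param units_max optional cap on the three unit dimensions (handy for
#'   reduced desk-scale searches; default 200).
#' @param batch_max cap on the batch-size dimension (default 128).
#' @return a [search_space()].
#' @export
default_search_space <- function(units_max = 200, batch_max = 128) {
  search_space(data.frame(
    name = c("units1", "units2", "dense_units", "dropout", "batch_size"),
    lower = c(1, 1, 1, 0.1, 1),
    upper = c(units_max, units_max, units_max, 0.9, batch_max),
    kind = c("integer", "integer", "integer", "continuous", "integer"),
    stringsAsFactors = FALSE))
}

#' Particle swarm settings
#'
#' Defaults are the protocol settings: inertia 0.2, cognitive weight 0.3, social
#' weight 0.5, 15 particles, 10 iterations.
#'
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration weights.
#' @param particles swarm size.
#' @param iterations number of swarm iterations (the first iteration
#'   evaluates the random initial positions).
#' @param seed integer seed for initialization and the per-update uniform
#'   draws.
#' @return a `pso_config`.
#' @export
pso_config <- function(w = 0.2, c1 = 0.3, c2 = 0.5, particles = 15L,
                       iterations = 10L, seed = 1L) {
  stopifnot(w >= 0, c1 >= 0, c2 >= 0, particles >= 1, iterations >= 1)
  structure(list(w = w, c1 = c1, c2 = c2, particles = as.integer(particles),
                 iterations = as.integer(iterations), seed = check_seed(seed)),
            class = "pso_config")
}

#' Velocity update
#'
#' `v' = w v + c1 r1 (p - x) + c2 r2 (g - x)` with `r1`, `r2` fresh
#' uniform(0,1) draws per dimension, then clipped to plus/minus the dimension
#' range.
#'
#' @param velocity,position,personal_best,global_best numeric vectors of
#'   equal length.
#' @param config a [pso_config()].
#' @param space the [search_space()] (for the clipping range).
#' @param r1,r2 optional fixed draws (vectors in \[0,1\]); by default drawn
#'   from R's RNG.
#' @return the new velocity vector.
#' @export
update_velocity <- function(velocity, position, personal_best, global_best,
                            config, space, r1 = NULL, r2 = NULL) {
  d <- length(velocity)
  r1 <- r1 %||% runif(d)
  r2 <- r2 %||% runif(d)
  v <- config$w * velocity +
    config$c1 * r1 * (personal_best - position) +
    config$c2 * r2 * (global_best - position)
  vmax <- space$upper - space$lower
  pmin(pmax(v, -vmax), vmax)
}

#' Position update
#'
#' `x' = x + v'`, clamped to the space bounds per dimension.
#'
#' @param position current position.
#' @param velocity updated velocity.
#' @param space the [search_space()].
#' @return the new position vector.
#' @export
update_position <- function(position, velocity, space) {
  pmin(pmax(position + velocity, space$lower), space$upper)
}

#' Decode a raw position into hyperparameters
#'
#' Integer dimensions are rounded to the nearest integer and then clamped to
#' their bounds; continuous dimensions are clamped only.
#'
#' @param position numeric position vector.
#' @param space the [search_space()].
#' @return named list of decoded values.
#' @export
decode_position <- function(position, space) {
  out <- as.list(position)
  names(out) <- space$name
  for (k in seq_len(nrow(space))) {
    x <- if (space$kind[k] == "integer") round(position[k]) else position[k]
    x <- min(max(x, space$lower[k]), space$upper[k])
    out[[k]] <- if (space$kind[k] == "integer") as.integer(x) else x
  }
  out
}

#' Particle swarm minimization
#'
#' Synchronous PSO: positions are initialized uniformly at random within the
#' bounds and velocities within plus/minus 10% of each range; every iteration
#' evaluates all particles, then updates personal bests and (once) the global
#' best, so the global-best trace is non-increasing by construction. A
#' non-finite fitness value is recorded as `+Inf` and leaves the particle's
#' personal best untouched.
#'
#' @param fitness function mapping a raw position vector to a scalar loss.
#'   When `decode = TRUE` the decoded named list is passed instead.
#' @param space a [search_space()].
#' @param config a [pso_config()].
#' @param decode pass decoded hyperparameters to `fitness` (default `FALSE`:
#'   raw positions).
#' @param cache memoize fitness on the decoded (integer-rounded) position so
#'   identical configurations are trained once (default `TRUE` when
#'   `decode = TRUE`).
#' @return list with `best_position`, `best_decoded`, `best_loss`, `trace`
#'   (global best loss after each iteration, non-increasing), and `log`
#'   (data.frame: iteration, particle, decoded dimensions, loss, cached).
#' @export
pso_optimize <- function(fitness, space, config, decode = FALSE,
                         cache = decode) {
  d <- nrow(space)
  with_seed(config$seed, {
    pos <- sapply(seq_len(d), function(k)
      runif(config$particles, space$lower[k], space$upper[k]))
    pos <- matrix(pos, config$particles, d)
    vel <- sapply(seq_len(d), function(k) {
      r <- space$upper[k] - space$lower[k]
      runif(config$particles, -0.1 * r, 0.1 * r)
    })
    vel <- matrix(vel, config$particles, d)

    pbest <- pos
    pbest_f <- rep(Inf, config$particles)
    gbest <- pos[1L, ]
    gbest_f <- Inf
    trace <- numeric(config$iterations)
    memo <- new.env(parent = emptyenv())
    n_log <- config$particles * config$iterations
    log_iter <- integer(n_log); log_part <- integer(n_log)
    log_loss <- numeric(n_log); log_cached <- logical(n_log)
    log_dec <- matrix(NA_real_, n_log, d,
                      dimnames = list(NULL, space$name))
    row <- 0L

    eval_at <- function(x) {
      dec <- decode_position(x, space)
      key <- paste(vapply(dec, format, "", digits = 17), collapse = "|")
      if (cache && !is.null(memo[[key]])) {
        return(list(loss = memo[[key]], decoded = dec, cached = TRUE))
      }
      f <- tryCatch(as.numeric(if (decode) fitness(dec) else fitness(x)),
                    error = function(e) Inf)
      if (!length(f) || !is.finite(f)) f <- Inf
      if (cache) memo[[key]] <- f
      list(loss = f, decoded = dec, cached = FALSE)
    }

    for (it in seq_len(config$iterations)) {
      if (it > 1L) {
        for (i in seq_len(config$particles)) {
          vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                      config, space)
          pos[i, ] <- update_position(pos[i, ], vel[i, ], space)
        }
      }
      for (i in seq_len(config$particles)) {
        ev <- eval_at(pos[i, ])
        row <- row + 1L
        log_iter[row] <- it; log_part[row] <- i
        log_loss[row] <- ev$loss; log_cached[row] <- ev$cached
        log_dec[row, ] <- unlist(ev$decoded)
        if (ev$loss < pbest_f[i]) {
          pbest_f[i] <- ev$loss
          pbest[i, ] <- pos[i, ]
        }
      }
      if (it == 1L && all(!is.finite(pbest_f))) {
        stop("all fitness evaluations were non-finite in the first iteration",
             call. = FALSE)
      }
      # synchronous global-best update, once per iteration
      b <- which.min(pbest_f)
      if (pbest_f[b] < gbest_f) {
        gbest_f <- pbest_f[b]
        gbest <- pbest[b, ]
      }
      trace[it] <- gbest_f
    }
    list(best_position = gbest,
         best_decoded = decode_position(gbest, space),
         best_loss = gbest_f,
         trace = trace,
         log = data.frame(iteration = log_iter, particle = log_part,
                          log_dec, loss = log_loss, cached = log_cached))
  })
}
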