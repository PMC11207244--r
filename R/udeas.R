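# uDEAS: univariate dynamic encoding algorithm for searches.
#
# Each variable is encoded as a binary row (an integer value plus a bit
# length); a local search runs sessions in which every variable gets one
# bisectional search (BSS: append a bit, keep the better child) followed by
# a unidirectional search (UDS: step the integer value in the direction the
# BSS winner indicates while the cost strictly decreases).  The global
# scheme restarts the local search from random binary matrices and keeps
# the best local minimum.  A cost-sensitivity score computed during each
# session can reorder the variables for the next session.

#' Decode a binary row to a real value
#'
#' A row of `n` bits with integer value `k` decodes to the midpoint of the
#' `k`-th of `2^n` equal subdivisions of `[lo, hi]`:
#' `lo + (hi - lo) * (k + 0.5) / 2^n`.  Every decoded value is strictly
#' inside the bounds, and at fixed length the map is strictly increasing
#' in `k`.
#'
#' @param row binary row: a character string of 0/1 (e.g. `"10"`), or an
#'   integer vector of bits.
#' @param lo,hi decoding bounds, `lo < hi`.
#' @return decoded real value.
#' @examples
#' decode_row("1", 0, 1)   # 0.75
#' decode_row("10", 0, 1)  # 0.625
#' @export
decode_row <- function(row, lo, hi) {
  if (is.character(row)) {
    stopifnot(length(row) == 1L)
    bits <- strsplit(row, "")[[1]]
    if (length(bits) == 0L || !all(bits %in% c("0", "1"))) {
      stop_pa("binary row must be a non-empty string of 0s and 1s")
    }
    bits <- as.integer(bits)
  } else {
    bits <- as.integer(row)
    if (length(bits) == 0L || !all(bits %in% c(0L, 1L))) {
      stop_pa("binary row must be non-empty 0/1 bits")
    }
  }
  if (!(lo < hi)) stop_pa("decode bounds must satisfy lo < hi")
  val <- sum(bits * 2^(rev(seq_along(bits)) - 1))
  decode_int(val, length(bits), lo, hi)
}

# integer-value form used internally
decode_int <- function(val, len, lo, hi) {
  lo + (hi - lo) * (val + 0.5) / 2^len
}

#' uDEAS optimizer settings
#'
#' @param init_bits starting bit length of every variable's binary row.
#' @param max_bits maximum bit length; the attainable values at depth `d`
#'   form a uniform grid of spacing `(hi - lo) / 2^d`.
#' @param restarts number of independent local searches from random
#'   initial binary matrices.
#' @param ordering `"sensitivity"` reorders variables between sessions by
#'   descending cost sensitivity (the first session is sequential);
#'   `"sequential"` always visits variables in index order.
#' @param seed integer seed making the whole run reproducible; `NULL`
#'   draws from the session RNG.
#' @param uds_max_steps cap on accepted UDS steps per variable per session
#'   (default: no cap beyond the range clamp).
#' @param refine_at_max_depth once a variable's row has reached `max_bits`,
#'   keep giving it unidirectional refinement passes on the finest grid
#'   (the step direction chosen by probing both neighbours) until a full
#'   session no longer improves; with `FALSE` fully-deepened variables are
#'   skipped and the search ends when every row is at `max_bits`.
#' @return a list of class `udeas_config`.
#' @export
udeas_config <- function(init_bits = 3, max_bits = 12, restarts = 5,
                         ordering = c("sensitivity", "sequential"),
                         seed = NULL, uds_max_steps = Inf,
                         refine_at_max_depth = TRUE) {
  ordering <- match.arg(ordering)
  stopifnot(init_bits >= 1, max_bits >= init_bits, restarts >= 1)
  structure(
    list(init_bits = as.integer(init_bits), max_bits = as.integer(max_bits),
         restarts = as.integer(restarts), ordering = ordering,
         seed = seed, uds_max_steps = uds_max_steps,
         refine_at_max_depth = isTRUE(refine_at_max_depth)),
    class = "udeas_config"
  )
}

#' Cost sensitivity of one variable over a session
#'
#' Averages the absolute cost slopes observed for a variable during its
#' bisectional search (the two children) and its `M` accepted
#' unidirectional steps:
#' `S = (|dL/dv|_BSS + sum_k |dL/dv|_UDS,k) / (M + 1)`.
#' With `M = 0` this is the BSS slope alone.  Sensitivities rank variables
#' for the next session's visiting order.
#'
#' @param bss_costs numeric length 2: costs at the left ("0") and right
#'   ("1") BSS children.
#' @param bss_values numeric length 2: decoded values of the two children.
#' @param uds_values decoded values of the UDS sequence, starting at the
#'   winning child; length `M + 1` (length 1 or 0 when no step succeeded).
#' @param uds_costs costs of the same sequence.
#' @return non-negative sensitivity score.
#' @examples
#' udeas_sensitivity(c(4, 1), c(0.25, 0.75))  # (3 / 0.5) / 1 = 6
#' @export
udeas_sensitivity <- function(bss_costs, bss_values,
                              uds_values = numeric(), uds_costs = numeric()) {
  stopifnot(length(bss_costs) == 2, length(bss_values) == 2,
            length(uds_values) == length(uds_costs))
  slope <- function(dl, dv) if (dv == 0) 0 else abs(dl) / abs(dv)
  s <- slope(bss_costs[1] - bss_costs[2], bss_values[1] - bss_values[2])
  m <- max(length(uds_values) - 1L, 0L)
  if (m > 0) {
    for (k in seq_len(m)) {
      s <- s + slope(uds_costs[k] - uds_costs[k + 1],
                     uds_values[k] - uds_values[k + 1])
    }
  }
  s / (m + 1)
}

# one BSS + UDS pass for variable i of the search state.
# state: list(val, len, x (decoded vector), cost, evals)
# returns updated state plus sensitivity and M for this variable.
udeas_step_var <- function(state, i, cost_fn, lo, hi, max_bits,
                           uds_max_steps = Inf, refine = TRUE) {
  at_depth <- state$len[i] >= max_bits
  if (at_depth && !refine) {
    return(list(state = state, sens = NA_real_, m = 0L, skipped = TRUE))
  }
  x <- state$x
  if (at_depth) {
    # depth exhausted: probe the two grid neighbours at the current
    # length instead of appending a bit, so refinement sessions can
    # keep walking the finest grid until no coordinate move improves
    len <- state$len[i]
    vmax0 <- 2^len - 1
    v0 <- max(state$val[i] - 1, 0)
    v1 <- min(state$val[i] + 1, vmax0)
  } else {
    len <- state$len[i] + 1L
    v0 <- state$val[i] * 2      # "0" child
    v1 <- v0 + 1                # "1" child
  }
  eval_at <- function(vi) {
    x[i] <- decode_int(vi, len, lo[i], hi[i])
    cost_fn(x)
  }
  c0 <- eval_at(v0)
  c1 <- eval_at(v1)
  state$evals <- state$evals + 2L
  # tie keeps the "0" (lower-half) child for determinism
  if (c1 < c0) {
    win_val <- v1; win_cost <- c1; dir <- +1
  } else {
    win_val <- v0; win_cost <- c0; dir <- -1
  }
  if (at_depth && win_cost >= state$cost) {
    # neither neighbour improves on the current point: keep it
    win_val <- state$val[i]
    win_cost <- state$cost
  }
  bss_costs <- c(c0, c1)
  bss_values <- c(decode_int(v0, len, lo[i], hi[i]),
                  decode_int(v1, len, lo[i], hi[i]))

  # unidirectional search at the new fixed length
  vmax <- 2^len - 1
  uds_values <- decode_int(win_val, len, lo[i], hi[i])
  uds_costs <- win_cost
  cur_val <- win_val
  cur_cost <- win_cost
  steps <- 0L
  while (steps < min(uds_max_steps, vmax)) {
    nxt <- cur_val + dir
    if (nxt < 0 || nxt > vmax) break
    nc <- eval_at(nxt)
    state$evals <- state$evals + 1L
    if (nc < cur_cost) {
      cur_val <- nxt
      cur_cost <- nc
      steps <- steps + 1L
      uds_values <- c(uds_values, decode_int(nxt, len, lo[i], hi[i]))
      uds_costs <- c(uds_costs, nc)
    } else break
  }

  state$val[i] <- cur_val
  state$len[i] <- len
  state$x[i] <- decode_int(cur_val, len, lo[i], hi[i])
  # cur_cost is the cost of the full vector with variable i updated,
  # since all other components were held fixed during this pass
  state$cost <- cur_cost
  if (cur_cost < state$best_cost) {
    state$best_cost <- cur_cost
    state$best_x <- state$x
  }
  sens <- udeas_sensitivity(bss_costs, bss_values, uds_values, uds_costs)
  list(state = state, sens = sens, m = steps, skipped = FALSE)
}

# one complete session: BSS + UDS for each variable in `order`
udeas_session <- function(state, order, cost_fn, lo, hi, config) {
  sens <- state$sens
  m_counts <- integer(length(state$val))
  for (i in order) {
    res <- udeas_step_var(state, i, cost_fn, lo, hi,
                          config$max_bits, config$uds_max_steps,
                          refine = config$refine_at_max_depth)
    state <- res$state
    if (!res$skipped) {
      sens[i] <- res$sens
      m_counts[i] <- res$m
    }
  }
  state$sens <- sens
  state$m_counts <- m_counts
  state
}

# one local search from a given initial binary matrix
udeas_local_search <- function(cost_fn, lo, hi, config, init_val, init_len) {
  n <- length(lo)
  x0 <- decode_int(init_val, init_len, lo, hi)
  c0 <- cost_fn(x0)
  state <- list(val = init_val, len = init_len, x = x0, cost = c0,
                best_cost = c0, best_x = x0, sens = rep(NA_real_, n),
                evals = 1L)
  order <- seq_len(n)
  trace <- list()
  session <- 0L
  repeat {
    session <- session + 1L
    before <- state$best_cost
    state <- udeas_session(state, order, cost_fn, lo, hi, config)
    trace[[session]] <- tibble::tibble(
      session = session, best_cost = state$best_cost,
      order = paste(order, collapse = ">"), evals = state$evals
    )
    all_deep <- all(state$len >= config$max_bits)
    improved <- state$best_cost < before
    if (all_deep && !improved) break
    if (config$ordering == "sensitivity") {
      s <- ifelse(is.na(state$sens), -Inf, state$sens)
      order <- order(s, decreasing = TRUE)
    }
  }
  list(best_x = state$best_x, best_cost = state$best_cost,
       evals = state$evals, sessions = session,
       trace = dplyr::bind_rows(trace), final = state)
}

#' Global optimisation with uDEAS
#'
#' Runs `restarts` independent local searches (each a sequence of BSS/UDS
#' sessions on binary-encoded variables) from random initial matrices and
#' returns the best local minimum found.  Deterministic given `seed`.
#'
#' @param cost_fn function taking a numeric vector (one value per variable)
#'   and returning a scalar cost; must be defined on the whole bounding box.
#' @param lo,hi numeric vectors of finite per-variable bounds.
#' @param config a [udeas_config()].
#' @param warm_start optional numeric vector or list of vectors; each adds
#'   one extra restart initialised at its binary encoding (at `init_bits`
#'   resolution).
#' @return list of class `udeas_fit`: `par` (best decoded vector), `cost`,
#'   `evals`, and `history`, a tibble with one row per session per restart.
#' @examples
#' fit <- udeas_optimize(function(x) (x[1] - 0.3)^2, 0, 1,
#'                       udeas_config(max_bits = 10, restarts = 2, seed = 1))
#' abs(fit$par - 0.3) <= 2^-10
#' @export
udeas_optimize <- function(cost_fn, lo, hi, config = udeas_config(),
                           warm_start = NULL) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == length(hi), all(is.finite(lo)), all(is.finite(hi)),
            all(lo < hi))
  n <- length(lo)
  runs <- local_seed(config$seed, {
    inits <- lapply(seq_len(config$restarts), function(r) {
      list(val = floor(runif(n) * 2^config$init_bits),
           len = rep(config$init_bits, n))
    })
    if (!is.null(warm_start)) {
      if (!is.list(warm_start)) warm_start <- list(warm_start)
      for (ws in warm_start) {
        stopifnot(length(ws) == n)
        # encoded a few bits deeper than random starts: close enough to
        # stay in the warm start's basin, coarse enough that BSS/UDS can
        # still refine without long fixed-grid walks
        wbits <- min(config$init_bits + 3L, config$max_bits)
        wv <- pmin(pmax(round((ws - lo) / (hi - lo) * 2^wbits - 0.5), 0),
                   2^wbits - 1)
        inits <- c(inits, list(list(val = wv, len = rep(wbits, n))))
      }
    }
    lapply(inits, function(ini) {
      udeas_local_search(cost_fn, lo, hi, config, ini$val, ini$len)
    })
  })
  costs <- vapply(runs, `[[`, numeric(1), "best_cost")
  best <- which.min(costs)
  history <- dplyr::bind_rows(
    lapply(seq_along(runs), function(r) {
      dplyr::mutate(runs[[r]]$trace, restart = r, .before = 1)
    })
  )
  structure(
    list(par = runs[[best]]$best_x, cost = costs[best],
         evals = sum(vapply(runs, `[[`, integer(1), "evals")),
         restart = best, history = history, config = config),
    class = "udeas_fit"
  )
}

#' @export
print.udeas_fit <- function(x, ...) {
  cat("<udeas_fit>\n")
  cat(sprintf("  best cost %.6g after %d evaluations (%d restarts)\n",
              x$cost, x$evals, max(x$history$restart)))
  invisible(x)
}
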