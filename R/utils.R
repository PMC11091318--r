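# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps library calls free of global RNG
# side effects.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(as.numeric(seed) %% 2147483647))
  }
  expr
}

# Linear interpolation on a trajectory column at time tq (grid includes event
# times, so this is exact at t_pp and accurate to O(dt^2) elsewhere).
interp_col <- function(traj, col, tq) {
  stats::approx(traj$t, traj[[col]], xout = tq, rule = 2, ties = "ordered")$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
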