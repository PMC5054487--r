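# Independent oracles used by the tests.  They work in enzyme space and rely
# only on one-dimensional root finding, deliberately sharing no code with the
# package's concentration-space optimizer.

# Steady state (X, P) of one isolated two-reaction cell with given enzymes,
# all kinetic constants 1, substrate S, uncompetitive inhibition inv_K_I.
# Solved by nested uniroot: for each P, X balances synthesis against
# conversion; P then balances conversion against consumption.
single_cell_steady <- function(E, S = 10, inv_K_I = 0) {
  fS <- function(X, P) (S - X) / (1 + S + X) / (1 + inv_K_I * P)
  fX <- function(X, P) (X - P) / (1 + X + P)
  g <- function(P) P / (1 + P)
  X_of_P <- function(P) {
    h <- function(X) E[1] * fS(X, P) - E[2] * fX(X, P)
    lo <- P + 1e-12
    if (lo >= S || h(lo) <= 0) return(NA_real_)
    stats::uniroot(h, c(lo, S - 1e-12), tol = 1e-12)$root
  }
  r <- function(P) {
    X <- X_of_P(P)
    if (is.na(X)) return(-Inf)
    E[2] * fX(X, P) - E[3] * g(P)
  }
  if (r(1e-10) <= 0) return(NULL)
  hi <- S - 1e-6
  if (r(hi) >= 0) return(NULL)
  P <- stats::uniroot(r, c(1e-10, hi), tol = 1e-12)$root
  X <- X_of_P(P)
  list(X = X, P = P, V_P = E[3] * g(P))
}

# Brute-force enzyme-space oracle for the isolated cell: two-stage grid
# search over (E_S, E_X, E_P), keeping the cheapest allocation whose steady
# state meets the demand.  Returns the minimal enzyme sum.
single_cell_grid_oracle <- function(S = 10, inv_K_I = 0, J = 1,
                                    range1 = c(0.5, 8), n1 = 12, n2 = 9) {
  best <- Inf; best_E <- NULL
  scan <- function(grid) {
    for (e1 in grid) for (e2 in grid2 <- grid) for (e3 in grid) {
      if (e1 + e2 + e3 >= best) next
      ss <- single_cell_steady(c(e1, e2, e3), S, inv_K_I)
      if (!is.null(ss) && ss$V_P >= J * (1 - 1e-9)) {
        best <<- e1 + e2 + e3
        best_E <<- c(e1, e2, e3)
      }
    }
  }
  scan(exp(seq(log(range1[1]), log(range1[2]), length.out = n1)))
  if (is.null(best_E)) return(Inf)
  fine <- lapply(best_E, function(e)
    exp(seq(log(e / 1.35), log(e * 1.35), length.out = n2)))
  for (e1 in fine[[1]]) for (e2 in fine[[2]]) for (e3 in fine[[3]]) {
    if (e1 + e2 + e3 >= best) next
    ss <- single_cell_steady(c(e1, e2, e3), S, inv_K_I)
    if (!is.null(ss) && ss$V_P >= J * (1 - 1e-9)) {
      best <- e1 + e2 + e3
      best_E <- c(e1, e2, e3)
    }
  }
  best
}

# Fast solver options for tests that exercise behaviour rather than optimum
# quality.
fast_opts <- function(seed = 1, n_starts = 6, ...) {
  solver_options(n_starts = n_starts, seed = seed, maxit = 300, ...)
}

# Random valid compartment state for a model.
random_state <- function(model, seed) {
  set.seed(seed)
  m <- model$chain_length
  intra <- matrix(runif(2 * (m + 1), 0, 5), 2)
  exch <- names(model$permeabilities)[model$permeabilities > 0]
  extra <- stats::setNames(runif(length(exch), 0, 5), exch)
  compartment_state(model, intra, extra)
}
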