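## Dense two-phase simplex for small LPs of the form
##   max c'x  s.t.  A x = b,  lb <= x <= ub
## Bland's rule throughout, so termination is guaranteed.  Written for
## the model sizes this package analyses in tests (tens of reactions);
## genome-scale models should use the "scipy" (HiGHS) backend.
##
## Infinite bounds are clamped to +/- .simplex_big; an optimum that hits
## the clamp is reported as "unbounded".
.simplex_big <- 1e6

simplex_solve <- function(c_obj, A, b, lb, ub, maximize = TRUE,
                          tol = 1e-9) {
  n <- length(c_obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  A <- as.matrix(A)
  clamped <- !is.finite(lb) | !is.finite(ub)
  lb <- pmax(lb, -.simplex_big)
  ub <- pmin(ub, .simplex_big)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ub <- pmax(ub, lb)
  if (!maximize) c_obj <- -c_obj

  ## shift to y = x - lb >= 0; add explicit rows y_i + s_i = d_i
  m_eq <- nrow(A)
  d <- ub - lb
  b2 <- b - drop(A %*% lb)
  ## normalize equality rows to non-negative rhs
  neg <- b2 < 0
  A2 <- A
  A2[neg, ] <- -A2[neg, , drop = FALSE]
  b2[neg] <- -b2[neg]

  n_var <- 2L * n          # y then slacks s
  n_art <- m_eq            # artificials for equality rows
  m_tot <- m_eq + n
  ## tableau T: rows constraints, cols [y | s | a], plus rhs vector
  Tm <- matrix(0, m_tot, n_var + n_art)
  rhs <- numeric(m_tot)
  Tm[seq_len(m_eq), seq_len(n)] <- A2
  if (n_art > 0)
    Tm[cbind(seq_len(m_eq), n_var + seq_len(m_eq))] <- 1
  rhs[seq_len(m_eq)] <- b2
  for (i in seq_len(n)) {
    Tm[m_eq + i, i] <- 1
    Tm[m_eq + i, n + i] <- 1
    rhs[m_eq + i] <- d[i]
  }
  basis <- c(n_var + seq_len(m_eq), n + seq_len(n))

  pivot <- function(row, col) {
    piv <- Tm[row, col]
    Tm[row, ] <<- Tm[row, ] / piv
    rhs[row] <<- rhs[row] / piv
    other <- which(abs(Tm[, col]) > 0 & seq_len(m_tot) != row)
    for (i in other) {
      f <- Tm[i, col]
      Tm[i, ] <<- Tm[i, ] - f * Tm[row, ]
      rhs[i] <<- rhs[i] - f * rhs[row]
    }
    rhs[abs(rhs) < tol] <<- 0
    basis[row] <<- col
  }

  run_phase <- function(obj, allowed) {
    ## maximize obj over allowed columns; returns "optimal"/"unbounded"
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > 20000L) stop("simplex iteration limit exceeded")
      ## reduced costs: z_j - c_j with current basis
      cb <- obj[basis]
      red <- obj - drop(crossprod(Tm, cb))
      red[!allowed] <- -Inf
      enter_cands <- which(red > tol)
      if (!length(enter_cands)) return("optimal")
      enter <- enter_cands[1L]          # Bland: lowest index
      col <- Tm[, enter]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      leave <- cand[which.min(basis[cand])] # Bland tie-break
      pivot(leave, enter)
    }
  }

  ## Phase 1: drive artificials to zero
  if (n_art > 0) {
    obj1 <- c(rep(0, n_var), rep(-1, n_art))
    st <- run_phase(obj1, rep(TRUE, n_var + n_art))
    infeas <- sum(rhs[basis > n_var])
    if (st != "optimal" || infeas > 1e-7)
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    ## pivot remaining zero-level artificials out of the basis
    for (row in which(basis > n_var)) {
      cands <- which(abs(Tm[row, seq_len(n_var)]) > tol)
      if (length(cands)) pivot(row, cands[1L])
      ## else: redundant row; artificial stays basic at 0, harmless
    }
  }

  ## Phase 2
  obj2 <- c(c_obj, rep(0, n), rep(0, n_art))
  allowed <- c(rep(TRUE, n_var), rep(FALSE, n_art))
  st <- run_phase(obj2, allowed)
  if (st == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))

  y <- numeric(n_var + n_art)
  y[basis] <- rhs
  x <- y[seq_len(n)] + lb
  obj_val <- sum(c_obj * y[seq_len(n)]) + sum(c_obj * lb)
  if (!maximize) obj_val <- -obj_val
  ## an objective variable pinned to a clamped infinite bound means the
  ## true LP is unbounded in that direction
  hit <- clamped & (abs(x) >= 0.99 * .simplex_big) & abs(c_obj) > 0
  if (any(hit))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  list(status = "optimal", objective = obj_val, x = x)
}
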