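# Bounded-variable two-phase revised simplex.
#
# Solves   max  c'x   s.t.  A x = b,  l <= x <= u
# with dense linear algebra; adequate for the network sizes this package
# targets (hundreds of reactions). Degeneracy is handled by switching from
# Dantzig pricing to Bland's rule after a run of degenerate pivots, and
# redundant equality rows (rank-deficient stoichiometric matrices are the
# norm) are absorbed by artificial variables pinned to zero after phase 1.

.LP_BIG <- 1e6  # stand-in for infinite bounds; FBA convention scales ~1000

#' Solve a bounded linear program
#'
#' Internal workhorse behind [solve_fba()]. Maximizes `obj %*% x` subject to
#' `A x = b` and `lower <= x <= upper`. Infinite bounds are clamped to
#' `+/-1e6`.
#'
#' @param A Dense or sparse constraint matrix (rows = equalities).
#' @param b Right-hand side vector.
#' @param lower,upper Variable bounds.
#' @param obj Objective coefficients.
#' @param maximize Direction; `FALSE` minimizes.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failure"`), `x` (solution, `NULL` unless optimal) and `objective`.
#' @keywords internal
solve_lp <- function(A, b, lower, upper, obj, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lower) == n, length(upper) == n,
            length(obj) == n)
  if (any(lower > upper)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  l <- pmax(lower, -.LP_BIG)
  u <- pmin(upper, .LP_BIG)
  cvec <- if (maximize) obj else -obj

  # initial nonbasic point: each structural variable at its bound nearest 0
  x0 <- ifelse(abs(l) <= abs(u), l, u)
  at_upper <- abs(l) > abs(u)
  r <- b - drop(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  ncol_all <- n + m
  Acols <- cbind(A, diag(sgn, nrow = m))
  lb <- c(l, rep(0, m))
  ub <- c(u, rep(Inf, m))
  xval <- c(x0, abs(r))
  basis <- (n + 1L):ncol_all
  # nonbasic status: TRUE = at upper bound
  nb_upper <- c(at_upper, rep(FALSE, m))
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  dtol <- 1e-9; ptol <- 1e-10; feastol <- 1e-7
  max_iter <- 200L * (ncol_all + 10L)

  run_phase <- function(cc, state) {
    basis <- state$basis; xval <- state$xval
    nb_upper <- state$nb_upper; is_basic <- state$is_basic
    lb <- state$lb; ub <- state$ub
    degen_run <- 0L
    for (iter in seq_len(max_iter)) {
      B <- Acols[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cc[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "failure"))
      nonbasic <- which(!is_basic)
      dvec <- cc[nonbasic] - drop(crossprod(Acols[, nonbasic, drop = FALSE], y))
      movable <- lb[nonbasic] < ub[nonbasic]
      cand <- movable & ((!nb_upper[nonbasic] & dvec > dtol) |
                           (nb_upper[nonbasic] & dvec < -dtol))
      if (!any(cand)) {
        return(list(status = "optimal", basis = basis, xval = xval,
                    nb_upper = nb_upper, is_basic = is_basic,
                    lb = lb, ub = ub))
      }
      idx <- which(cand)
      if (degen_run > 40L) {
        pick <- idx[which.min(nonbasic[idx])]       # Bland
      } else {
        pick <- idx[which.max(abs(dvec[idx]))]      # Dantzig
      }
      j <- nonbasic[pick]
      s <- if (nb_upper[j]) -1 else 1
      dB <- -s * tryCatch(solve(B, Acols[, j]), error = function(e) NULL)
      if (is.null(dB)) return(list(status = "failure"))
      # ratio test
      t_enter <- ub[j] - lb[j]
      t_best <- t_enter; leave_pos <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        di <- dB[i]
        if (di > ptol) {
          ti <- (ub[basis[i]] - xval[basis[i]]) / di
          if (ti < t_best - 1e-12 ||
              (ti < t_best + 1e-12 && leave_pos > 0L &&
               basis[i] < basis[leave_pos])) {
            t_best <- max(ti, 0); leave_pos <- i; leave_to_upper <- TRUE
          }
        } else if (di < -ptol) {
          ti <- (lb[basis[i]] - xval[basis[i]]) / di
          if (ti < t_best - 1e-12 ||
              (ti < t_best + 1e-12 && leave_pos > 0L &&
               basis[i] < basis[leave_pos])) {
            t_best <- max(ti, 0); leave_pos <- i; leave_to_upper <- FALSE
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded"))
      }
      degen_run <- if (t_best < 1e-11) degen_run + 1L else 0L
      xval[basis] <- xval[basis] + t_best * dB
      xval[j] <- xval[j] + s * t_best
      if (leave_pos == 0L) {
        nb_upper[j] <- !nb_upper[j]   # bound flip, basis unchanged
      } else {
        out <- basis[leave_pos]
        xval[out] <- if (leave_to_upper) ub[out] else lb[out]
        is_basic[out] <- FALSE
        nb_upper[out] <- leave_to_upper
        basis[leave_pos] <- j
        is_basic[j] <- TRUE
      }
    }
    list(status = "failure")
  }

  state <- list(basis = basis, xval = xval, nb_upper = nb_upper,
                is_basic = is_basic, lb = lb, ub = ub)
  if (any(abs(r) > feastol)) {
    cc1 <- c(rep(0, n), rep(-1, m))
    state <- run_phase(cc1, state)
    if (state$status != "optimal") {
      return(list(status = if (state$status == "unbounded") "failure" else
        state$status, x = NULL, objective = NA_real_))
    }
    art_total <- sum(state$xval[(n + 1L):ncol_all])
    if (art_total > feastol * (1 + max(abs(b)))) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    }
  }
  # pin artificials at zero for phase 2 (redundant rows keep them basic at 0)
  state$lb[(n + 1L):ncol_all] <- 0
  state$ub[(n + 1L):ncol_all] <- 0
  state$xval[(n + 1L):ncol_all] <- pmin(pmax(state$xval[(n + 1L):ncol_all], 0), 0)

  cc2 <- c(cvec, rep(0, m))
  state <- run_phase(cc2, state)
  if (state$status != "optimal") {
    return(list(status = state$status, x = NULL, objective = NA_real_))
  }
  x <- state$xval[seq_len(n)]
  x <- pmin(pmax(x, l), u)  # shave roundoff on the bounds
  list(status = "optimal", x = x, objective = sum(obj * x))
}
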