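#' Linear-program solver contract
#'
#' All growth-rate and flux computations in this package go through one
#' solve-LP contract: minimize or maximize `obj' x` subject to `A x = b`
#' and `lb <= x <= ub`. The backend is a dense bounded-variable revised
#' simplex with a composite (Maros-style) phase 1, an explicitly
#' maintained basis inverse with eta updates and periodic
#' refactorization, and a Bland anti-cycling fallback. Double precision
#' with a feasibility tolerance of 1e-9 is the numerical contract; see
#' the methods vignette for the fidelity discussion.
#'
#' Warm starts: the returned `state` (basis + nonbasic bound statuses)
#' can be passed back for a problem of identical dimensions with
#' modified bounds or objective; the composite phase 1 repairs any
#' resulting infeasibility, which makes sequences of closely related
#' solves (bisection steps, single-protein depletions) cheap.
#'
#' @param A Constraint matrix (dense or `Matrix` sparse), m x n.
#' @param lb,ub Variable bounds, length n, all finite.
#' @param obj Objective coefficients (length n) or `NULL` for a pure
#'   feasibility solve.
#' @param b Right-hand side (default all zero).
#' @param maximize Maximize `obj` (default) or minimize.
#' @param control List from [lp_control()].
#' @param state Optional warm-start state from a previous solve.
#' @return A list with `status` ("optimal", "infeasible" or
#'   "solver_error"), `x` (length n), `objval`, `iter`, and `state`.
#' @export
solve_lp <- function(A, lb, ub, obj = NULL, b = NULL, maximize = TRUE,
                     control = lp_control(), state = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(lb) == n, length(ub) == n, length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds; replace infinities by the model's INF sentinel")
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL,
                                        objval = NA_real_, iter = 0L, state = NULL))
  res <- tryCatch(
    simplex_bounded(A, b, lb, ub, obj, maximize, control, state),
    error = function(e) list(status = "solver_error", x = NULL, objval = NA_real_,
                             iter = 0L, state = NULL, message = conditionMessage(e))
  )
  res
}

#' Solver control parameters
#'
#' @param tol_feas Primal feasibility tolerance.
#' @param tol_d Reduced-cost (dual) tolerance.
#' @param tol_piv Smallest acceptable pivot magnitude.
#' @param max_iter Iteration cap across both phases.
#' @param refactor_every Refactorize the basis inverse this often.
#' @return A named list.
#' @export
lp_control <- function(tol_feas = 1e-9, tol_d = 1e-9, tol_piv = 1e-7,
                       max_iter = 50000L, refactor_every = 30L) {
  list(tol_feas = tol_feas, tol_d = tol_d, tol_piv = tol_piv,
       max_iter = as.integer(max_iter), refactor_every = as.integer(refactor_every))
}

## Internal bounded-variable revised simplex.
## Columns n+1..n+m are fixed-at-zero artificial identity columns; they make
## every basis completable and give the cold start (B = I).
## Internal bounded-variable revised simplex.
## Columns n+1..n+m are fixed-at-zero artificial identity columns; they make
## every basis completable and give the cold start (B = I). Phase 1 is the
## composite method: basic variables outside their bounds carry cost -1/+1
## until primal feasible, which doubles as warm-start repair after bound
## changes. ME LPs mix O(1) stoichiometry with O(mu/k_eff) coupling entries,
## so the basis can become ill-conditioned; a singular or drifted
## factorization triggers repair or a full reset back to phase 1.
simplex_bounded <- function(A, b, lb, ub, obj, maximize, control, state) {
  m <- nrow(A); n <- ncol(A)
  N <- n + m
  Afull <- cbind(A, Matrix::Diagonal(m))
  Afull <- methods::as(methods::as(Afull, "generalMatrix"), "CsparseMatrix")
  LB <- c(lb, numeric(m))
  UB <- c(ub, numeric(m))
  fixed <- LB >= UB
  cost <- numeric(N)
  if (!is.null(obj)) {
    stopifnot(length(obj) == n)
    cost[seq_len(n)] <- if (maximize) -obj else obj
  }

  if (!is.null(state) && length(state$basic) == m &&
      length(state$at_upper) == N && all(state$basic >= 1L) &&
      all(state$basic <= N)) {
    basic <- state$basic
    at_upper <- state$at_upper
  } else {
    basic <- seq.int(n + 1L, N)
    at_upper <- rep(FALSE, N)
  }
  inbase <- rep(FALSE, N); inbase[basic] <- TRUE
  at_upper[inbase] <- FALSE
  x <- ifelse(at_upper, UB, LB)
  x[basic] <- 0

  did_reset <- FALSE
  resets <- 0L
  reset_basis <- function() {
    did_reset <<- TRUE
    resets <<- resets + 1L
    for (v in basic[basic <= n]) { at_upper[v] <<- FALSE; x[v] <<- LB[v] }
    inbase[] <<- FALSE
    basic <<- seq.int(n + 1L, N)
    inbase[basic] <<- TRUE
    diag(m)
  }
  refactor <- function() {
    B <- as.matrix(Afull[, basic, drop = FALSE])
    Bi <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Bi)) {
      ## singular basis: swap dependent columns for artificial identity
      ## columns of uncovered rows; on any failure, reset completely
      Bi <- tryCatch({
        qrB <- qr(B)
        r <- qrB$rank
        if (r >= m) stop("singular at full rank")
        drop_pos <- qrB$pivot[seq.int(r + 1L, m)]
        keep <- qrB$pivot[seq_len(r)]
        for (p in drop_pos) {
          inbase[basic[p]] <<- FALSE
          at_upper[basic[p]] <<- FALSE
          x[basic[p]] <<- LB[basic[p]]
        }
        Bk <- as.matrix(Afull[, basic[keep], drop = FALSE])
        qt <- qr(t(Bk))
        covered <- qt$pivot[seq_len(qt$rank)]
        freerows <- setdiff(seq_len(m), covered)
        basic[drop_pos] <<- n + freerows[seq_along(drop_pos)]
        inbase[basic[drop_pos]] <<- TRUE
        did_reset <<- TRUE  # basis changed structurally; redo phase 1
        solve(as.matrix(Afull[, basic, drop = FALSE]))
      }, error = function(e) NULL)
      if (is.null(Bi)) Bi <- reset_basis()
    }
    Bi
  }
  Binv <- refactor()
  did_reset <- FALSE

  set_basic_values <- function() {
    xn <- x; xn[basic] <- 0
    r <- b - as.numeric(Afull %*% xn)
    x[basic] <<- as.numeric(Binv %*% r)
  }
  set_basic_values()

  tolp <- control$tol_feas * max(1, max(abs(b), 1))
  told <- control$tol_d
  iter <- 0L
  eta_count <- 0L
  stall <- 0L
  bland <- FALSE
  phase <- 1L
  cols_struct <- which(!fixed)
  outcome <- NULL

  while (is.null(outcome)) {
    if (resets > 5L) { outcome <- "error:repeated basis resets"; break }
    if (did_reset) {
      did_reset <- FALSE
      phase <- 1L
      set_basic_values()
    }
    if (iter >= control$max_iter) { outcome <- "error:iteration limit"; break }

    xb <- x[basic]
    lo_viol <- xb < LB[basic] - tolp
    hi_viol <- xb > UB[basic] + tolp
    infeas <- sum(pmax(LB[basic] - xb, 0)) + sum(pmax(xb - UB[basic], 0))

    if (phase == 1L && !any(lo_viol) && !any(hi_viol)) {
      if (is.null(obj)) { outcome <- "done"; break }
      phase <- 2L
      next
    }
    if (phase == 2L && (any(lo_viol) || any(hi_viol))) {
      ## drift re-introduced infeasibility; repair it first
      phase <- 1L
      next
    }

    if (phase == 1L) {
      cB <- numeric(m); cB[lo_viol] <- -1; cB[hi_viol] <- 1
    } else {
      cB <- cost[basic]
    }
    y <- as.numeric(crossprod(Binv, cB))
    dall <- (if (phase == 1L) numeric(N) else cost) -
      as.numeric(Matrix::crossprod(Afull, y))

    cand <- cols_struct[!inbase[cols_struct]]
    dl <- dall[cand]
    up <- at_upper[cand]
    improving <- (!up & dl < -told) | (up & dl > told)
    if (!any(improving)) {
      if (phase == 1L) {
        if (infeas <= 10 * tolp) {
          if (is.null(obj)) { outcome <- "done"; break }
          phase <- 2L
          next
        }
        outcome <- "infeasible"; break
      }
      outcome <- "done"; break
    }
    ci <- cand[improving]
    j <- if (bland) ci[1L] else ci[which.max(abs(dl[improving]))]
    tdir <- if (at_upper[j]) -1 else 1

    w <- as.numeric(Binv %*% as.numeric(Afull[, j]))
    rate <- -tdir * w

    theta <- UB[j] - LB[j]
    leave_pos <- 0L
    xbv <- x[basic]
    lbB <- LB[basic]; ubB <- UB[basic]
    for (i in seq_len(m)) {
      ri <- rate[i]
      if (abs(ri) < control$tol_piv) next
      xi <- xbv[i]
      if (xi < lbB[i] - tolp) {
        if (ri > 0) t_i <- (lbB[i] - xi) / ri else next
      } else if (xi > ubB[i] + tolp) {
        if (ri < 0) t_i <- (ubB[i] - xi) / ri else next
      } else {
        t_i <- if (ri > 0) (ubB[i] - xi) / ri else (lbB[i] - xi) / ri
      }
      if (t_i < theta - 1e-12 ||
          (t_i < theta + 1e-12 && leave_pos > 0L && abs(ri) > abs(rate[leave_pos]))) {
        theta <- t_i
        leave_pos <- i
      }
    }
    if (!is.finite(theta)) { outcome <- "error:unbounded step"; break }
    theta <- max(theta, 0)

    x[j] <- x[j] + tdir * theta
    x[basic] <- x[basic] + rate * theta
    if (theta <= 1e-11) stall <- stall + 1L else { stall <- 0L; bland <- FALSE }
    if (stall > 150L) bland <- TRUE
    if (stall > 3000L) { outcome <- "error:cycling detected"; break }

    if (leave_pos == 0L) {
      at_upper[j] <- !at_upper[j]
      x[j] <- if (at_upper[j]) UB[j] else LB[j]
    } else {
      lv <- basic[leave_pos]
      piv <- w[leave_pos]
      if (abs(piv) < control$tol_piv) {
        Binv <- refactor(); set_basic_values(); iter <- iter + 1L
        next
      }
      xl <- x[lv]
      at_upper[lv] <- abs(xl - UB[lv]) < abs(xl - LB[lv])
      x[lv] <- if (at_upper[lv]) UB[lv] else LB[lv]
      if (fixed[lv]) at_upper[lv] <- FALSE
      inbase[lv] <- FALSE
      basic[leave_pos] <- j
      inbase[j] <- TRUE
      at_upper[j] <- FALSE
      brow <- Binv[leave_pos, ] / piv
      Binv <- Binv - outer(w, brow)
      Binv[leave_pos, ] <- brow
      eta_count <- eta_count + 1L
      if (eta_count >= control$refactor_every) {
        Binv <- refactor(); set_basic_values(); eta_count <- 0L
      }
    }
    iter <- iter + 1L
  }

  if (startsWith(outcome, "error:"))
    return(list(status = "solver_error", x = NULL, objval = NA_real_,
                iter = iter, state = NULL, message = sub("^error:", "", outcome)))
  if (outcome == "infeasible")
    return(list(status = "infeasible", x = NULL, objval = NA_real_, iter = iter,
                state = list(basic = basic, at_upper = at_upper)))

  ## verify the final point against a fresh factorization
  Binv <- refactor()
  if (!did_reset) set_basic_values()
  xb <- x[basic]
  viol <- sum(pmax(LB[basic] - xb, 0)) + sum(pmax(xb - UB[basic], 0))
  if (did_reset || viol > 1e-6)
    return(list(status = "solver_error", x = NULL, objval = NA_real_,
                iter = iter, state = NULL, message = "numerical drift at exit"))
  x[basic] <- pmin(pmax(xb, LB[basic]), UB[basic])
  xs <- x[seq_len(ncol(A))]
  objval <- if (is.null(obj)) NA_real_ else sum(obj * xs)
  list(status = "optimal", x = xs, objval = objval, iter = iter,
       state = list(basic = basic, at_upper = at_upper))
}
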