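#' Growth-rate search options
#'
#' @param mu_lo,mu_hi Growth-rate search interval (h^-1), `0 <= mu_lo < mu_hi`.
#' @param bisect_tol Absolute bisection tolerance on mu (h^-1).
#' @param feas_tol LP feasibility tolerance.
#' @param max_iter Bisection iteration cap.
#' @return A named list of class `solve_options`.
#' @export
solve_options <- function(mu_lo = 0, mu_hi = 2, bisect_tol = 1e-6,
                          feas_tol = 1e-9, max_iter = 80L) {
  stopifnot(mu_lo >= 0, mu_lo < mu_hi, bisect_tol > 0, feas_tol > 0)
  structure(list(mu_lo = mu_lo, mu_hi = mu_hi, bisect_tol = bisect_tol,
                 feas_tol = feas_tol, max_iter = as.integer(max_iter)),
            class = "solve_options")
}

#' Test LP feasibility at a fixed growth rate
#'
#' Assembles the LP at `mu` and runs a pure feasibility solve. The
#' all-zero flux vector always satisfies `S v = 0`, so feasibility hinges
#' on the bounds (the biomass lower bound raised to `mu`, and the medium).
#'
#' @param model An `me_model`.
#' @param mu Growth rate, h^-1.
#' @param options A [solve_options()] list.
#' @param state Optional LP warm-start state.
#' @return A list: `feasible` (logical, `NA` on solver error), `flux`
#'   (named vector or `NULL`), `state`, `status`.
#' @export
feasible_at <- function(model, mu, options = solve_options(), state = NULL) {
  lp <- assemble_lp(model, mu)
  res <- solve_lp(lp$A, lp$lb, lp$ub, obj = NULL,
                  control = lp_control(tol_feas = options$feas_tol),
                  state = state)
  if (res$status == "solver_error") {
    ## retry cold with conservative numerics before giving up
    res <- solve_lp(lp$A, lp$lb, lp$ub, obj = NULL,
                    control = lp_control(tol_feas = options$feas_tol,
                                         refactor_every = 10L))
  }
  if (res$status == "solver_error")
    return(list(feasible = NA, flux = NULL, state = NULL,
                status = "solver_error", message = res$message))
  if (res$status == "infeasible")
    return(list(feasible = FALSE, flux = NULL, state = res$state,
                status = "infeasible"))
  list(feasible = TRUE, flux = stats::setNames(res$x, lp$col_ids),
       state = res$state, status = "optimal")
}

#' Maximize the growth rate by bisection over LP feasibility
#'
#' Standard feasibility bisection: keep a feasible lower and infeasible
#' upper bracket and halve until the bracket width is below tolerance.
#' The reported `mu_max` is the feasible end, with the certifying flux
#' vector from the last feasible solve.
#'
#' @param model An `me_model`.
#' @param options A [solve_options()] list.
#' @return A list of class `solve_result`: `status` ("optimal" or
#'   "infeasible_at_floor"), `mu_max`, `flux`, `iterations`, `notes`.
#' @export
maximize_growth <- function(model, options = solve_options()) {
  model <- cache_lp_structure(model)
  notes <- character(0)
  lo <- options$mu_lo
  f_lo <- feasible_at(model, lo, options)
  if (identical(f_lo$feasible, NA))
    stop("solver error at mu = ", lo, ": ", f_lo$message)
  if (!f_lo$feasible) {
    return(structure(list(status = "infeasible_at_floor", mu_max = NA_real_,
                          flux = NULL, iterations = 1L, notes = notes),
                     class = "solve_result"))
  }
  state <- f_lo$state
  best_flux <- f_lo$flux
  hi <- options$mu_hi
  f_hi <- feasible_at(model, hi, options, state)
  iters <- 2L
  if (isTRUE(f_hi$feasible)) {
    notes <- c(notes, "feasible at mu_hi; search interval may be too small")
    return(structure(list(status = "optimal", mu_max = hi, flux = f_hi$flux,
                          iterations = iters, notes = notes),
                     class = "solve_result"))
  }
  mu_lo <- lo; mu_hi <- hi
  while (mu_hi - mu_lo > options$bisect_tol && iters < options$max_iter) {
    mid <- (mu_lo + mu_hi) / 2
    f <- feasible_at(model, mid, options, state)
    iters <- iters + 1L
    if (identical(f$feasible, NA)) {
      notes <- c(notes, paste0("solver error at mu = ", mid, "; treated as infeasible"))
      mu_hi <- mid
      next
    }
    if (f$feasible) {
      mu_lo <- mid
      best_flux <- f$flux
      state <- f$state
    } else {
      mu_hi <- mid
    }
  }
  structure(list(status = "optimal", mu_max = mu_lo, flux = best_flux,
                 iterations = iters, notes = notes),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("<solve_result> status: ", x$status, ", mu_max = ",
      format(x$mu_max, digits = 8), " 1/h (", x$iterations, " feasibility solves)\n",
      sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Optimize a linear flux objective at a fixed growth rate
#'
#' Growth is handled by fixing `mu` (the biomass lower bound is raised to
#' it); on top of that any linear objective over reaction fluxes can be
#' optimized, e.g. sink-flux sums for the blockage test.
#'
#' @param model An `me_model`.
#' @param mu Growth rate, h^-1; must be feasible.
#' @param objective Named numeric vector: reaction id -> weight.
#' @param maximize Direction.
#' @param options A [solve_options()] list.
#' @return Named flux vector at the optimum.
#' @export
optimize_at_mu <- function(model, mu, objective, maximize = TRUE,
                           options = solve_options()) {
  lp <- assemble_lp(model, mu)
  w <- numeric(length(lp$col_ids))
  idx <- match(names(objective), lp$col_ids)
  if (anyNA(idx)) stop("unknown reaction(s) in objective: ",
                       paste(names(objective)[is.na(idx)], collapse = ", "))
  w[idx] <- objective
  res <- solve_lp(lp$A, lp$lb, lp$ub, obj = w, maximize = maximize,
                  control = lp_control(tol_feas = options$feas_tol))
  if (res$status == "infeasible") stop("infeasible at mu = ", mu)
  if (res$status != "optimal") stop("solver error at mu = ", mu, ": ", res$message)
  stats::setNames(res$x, lp$col_ids)
}

#' Parsimonious flux distribution at a fixed growth rate
#'
#' Among the (generally degenerate) feasible flux vectors at `mu`,
#' returns one minimizing the total absolute flux via the standard
#' split-variable LP. All reported flux summaries (activities, partition
#' ratios, inventories) use this solution, making them deterministic.
#'
#' @param model An `me_model`.
#' @param mu Growth rate, h^-1; must be feasible.
#' @param options A [solve_options()] list.
#' @return Named flux vector.
#' @export
parsimonious_solution <- function(model, mu, options = solve_options()) {
  lp <- assemble_lp(model, mu)
  n <- length(lp$col_ids)
  lb <- lp$lb; ub <- lp$ub
  ## split columns: v = p - q with p, q >= 0; variables with one-signed
  ## ranges keep a single column to avoid needless degeneracy
  pos_j <- which(lb >= 0)
  neg_j <- which(ub <= 0 & lb < 0)
  mix_j <- setdiff(seq_len(n), c(pos_j, neg_j))
  cols <- list(); sgn <- numeric(0); src <- integer(0)
  slb <- numeric(0); sub <- numeric(0)
  add_col <- function(j, s, l, u) {
    sgn <<- c(sgn, s); src <<- c(src, j); slb <<- c(slb, l); sub <<- c(sub, u)
  }
  for (j in pos_j) add_col(j, 1, lb[j], ub[j])
  for (j in neg_j) add_col(j, -1, -ub[j], -lb[j])
  for (j in mix_j) { add_col(j, 1, 0, ub[j]); add_col(j, -1, 0, -lb[j]) }
  A2 <- lp$A[, src, drop = FALSE] %*% Matrix::Diagonal(x = sgn)
  res <- solve_lp(A2, slb, sub, obj = rep(1, length(src)), maximize = FALSE,
                  control = lp_control(tol_feas = options$feas_tol))
  if (res$status == "infeasible") stop("infeasible at mu = ", mu)
  if (res$status != "optimal") stop("solver error at mu = ", mu, ": ", res$message)
  v <- numeric(n)
  contrib <- res$x * sgn
  for (k in seq_along(src)) v[src[k]] <- v[src[k]] + contrib[k]
  stats::setNames(v, lp$col_ids)
}

#' Brute-force growth-rate oracle by upward grid scan
#'
#' Independent of the bisection path: scans mu upward from 0 in steps of
#' `delta` and returns the largest grid point that is LP-feasible.
#'
#' @param model An `me_model`.
#' @param delta Grid step (h^-1).
#' @param mu_hi Scan ceiling.
#' @param options A [solve_options()] list.
#' @return The growth-rate estimate (0 if infeasible at every mu > 0).
#' @export
brute_force_mu_max <- function(model, delta = 1e-3, mu_hi = 2,
                               options = solve_options()) {
  model <- cache_lp_structure(model)
  mu <- 0
  state <- NULL
  best <- 0
  repeat {
    f <- feasible_at(model, mu, options, state)
    if (!isTRUE(f$feasible)) break
    best <- mu
    state <- f$state
    mu <- mu + delta
    if (mu > mu_hi + 1e-15) break
  }
  best
}
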