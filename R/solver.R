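#' Bounded-variable linear programming by the two-phase simplex method
#'
#' Solves
#' \deqn{\max_{v} \; c^\top v \quad \text{s.t.} \quad A v = b,\; l \le v \le u}
#' with a dense revised simplex that keeps nonbasic variables at one of
#' their finite bounds.  This is the workhorse behind every flux balance
#' analysis call in the package; it is written for the moderately sized,
#' highly degenerate equality systems that stoichiometric models produce,
#' where off-the-shelf textbook tableau codes tend to cycle or go
#' singular.
#'
#' Phase 1 minimizes the sum of artificial variables to find a basic
#' feasible point; phase 2 optimizes the user objective.  Pricing is
#' Dantzig's rule with an automatic switch to Bland's rule when progress
#' stalls, which guarantees termination on degenerate problems.  The
#' basis inverse is re-factorized from scratch at every iteration
#' (problems here have at most a few hundred rows, so robustness is
#' cheaper than speed).
#'
#' @param obj numeric objective vector `c`.
#' @param A dense or sparse constraint matrix (rows = equalities).
#' @param b right-hand side vector.
#' @param lb,ub finite lower/upper bounds on the variables.  Infinite
#'   bounds are clamped to `big` with a warning, since flux bounds in
#'   constraint-based models are conventionally finite (+/- 1000).
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility / pivot tolerance.
#' @param max_iter iteration cap; degenerate FBA bases rarely need more
#'   than a few times the row count.
#' @param big replacement magnitude for infinite bounds.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the primal point `x` (length = ncol(A)).
#' @keywords internal
simplex_bounded <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                            tol = 1e-9, max_iter = NULL, big = 1e5) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) stop("infeasible bounds: lb > ub")
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    warning("infinite bounds clamped to +/- ", big)
    lb <- pmax(lb, -big)
    ub <- pmin(ub, big)
  }
  cc <- if (sense == "max") obj else -obj
  if (is.null(max_iter)) max_iter <- max(2000L, 60L * (m + n))

  ## Variable status: 0 = nonbasic at lb, 1 = nonbasic at ub, 2 = basic.
  ## Start all structural variables at the bound of smaller magnitude and
  ## make the m artificial columns the initial basis.
  at_upper <- abs(ub) < abs(lb)
  x <- ifelse(at_upper, ub, lb)
  resid <- b - as.vector(A %*% x)
  art_sign <- ifelse(resid >= 0, 1, -1)
  n_tot <- n + m
  Afull <- cbind(A, diag(art_sign, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(big * m + sum(abs(resid)) + 1, m))
  status <- integer(n_tot)
  status[seq_len(n)] <- ifelse(at_upper, 1L, 0L)
  status[n + seq_len(m)] <- 2L
  basis <- n + seq_len(m)
  xf <- c(x, abs(resid))

  run_phase <- function(cvec, basis, status, xf, phase1) {
    iter <- 0L
    stalled <- 0L
    last_obj <- -Inf
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit", basis = basis,
                    vstat = status, x = xf))
      }
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) {
        return(list(status = "singular", basis = basis,
                    vstat = status, x = xf))
      }
      y <- as.vector(crossprod(Binv, cvec[basis]))      # duals
      nonbasic <- which(status != 2L)
      dj <- cvec[nonbasic] - as.vector(y %*% Afull[, nonbasic, drop = FALSE])
      ## A nonbasic variable improves the (maximized) objective if it has
      ## positive reduced cost at its lower bound or negative at its upper.
      improving <- (status[nonbasic] == 0L & dj > tol) |
                   (status[nonbasic] == 1L & dj < -tol)
      if (!any(improving)) {
        return(list(status = "optimal", basis = basis, vstat = status,
                    x = xf, Binv = Binv))
      }
      cand <- nonbasic[improving]
      use_bland <- stalled > 2L * (m + 10L)
      if (use_bland) {
        q <- min(cand)                                  # Bland: smallest index
      } else {
        gain <- abs(dj[improving])
        q <- cand[which.max(gain)]
      }
      ## Direction: entering variable moves up from lb (+1) or down from ub.
      dirn <- if (status[q] == 0L) 1 else -1
      d <- dirn * as.vector(Binv %*% Afull[, q])        # basic vars move by -d*t
      xb <- xf[basis]
      ## Ratio test: t limited by entering var's own span and by each basic
      ## variable hitting one of its bounds.
      t_max <- ubf[q] - lbf[q]
      leave <- 0L                                       # 0 = bound flip
      for (i in seq_len(m)) {
        if (d[i] > tol) {
          tt <- (xb[i] - lbf[basis[i]]) / d[i]
        } else if (d[i] < -tol) {
          tt <- (xb[i] - ubf[basis[i]]) / d[i]
        } else next
        if (tt < t_max - tol ||
            (tt < t_max + tol && leave != 0L && use_bland &&
             basis[i] < basis[leave])) {
          t_max <- max(tt, 0)
          leave <- i
        }
      }
      if (is.infinite(t_max)) {
        return(list(status = "unbounded", basis = basis, vstat = status,
                    x = xf))
      }
      ## Apply the step.
      xf[basis] <- xb - d * t_max
      xf[q] <- xf[q] + dirn * t_max
      if (leave == 0L) {
        status[q] <- if (status[q] == 0L) 1L else 0L    # flipped bound
      } else {
        p <- basis[leave]
        hit_upper <- d[leave] < 0
        status[p] <- if (hit_upper) 1L else 0L
        xf[p] <- if (hit_upper) ubf[p] else lbf[p]      # snap exactly
        status[q] <- 2L
        basis[leave] <- q
      }
      obj_now <- sum(cvec[basis] * xf[basis]) + sum(cvec[-basis] * xf[-basis])
      if (obj_now > last_obj + tol) {
        stalled <- 0L
        last_obj <- obj_now
      } else {
        stalled <- stalled + 1L
      }
    }
  }

  ## Phase 1: minimize sum of artificials (maximize its negative).
  c1 <- c(rep(0, n), rep(-1, m))
  r1 <- run_phase(c1, basis, status, xf, phase1 = TRUE)
  if (r1$status %in% c("singular", "iteration_limit")) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), detail = paste("phase1", r1$status)))
  }
  art_val <- sum(r1$x[n + seq_len(m)])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  ## Pin all artificials to zero so phase 2 cannot reuse them; basic
  ## artificials at level zero are harmless once their bounds collapse.
  lbf[n + seq_len(m)] <- 0
  ubf[n + seq_len(m)] <- 0
  environment(run_phase)$lbf <- lbf
  environment(run_phase)$ubf <- ubf
  r1$x[n + seq_len(m)] <- 0

  ## Phase 2: user objective, artificials fixed at 0.
  c2 <- c(cc, rep(0, m))
  r2 <- run_phase(c2, r1$basis, r1$vstat, r1$x, phase1 = FALSE)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  if (r2$status %in% c("singular", "iteration_limit")) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), detail = paste("phase2", r2$status)))
  }
  x_out <- r2$x[seq_len(n)]
  x_out <- pmin(pmax(x_out, lb), ub)                    # clean roundoff
  objective <- sum(cc * x_out)
  if (sense == "min") objective <- -objective
  list(status = "optimal", objective = objective, x = x_out)
}
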