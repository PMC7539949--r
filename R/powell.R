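#' Powell's derivative-free conjugate-direction minimizer
#'
#' Minimizes a scalar function of several variables without derivatives by
#' successive line minimizations along a set of directions that is updated
#' towards mutual conjugacy (Powell 1964; the convergence-safeguarded
#' variant that replaces the direction of largest decrease only when the
#' extrapolated point keeps improving).  Box constraints are honoured by
#' restricting each line search to the feasible segment; line minimization
#' uses Brent's method ([stats::optimize()]).  A derivative-free method is
#' appropriate here because the calibration objective is only piecewise
#' smooth (the surface-casting fraction has a kink at the threshold).
#'
#' @param par Numeric start vector (must be finite and within bounds).
#' @param fn Objective function of `par`; must return a finite scalar
#'   (return a large penalty for infeasible inputs).
#' @param lower,upper Bounds, recycled to `length(par)`.
#' @param control List: `maxit` (outer iterations, default 200), `reltol`
#'   (relative decrease tolerance, default 1e-10), `line_tol` (Brent
#'   tolerance, default 1e-8).
#' @return List with `par`, `value`, `counts` (function evaluations),
#'   `iterations` and `convergence` (0 = converged, 1 = maxit reached).
#' @references Powell, M.J.D. (1964) An efficient method for finding the
#'   minimum of a function of several variables without calculating
#'   derivatives. *The Computer Journal* 7, 155-162.
#' @export
powell <- function(par, fn, lower = -Inf, upper = Inf, control = list()) {
  ctrl <- utils::modifyList(list(maxit = 200, reltol = 1e-10,
                                 line_tol = 1e-8), control)
  np <- length(par)
  lower <- rep_len(lower, np)
  upper <- rep_len(upper, np)
  if (any(par < lower) || any(par > upper))
    stop("start point outside bounds", call. = FALSE)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; fn(x) }

  # line minimization from x along direction d within the box
  linmin <- function(x, d, fx) {
    nz <- abs(d) > 0
    if (!any(nz)) return(list(x = x, f = fx, t = 0))
    tlo <- -Inf; thi <- Inf
    for (i in which(nz)) {
      r <- sort(c((lower[i] - x[i]) / d[i], (upper[i] - x[i]) / d[i]))
      tlo <- max(tlo, r[1]); thi <- min(thi, r[2])
    }
    if (!is.finite(tlo)) tlo <- -1e6
    if (!is.finite(thi)) thi <- 1e6
    if (thi <= tlo) return(list(x = x, f = fx, t = 0))
    opt <- stats::optimize(function(t) f(x + t * d), c(tlo, thi),
                           tol = ctrl$line_tol)
    if (opt$objective < fx)
      list(x = x + opt$minimum * d, f = opt$objective, t = opt$minimum)
    else list(x = x, f = fx, t = 0)
  }

  dirs <- diag(np)
  x <- par
  fx <- f(x)
  iter <- 0L
  convergence <- 1L
  while (iter < ctrl$maxit) {
    iter <- iter + 1L
    x0 <- x; f0 <- fx
    biggest <- 0; ibig <- 1L
    for (i in seq_len(np)) {
      fprev <- fx
      lm <- linmin(x, dirs[, i], fx)
      x <- lm$x; fx <- lm$f
      if (fprev - fx > biggest) { biggest <- fprev - fx; ibig <- i }
    }
    if (2 * (f0 - fx) <= ctrl$reltol * (abs(f0) + abs(fx)) + 1e-300) {
      convergence <- 0L
      break
    }
    # extrapolated point along the net displacement of the cycle
    d_new <- x - x0
    xe <- pmin(pmax(2 * x - x0, lower), upper)
    fe <- f(xe)
    if (fe < f0) {
      t1 <- 2 * (f0 - 2 * fx + fe) * (f0 - fx - biggest)^2
      t2 <- biggest * (f0 - fe)^2
      if (t1 < t2 && sum(d_new^2) > 0) {
        lm <- linmin(x, d_new, fx)
        x <- lm$x; fx <- lm$f
        dirs[, ibig] <- dirs[, np]
        dirs[, np] <- d_new / sqrt(sum(d_new^2))
      }
    }
  }
  list(par = x, value = fx, counts = evals, iterations = iter,
       convergence = convergence)
}
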