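# Parameter specifications and the (mu+lambda) self-adaptive evolutionary
# strategy used for global parameter estimation.

#' Build a parameter specification table
#'
#' @param name Parameter names (dotted paths for model parameters).
#' @param low,high Bounds on the natural scale (low < high; low > 0 for
#'   log-scale parameters).
#' @param scale Search scale per parameter: `"log"` (log10), `"linear"` or
#'   `"logit"` (for fractions such as fu).
#' @param status `"free"` or `"fixed"`.
#' @param value Fixed value (inside the bounds) for fixed parameters,
#'   optionally a start value for free ones.
#' @return data.frame of class `parameter_spec`.
#' @export
parameter_spec <- function(name, low, high, scale = "log", status = "free",
                           value = NA_real_) {
  spec <- data.frame(name = name, low = low, high = high, scale = scale,
                     status = status, value = value, stringsAsFactors = FALSE)
  if (any(spec$low >= spec$high)) stop("bounds require low < high", call. = FALSE)
  if (any(spec$scale == "log" & spec$low <= 0)) stop("log-scale parameters need positive bounds", call. = FALSE)
  fx <- spec$status == "fixed"
  if (any(fx & (is.na(spec$value) | spec$value < spec$low | spec$value > spec$high))) {
    stop("fixed values must lie inside the bounds", call. = FALSE)
  }
  class(spec) <- c("parameter_spec", "data.frame")
  spec
}

#' Default bounds and search scale for a model parameter path
#'
#' Rate-like parameters are searched in log10 space, fractions unbound in
#' logit space. Bounds are wide, deliberately spanning several orders of
#' magnitude around the printed parameter tables.
#'
#' @param paths Character vector of dotted parameter paths.
#' @return A [parameter_spec()] with one free row per path.
#' @export
default_bounds <- function(paths) {
  one <- function(p) {
    if (grepl("^bind\\.fu", p)) {
      parameter_spec(p, 0.001, 0.999, scale = "logit")
    } else if (grepl("^transport\\.kappa", p)) {
      parameter_spec(p, 1e-3, 1e4, scale = "log") # uL/min
    } else if (grepl("^hyd\\.k_pon", p)) {
      parameter_spec(p, 1e-5, 10, scale = "log")
    } else if (grepl("^betaox\\.", p)) {
      parameter_spec(p, 1e-6, 1, scale = "log")
    } else if (grepl("rmax", p)) {
      parameter_spec(p, 1, 1e5, scale = "log")
    } else if (grepl("km|\\.ki$", p)) {
      parameter_spec(p, 10, 1e6, scale = "log")
    } else {
      parameter_spec(p, 1e-6, 1e6, scale = "log")
    }
  }
  do.call(rbind, lapply(paths, one))
}

# transforms between the natural scale and the search scale
.to_search <- function(x, spec) {
  z <- numeric(length(x))
  for (i in seq_along(x)) {
    z[i] <- switch(spec$scale[i],
      log = log10(x[i]),
      logit = stats::qlogis((x[i] - spec$low[i]) / (spec$high[i] - spec$low[i])),
      linear = x[i])
  }
  z
}

.from_search <- function(z, spec) {
  x <- numeric(length(z))
  for (i in seq_along(z)) {
    x[i] <- switch(spec$scale[i],
      log = 10^z[i],
      logit = spec$low[i] + (spec$high[i] - spec$low[i]) * stats::plogis(z[i]),
      linear = z[i])
  }
  stats::setNames(x, spec$name)
}

.search_bounds <- function(spec) {
  lo <- hi <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (spec$scale[i] == "log") {
      lo[i] <- log10(spec$low[i]); hi[i] <- log10(spec$high[i])
    } else if (spec$scale[i] == "logit") {
      lo[i] <- -13.8; hi[i] <- 13.8 # plogis saturates to ~1e-6 resolution
    } else {
      lo[i] <- spec$low[i]; hi[i] <- spec$high[i]
    }
  }
  list(lo = lo, hi = hi)
}

.reflect <- function(z, lo, hi) {
  r <- hi - lo
  z <- (z - lo) %% (2 * r)
  lo + ifelse(z > r, 2 * r - z, z)
}

#' (mu+lambda) self-adaptive evolutionary strategy
#'
#' Global minimization of a boxed objective with a plus-selection evolution
#' strategy (defaults mu = 8 parents, lambda = 4 offspring per generation; a
#' plus strategy because lambda < mu is unviable under comma selection).
#' Mutation is Gaussian on the declared search scale with per-coordinate
#' log-normally self-adapted step sizes. Deterministic given `seed`.
#'
#' @param fn Objective: takes a named numeric vector on the natural scale,
#'   returns a scalar to minimize.
#' @param specs A [parameter_spec()]; only `status == "free"` rows are searched.
#' @param mu,lambda Parent and offspring population sizes.
#' @param seed Integer seed (RNG state is restored on exit).
#' @param budget Maximum number of objective evaluations.
#' @param sigma0 Initial step size as a fraction of the search-scale range.
#' @param init Optional named start vector (natural scale) seeding one parent.
#' @return Object of class `fit_result`: `par` (named, natural scale),
#'   `value`, `evals`, `seed`, `trace` (best value per generation), `mu`,
#'   `lambda`.
#' @export
es_optimize <- function(fn, specs, mu = 8, lambda = 4, seed = 1,
                        budget = 2000, sigma0 = 0.25, init = NULL) {
  free <- specs[specs$status == "free", , drop = FALSE]
  if (nrow(free) == 0) stop("no free parameters to optimize", call. = FALSE)
  if (budget <= 0) stop("budget must be positive", call. = FALSE)
  n <- nrow(free)
  b <- .search_bounds(free)
  tau_g <- 1 / sqrt(2 * n)
  tau_l <- 1 / sqrt(2 * sqrt(n))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  evals <- 0L
  eval_fn <- function(z) {
    evals <<- evals + 1L
    fn(.from_search(z, free))
  }

  pop_z <- matrix(stats::runif(mu * n, b$lo, b$hi), nrow = mu, byrow = TRUE)
  if (!is.null(init)) {
    zi <- .to_search(init[free$name], free)
    if (!anyNA(zi)) pop_z[1, ] <- pmin(pmax(zi, b$lo), b$hi)
  }
  pop_s <- matrix(sigma0 * (b$hi - b$lo), nrow = mu, ncol = n, byrow = TRUE)
  pop_f <- apply(pop_z, 1, eval_fn)

  trace <- min(pop_f)
  while (evals + lambda <= budget) {
    ch_z <- matrix(0, lambda, n); ch_s <- matrix(0, lambda, n)
    ch_f <- numeric(lambda)
    for (k in seq_len(lambda)) {
      i <- sample.int(mu, 1)
      s <- pop_s[i, ] * exp(tau_g * stats::rnorm(1) + tau_l * stats::rnorm(n))
      s <- pmin(pmax(s, 1e-8), b$hi - b$lo)
      z <- .reflect(pop_z[i, ] + s * stats::rnorm(n), b$lo, b$hi)
      ch_z[k, ] <- z; ch_s[k, ] <- s
      ch_f[k] <- eval_fn(z)
    }
    all_z <- rbind(pop_z, ch_z); all_s <- rbind(pop_s, ch_s)
    all_f <- c(pop_f, ch_f)
    keep <- order(all_f)[seq_len(mu)]
    pop_z <- all_z[keep, , drop = FALSE]
    pop_s <- all_s[keep, , drop = FALSE]
    pop_f <- all_f[keep]
    trace <- c(trace, pop_f[1])
  }

  best <- which.min(pop_f)
  structure(list(par = .from_search(pop_z[best, ], free),
                 value = pop_f[best], evals = evals, seed = seed,
                 trace = trace, mu = mu, lambda = lambda),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: J* =", format(x$value, digits = 6),
      "after", x$evals, "evaluations (seed", paste0(x$seed, ")"), "\n")
  print(signif(x$par, 4))
  invisible(x)
}

#' Local polish of an optimizer result on the search scale
#'
#' Bounded quasi-Newton (L-BFGS-B) refinement of a [es_optimize()] result,
#' run on the same transformed scale, followed by a short Nelder-Mead sweep;
#' the better of the refined and original points is kept. The weighted
#' least-squares surface is smooth in the search coordinates, which is what
#' makes the local step effective after the global ES.
#'
#' @param fn,specs As in [es_optimize()].
#' @param result A `fit_result`.
#' @param maxit Iteration cap per `stats::optim` stage.
#' @return An updated `fit_result`.
#' @export
polish_fit <- function(fn, specs, result, maxit = 500) {
  free <- specs[specs$status == "free", , drop = FALSE]
  b <- .search_bounds(free)
  fz <- function(z) fn(.from_search(pmin(pmax(z, b$lo), b$hi), free))
  z <- .to_search(result$par[free$name], free)
  value <- result$value
  extra <- 0L
  for (stage in c("L-BFGS-B", "Nelder-Mead", "L-BFGS-B")) {
    opt <- if (stage == "L-BFGS-B") {
      tryCatch(stats::optim(z, fz, method = "L-BFGS-B", lower = b$lo, upper = b$hi,
                            control = list(maxit = maxit)),
               error = function(e) NULL)
    } else {
      stats::optim(z, fz, method = "Nelder-Mead", control = list(maxit = maxit))
    }
    if (is.null(opt)) next
    extra <- extra + opt$counts[["function"]]
    if (opt$value < value) {
      z <- pmin(pmax(opt$par, b$lo), b$hi)
      value <- opt$value
    }
  }
  if (value < result$value) {
    result$par <- .from_search(z, free)
    result$value <- value
  }
  result$evals <- result$evals + extra
  result
}
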