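#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar positivity check with a hard error naming the offending argument
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite", name),
         call. = FALSE)
  }
  invisible(x)
}

ptosis_levels <- c(0, 1, 2, 2.5, 3)

check_ptosis <- function(g, name = "ptosis_grade") {
  bad <- !is.na(g) & !(g %in% ptosis_levels)
  if (any(bad)) {
    stop(sprintf("`%s` must be one of {%s}; got: %s", name,
                 paste(ptosis_levels, collapse = ", "),
                 paste(unique(g[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(g)
}

# Moments of a normal(mu, sigma) truncated to [a, b]
tn_moments <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- pnorm(beta) - pnorm(alpha)
  lambda <- (dnorm(alpha) - dnorm(beta)) / z
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + (alpha * dnorm(alpha) - beta * dnorm(beta)) / z -
                    lambda^2)
  c(mean = unname(m), sd = unname(sqrt(pmax(v, 0))))
}

# Solve for the underlying (mu, sigma) whose [a, b]-truncation has the
# requested mean and sd (moment matching, so sampled marginals hit their
# targets despite truncation).
tn_solve <- function(mean, sd, a, b) {
  if (!is.finite(a) || !is.finite(b) || a >= b) {
    stop("infeasible truncation range: min must be < max", call. = FALSE)
  }
  if (mean <= a || mean >= b) {
    stop("target mean must lie inside the truncation range", call. = FALSE)
  }
  obj <- function(par) {
    mm <- tn_moments(par[1], exp(par[2]), a, b)
    ((mm["mean"] - mean) / sd)^2 + ((mm["sd"] - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), a = a, b = b)
}

# Truncated-normal quantile from a uniform u, used to transform copula draws
tn_quantile <- function(u, pars) {
  pa <- pnorm(pars$a, pars$mu, pars$sigma)
  pb <- pnorm(pars$b, pars$mu, pars$sigma)
  qnorm(pa + u * (pb - pa), pars$mu, pars$sigma)
}
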