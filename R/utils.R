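#' @importFrom rlang %||% abort
#' @importFrom stats qnorm pnorm qlnorm plnorm rnorm runif rbinom setNames
#' @importFrom stats kruskal.test t.test wilcox.test qt sd quantile uniroot
#' @useDynLib imatpbpk
NULL

# run expr with a local, restored RNG state seeded deterministically
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-subject substream seed (counter scheme; < 2^31)
subject_seed <- function(root, trial, subject) {
  root <- as.double(root %% 2147483647L)
  ((root * 1000003 + trial * 10007 + subject * 101) %% 2147483629) + 1
}

stop_config <- function(msg) abort(msg, class = "imatpbpk_config_error")
stop_domain <- function(msg) abort(msg, class = "imatpbpk_domain_error")
stop_validation <- function(msg) abort(msg, class = "imatpbpk_validation_error")

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_validation(sprintf("field '%s' must be strictly positive", name))
  }
  invisible(x)
}

check_fraction <- function(x, name, closed_upper = FALSE) {
  hi_ok <- if (closed_upper) all(x <= 1) else all(x < 1)
  if (any(!is.finite(x)) || any(x <= 0) || !hi_ok) {
    stop_validation(sprintf(
      "field '%s' must lie in (0, 1%s", name, if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

# mean/cv parameterisation of a log-normal
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# quantile transform for a truncated log-normal; u in (0,1)
qlnorm_trunc <- function(u, mean, cv, lo = 0, hi = Inf) {
  pp <- lnorm_pars(mean, cv)
  p_lo <- if (lo <= 0) 0 else plnorm(lo, pp$meanlog, pp$sdlog)
  p_hi <- if (is.infinite(hi)) 1 else plnorm(hi, pp$meanlog, pp$sdlog)
  qlnorm(p_lo + u * (p_hi - p_lo), pp$meanlog, pp$sdlog)
}

rlnorm_trunc <- function(n, mean, cv, lo = 0, hi = Inf) {
  qlnorm_trunc(runif(n), mean, cv, lo, hi)
}

# truncated normal via inverse CDF
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

uM_to_mgL <- function(x_uM, mw) x_uM * mw / 1000
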