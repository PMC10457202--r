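# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (and the survival/glmnet fitters) so they can
# serve as cross-checks.

# Efron partial log-likelihood for a single covariate, evaluated directly
# from its definition; used to grid/optimise-check Cox coefficients.
efron_loglik <- function(b, x, time, event) {
  eta <- x * b
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumR <- sum(w[R])
    sumD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in 0:(d - 1)) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

efron_mle <- function(x, time, event, interval = c(-10, 10)) {
  stats::optimize(function(b) efron_loglik(b, x, time, event),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# tiny beta matrix builder
make_beta <- function(values, cpgs = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cpgs %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulation config for fast unit tests (identical structure to the
# study-scale default, just fewer null CpGs)
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_cpgs = 1000L, n_drift_hyper = 30L, n_drift_hypo = 3L,
         n_age_cpgs = 20L, n_comp_cpgs = 20L, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}
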