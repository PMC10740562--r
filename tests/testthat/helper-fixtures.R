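# Shared fixtures: small synthetic protocols/kinetics and a numerical
# gradient checker used by the nn tests.

tiny_adenosine <- function(ladder = c(1e-6, 1e-5)) {
  sensing_protocol("adenosine35", concentration_ladder = ladder)
}

quiet_kinetics <- function(seed = 1L, ...) {
  kinetics_params(noise_sd = 0, drift_slope = 0, spike_amplitude = 0, seed = seed, ...)
}

# central finite differences of scalar f(params) wrt every leaf of params
numeric_grad <- function(f, params, h = 1e-5) {
  leaves <- list()
  collect <- function(p, path) {
    if (is.list(p)) {
      for (k in seq_along(p)) collect(p[[k]], c(path, k))
    } else {
      leaves[[length(leaves) + 1L]] <<- path
    }
  }
  collect(params, integer(0))
  out <- params
  for (path in leaves) {
    leaf <- params[[path]]
    g <- leaf * 0
    for (i in seq_along(leaf)) {
      pp <- params
      leaf2 <- leaf; leaf2[i] <- leaf2[i] + h
      pp[[path]] <- leaf2
      fp <- f(pp)
      leaf2[i] <- leaf[i] - h
      pp[[path]] <- leaf2
      fm <- f(pp)
      g[i] <- (fp - fm) / (2 * h)
    }
    out[[path]] <- g
  }
  out
}

unlist_params <- function(p) {
  if (is.list(p)) unlist(lapply(p, unlist_params), use.names = FALSE) else as.vector(p)
}

max_rel_err <- function(a, b) {
  va <- unlist_params(a); vb <- unlist_params(b)
  max(abs(va - vb) / pmax(abs(va) + abs(vb), 1e-4))
}

# compare analytic gradients to finite differences at a random subset of
# coordinates per leaf (full sweeps are too slow for the larger models)
check_grad_subset <- function(f, params, analytic, k = 4L, h = 1e-4) {
  worst <- 0
  walk <- function(path) {
    leaf <- params[[path]]
    an <- analytic[[path]]
    idx <- sample(seq_along(leaf), min(k, length(leaf)))
    for (i in idx) {
      pp <- params
      leaf2 <- leaf; leaf2[i] <- leaf2[i] + h
      pp[[path]] <- leaf2
      fp <- f(pp)
      leaf2[i] <- leaf[i] - h
      pp[[path]] <- leaf2
      fm <- f(pp)
      fd <- (fp - fm) / (2 * h)
      rel <- abs(fd - an[i]) / max(abs(fd) + abs(an[i]), 1e-3)
      worst <<- max(worst, rel)
    }
  }
  paths <- list()
  collect <- function(p, path) {
    if (is.list(p)) for (j in seq_along(p)) collect(p[[j]], c(path, j))
    else paths[[length(paths) + 1L]] <<- path
  }
  collect(params, integer(0))
  for (path in paths) walk(path)
  worst
}
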