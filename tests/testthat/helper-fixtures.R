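# Shared fixtures: tiny configurations and cached pipeline runs.

tiny_config <- function(..., seed = 42) {
  simulation_config(
    n_events_per_class = c(SE = 2, A5SS = 2, A3SS = 3, RI = 2, MXE = 2),
    seed = seed, ...
  )
}

# cache expensive preset runs within one test session
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(preset, n_events = 500, seed = 1,
                       thresholds = threshold_preset()) {
  key <- paste(preset, n_events, seed, thresholds$name, sep = "|")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(
      sim_preset(preset, n_events = n_events, seed = seed),
      thresholds = thresholds)
  }
  .run_cache[[key]]
}

# independent naive BH step-up (oracle)
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# independent exact Mann-Whitney oracle: enumerate group assignments and
# compute U by directly counting pairs (x > y) + 0.5 * ties
naive_exact_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_count <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  eu <- n * length(y) / 2
  obs <- abs(u_count(x, y) - eu)
  idx <- utils::combn(length(pooled), n)
  devs <- apply(idx, 2, function(i) {
    abs(u_count(pooled[i], pooled[-i]) - eu)
  })
  mean(devs >= obs - 1e-9)
}

# simple synthetic clinical table with a planted 3-group structure
planted_pheno <- function(n_per_group = 8, noise_features = 2, seed = 99) {
  withr::with_seed(seed, {
    groups <- rep(1:3, each = n_per_group)
    archetype <- rbind(
      c(1, 1, 1, 0, 0, 0),
      c(0, 0, 0, 1, 1, 1),
      c(1, 0, 1, 0, 1, 0)
    )
    m <- archetype[groups, ]
    noise <- matrix(sample(c(0, 0.5, 1), length(groups) * noise_features,
                           replace = TRUE),
                    nrow = length(groups))
    tbl <- cbind(m, noise)
    colnames(tbl) <- paste0("f", seq_len(ncol(tbl)))
    out <- tibble::as_tibble(tbl)
    out$patient <- sprintf("P%02d", seq_along(groups))
    out <- out[, c("patient", paste0("f", seq_len(ncol(tbl))))]
    class(out) <- c("pheno_matrix", class(out))
    list(encoded = out, groups = groups)
  })
}
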