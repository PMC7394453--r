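# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# A small single-blip subject on a 32^3 grid, smooth field.
small_subject <- function() {
  fixture("small_subject", function() {
    p <- phantom_params(shape = 32, seed = 7, n_hotspots = 0)
    simulate_subject(p, pe_axis = 2, readout = 0.05, n_blips = 1)
  })
}

# A small dual-blip subject on the same grid.
small_subject2 <- function() {
  fixture("small_subject2", function() {
    p <- phantom_params(shape = 32, seed = 8, n_hotspots = 0)
    simulate_subject(p, pe_axis = 2, readout = 0.05, n_blips = 2)
  })
}

# Cheap content fingerprint for identity/distinctness checks.
digest_vol <- function(x) paste(sum(x), sum(x^2), stats::sd(x), sep = "|")

# Tiny prepared samples with random (non-image) content for training-loop
# tests: valid gradients, fast epochs.  Grid 8^3 suits a 2-level U-Net.
toy_preps <- function(n = 6, gd = c(8L, 8L, 8L), seed = 3) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      V <- prod(gd)
      t1 <- stats::rnorm(V)
      truth <- 0.6 * t1 + 0.1 * stats::rnorm(V)
      blips <- if (i %% 2 == 0) list(truth + 0.3 * stats::rnorm(V),
                                     truth + 0.3 * stats::rnorm(V))
               else list(truth + 0.3 * stats::rnorm(V))
      list(subject = sprintf("toy-%02d", i), gd = gd, t1 = t1,
           blips = blips, truth = truth,
           mask = rep(TRUE, V), norm = list(p99 = 1),
           pe = list(pe_spec(2, 1, 0.05)))
    })
  })
}
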