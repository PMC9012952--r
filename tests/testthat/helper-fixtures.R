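# Shared fixtures: small random tensors and a cached small simulation.

rand_tensor <- function(V, T, K, seed = 1) {
  set.seed(seed)
  array(rnorm(V * T * K), dim = c(V, T, K))
}

# Small, fast simulation spec for unit tests.
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_sources = 3L, grid = c(14L, 14L), n_timepoints = 40L,
         n_subjects = 4L, snr_db = Inf, seed = 7L),
    list(...))
  do.call(fmri_sim_spec, args)
}

# Memoized expensive fixtures, shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, maker(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_sim <- function() fixture("tiny_sim", function() simulate_fmri(tiny_spec()))

tiny_fit <- function() fixture("tiny_fit", function() {
  slctkd(tiny_sim()$X, order = 3,
         control = slctkd_control(iter_max = 60))
})

# Independent triple-loop oracle for the mode-n product.
mode_product_oracle <- function(x, m, mode) {
  d <- dim(x)
  nd <- d; nd[mode] <- nrow(m)
  out <- array(0, dim = nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    s <- 0
    for (q in seq_len(d[mode])) {
      s <- s + switch(mode,
                      m[i, q] * x[q, j, k],
                      m[j, q] * x[i, q, k],
                      m[k, q] * x[i, j, q])
    }
    out[i, j, k] <- s
  }
  out
}

# Rand index between two labelings.
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sa <- sum(choose(tab, 2)); rb <- sum(choose(rowSums(tab), 2))
  cb <- sum(choose(colSums(tab), 2)); tot <- choose(n, 2)
  (tot + 2 * sa - rb - cb) / tot
}
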