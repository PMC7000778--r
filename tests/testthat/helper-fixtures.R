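# Shared simulated fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# default asymmetric session, noiseless (ground-truth oracle work)
default_session_noiseless <- function() {
  fixture("default_noiseless", function() {
    p <- slip_params(n_strides = 10, noise_sigma_force = 0,
                     noise_sigma_marker = 0, seed = 1)
    ses <- generate_session(p)
    list(params = p, ses = ses, fit = analyze_session(ses))
  })
}

# default asymmetric session with sensor noise
default_session_noisy <- function() {
  fixture("default_noisy", function() {
    p <- slip_params(n_strides = 10, seed = 42)
    ses <- generate_session(p)
    list(params = p, ses = ses, fit = analyze_session(ses))
  })
}

# symmetric-leg session builder
symmetric_session <- function(k, alpha = 0.55, n_strides = 8, seed = 1,
                              noise = 0) {
  p <- slip_params(k = c(AL = k, UL = k),
                   alpha = c(AL = alpha, UL = alpha),
                   L0 = c(AL = 1, UL = 1), n_strides = n_strides,
                   noise_sigma_force = noise, noise_sigma_marker = 0,
                   seed = seed)
  generate_session(p)
}

# analytic half-sine fixture constants used across signal tests
halfsine <- list(peak = 1500, duration = 0.12, rate = 1000, pad = 0.1,
                 threshold = 30)
halfsine_crossings <- function(h = halfsine) {
  t1 <- (h$duration / pi) * asin(h$threshold / h$peak)
  c(on = h$pad + t1, off = h$pad + h$duration - t1)
}
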