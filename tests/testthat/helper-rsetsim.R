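# shared fixtures: small ensembles built in code

homog_ensemble <- function(N = 8, seed = 1) {
  sample_ensemble(N, heterogeneity_spec(delta = 0), seed = seed)
}

heterog_ensemble <- function(N = 8, delta = 0.25, seed = 1) {
  sample_ensemble(N, heterogeneity_spec(delta = delta), seed = seed)
}

# a spike train built directly from event times (list of numeric vectors)
make_train <- function(times, duration) {
  ev <- data.frame(
    member = rep(seq_along(times), lengths(times)),
    time = unlist(times, use.names = FALSE)
  )
  as_spike_train(ev, duration = duration, N = length(times))
}

E_CHARGE <- rset_constants()$e
DEFAULT_VTH <- E_CHARGE / 2  # threshold of the 1 aF reference island
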