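# Shared fixtures, built in code.

small_spec <- function(seed = 7, ...) {
  session_spec(
    regions = list(A = c(integration = 3, interneuron = 2,
                         unresponsive = 3)),
    seed = seed, ...
  )
}

small_session <- function(seed = 7, ...) {
  simulate_spike_session(small_spec(seed = seed, ...))
}

# hand-rolled spike_data with explicit spike times
manual_spikes <- function(times_list, region = "A") {
  units <- data.frame(unit_id = names(times_list), region = region,
                      stringsAsFactors = FALSE)
  spike_data(units, times_list)
}
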