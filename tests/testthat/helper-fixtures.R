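# Shared small fixtures, built in code.  The small emulator configuration
# trades slice count for speed; dynamics are unchanged.

small_config <- function(...) emulator_config(n_slices = 30L, ...)

# cached small dataset for surrogate-level tests
small_dataset <- local({
  cache <- NULL
  function(n = 48L, seed = 4L) {
    if (is.null(cache)) cache <<- generate_dataset(n = n, config = small_config(), seed = seed)
    cache
  }
})

midpoint_params <- function(space = isr_parameter_space()) (space$mins + space$maxs) / 2
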