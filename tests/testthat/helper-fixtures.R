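# Shared fixtures: base inputs and a small grid of convention combinations.
base_params <- function(...) cea_parameters(...)

convention_grid <- function() {
  grid <- expand.grid(
    entry = c("all-treated", "fn-diseased", "positives-decrement"),
    resolution = c("tunnel", "persistent"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    cea_conventions(entry = grid$entry[i], resolution = grid$resolution[i])
  })
}
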