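# Memoised canonical runs shared across test files (each takes tens of
# seconds; several tests interrogate the same result).
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (!exists(key, envir = .run_cache)) {
    assign(key, simulate_artery(canned_case(name, ...)), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
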