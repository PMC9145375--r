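# Classed conditions so callers (and the CLI) can map failures to categories.

abort_meshfair <- function(message, class) {
  stop(structure(
    class = c(paste0("meshfair_", class, "_error"), "meshfair_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_usage     <- function(message) abort_meshfair(message, "usage")
abort_io        <- function(message) abort_meshfair(message, "io")
abort_geometry  <- function(message) abort_meshfair(message, "geometry")
abort_numerical <- function(message) abort_meshfair(message, "numerical")
abort_topology  <- function(message) abort_meshfair(message, "topology")
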