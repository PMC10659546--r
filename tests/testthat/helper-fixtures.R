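# Shared fixtures built in code.

# The 15-epoch worked example: y = (a,a,a,r,r,a,r,a,a,a,r,r,a,r,r)
example_sequence <- function() {
  state_series(c("a", "a", "a", "r", "r", "a", "r", "a", "a", "a",
                 "r", "r", "a", "r", "r"))
}

# Random binary state series with both states present.
random_states <- function(T_len, p_active = 0.5) {
  repeat {
    s <- ifelse(stats::runif(T_len) < p_active, "a", "r")
    if (length(unique(s)) == 2L) return(state_series(s))
  }
}
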