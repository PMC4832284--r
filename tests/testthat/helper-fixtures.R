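# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

default_params <- function() {
  if (is.null(.fixtures$params)) .fixtures$params <- scrf_params()
  .fixtures$params
}

# 60 s @ 10 Hz dictionary (701 atoms), reused across files
dict60 <- function() {
  if (is.null(.fixtures$dict60))
    .fixtures$dict60 <- build_dictionary(600, 10, default_params())
  .fixtures$dict60
}

# small dictionary for brute-force comparisons: 30 s @ 10 Hz, thinned to
# n_atoms evenly spaced onsets (base dictionary cached, thinning is cheap)
small_dict <- function(n_atoms = 40) {
  if (is.null(.fixtures$base300))
    .fixtures$base300 <- build_dictionary(300, 10, default_params())
  d <- .fixtures$base300
  idx <- round(seq(1, length(d$onsets), length.out = n_atoms))
  d$onsets <- d$onsets[idx]
  d$atoms <- d$atoms[, idx, drop = FALSE]
  d$norms <- d$norms[idx]
  d
}
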