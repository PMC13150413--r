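# Frame-wise parallel map with order-preserving reduction.
#
# Analyses apply a pure function to each frame index and combine results
# in frame order, so the output is identical for any worker count
# (including 1). Forked workers are used where available; on platforms
# without fork support the map silently runs serially.
frame_map <- function(indices, fn, n_workers = 1) {
  n_workers <- max(1L, as.integer(n_workers))
  if (n_workers == 1L || .Platform$OS.type == "windows") {
    lapply(indices, fn)
  } else {
    out <- parallel::mclapply(indices, fn, mc.cores = n_workers,
                              mc.preschedule = TRUE)
    err <- vapply(out, inherits, logical(1), "try-error")
    if (any(err)) stop(attr(out[[which(err)[1]]], "condition")$message)
    out
  }
}
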