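`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ecoscan <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# row-wise minimum ignoring NA; all-NA rows give NA
row_mins <- function(m) {
  out <- do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
  out[!is.finite(out)] <- NA_real_
  as.numeric(out)
}

is_whole <- function(x) is.finite(x) & abs(x - round(x)) < 1e-8
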