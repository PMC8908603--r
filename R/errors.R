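#' @keywords internal
#' Signal a classed cmrlv error.
#'
#' All package errors inherit from "cmrlv_error" plus a specific class so
#' callers can branch on the failure mode (degenerate geometry, bad data, ...).
#' @noRd
cmr_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cmrlv_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) cmr_stop("domain_error", "cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
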