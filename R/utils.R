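# shared small helpers

.parse_utc <- function(x, context = "input") {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  t <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], format = f, tz = "UTC"), tz = "UTC")
  }
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop("unparseable timestamp in ", context, " at row ", bad, ": '", x[bad], "'")
  }
  t
}

# wrap angles into (-pi, pi]
.wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

# deterministic 31-bit child seed from a master seed and a string label
.child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (31^(seq_along(utf8ToInt(label)) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
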