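#' @keywords internal
"_PACKAGE"

# shared argument checks -------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  as.numeric(x)
}

# ISO-8601-tolerant timestamp parsing ("T" separator and trailing "Z")
parse_time <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = tz,
             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"))
}

# adjusted R2 from residual and total sums of squares, p predictors
# (intercept excluded from p), n observations
adj_r2 <- function(sse, tss, n, p) {
  r2 <- 1 - sse / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}
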