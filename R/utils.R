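# internal helpers shared across modules

# great-circle distance matrix in km from lon/lat columns
haversineKm <- function(lon, lat) {
  pts <- cbind(lon, lat)
  m <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  dimnames(m) <- NULL
  m
}

# derive a reproducible child seed (< 2^31) from a parent seed and a tag
childSeed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(as.character(tag))) * 10007L) %% 2147483647L
}

# standardize columns of a numeric data.frame/matrix (zero-variance kept as 0)
standardizeCols <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
}

stopifnotMsg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
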