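# Internal helpers: geometry, classed conditions, seeded RNG, checksums.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(NULL)
  v / n
}

#' @noRd
# Angle between two vectors in degrees, clamped against acos domain error.
angle_deg <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about an arbitrary unit axis, angle in degrees.
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# --- classed conditions -----------------------------------------------------
# usage errors exit the CLI with 1, data/contract errors with 2.

stop_usage <- function(msg, ...) {
  stop(structure(class = c("rls_usage_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("rls_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# --- RNG isolation ----------------------------------------------------------
# Run expr under a given seed without disturbing the caller's RNG stream.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- checksum ---------------------------------------------------------------
# Adler-32 over the bytes of a character string; plain-R modular arithmetic
# (values stay far below 2^53).  Used to detect model-archive corruption.

rls_checksum <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  a <- 1; b <- 0
  # process in chunks so the modulo is taken before doubles lose precision
  n <- length(bytes)
  i <- 1
  while (i <= n) {
    j <- min(n, i + 3000L)
    for (k in i:j) {
      a <- a + bytes[k]
      b <- b + a
    }
    a <- a %% 65521
    b <- b %% 65521
    i <- j + 1L
  }
  sprintf("%04x%04x", as.integer(b), as.integer(a))
}
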