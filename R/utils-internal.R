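# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() rounds half to even).
roundHalfUp <- function(x) trunc(x + sign(x) * 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Vectorized HSV -> RGB, h in degrees, s and v in [0, 1]; returns n x 3 in [0, 1].
hsv2rgbMat <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r, g, b)
}

# Condition error constructors so callers can distinguish failure modes.
pgError <- function(class, message, ...) {
  stop(structure(class = c(class, "pgError", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

stopIfNot8bitRGB <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an RGB image array (height x width x 3)")
  invisible(d)
}
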