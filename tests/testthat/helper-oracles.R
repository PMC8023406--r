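# Independent oracles, written without reference to the package internals.

# scalar ray-casting point-in-polygon (open boundary; used off-boundary only)
rayCastPoint <- function(x, y, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((verts[i, 2] > y) != (verts[j, 2] > y)) &&
        (x < (verts[j, 1] - verts[i, 1]) * (y - verts[i, 2]) /
           (verts[j, 2] - verts[i, 2]) + verts[i, 1]))
      inside <- !inside
    j <- i
  }
  inside
}

# brute-force inverse Simpson on a probability vector
bruteD2 <- function(p) {
  s <- 0
  for (v in p) s <- s + v * v
  1 / s
}

# brute-force Shannon entropy
bruteShannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

randProb <- function(len) {
  p <- rexp(len)
  p / sum(p)
}
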