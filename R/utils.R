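## Internal helpers: seeded evaluation, seed substreams, polygon geometry.

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG state is restored afterwards. NULL seed = use current stream.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a reproducible per-stage/per-sample seed below 2^31 from a base
## seed and an index (LCG step keeps streams well separated).
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k) %% 2147483647)
}

## Point-in-polygon with closed boundary: returns list(inside, boundary).
## `inside` is the even-odd crossing test; `boundary` flags points within
## `eps` of any edge (these count as inside under the closed convention).
.pipRaw <- function(px, py, verts, eps = 1e-9) {
  n <- nrow(verts)
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
      d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
    } else {
      d2 <- (px - xi)^2 + (py - yi)^2
    }
    onb <- onb | d2 <= eps * eps
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  list(inside = inside, boundary = onb)
}

.pointsInPolygon <- function(px, py, verts, eps = 1e-9) {
  r <- .pipRaw(px, py, verts, eps)
  r$inside | r$boundary
}

## Proper intersection test for two segments (shared endpoints excluded).
.segsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

## A polygon is simple if no two non-adjacent edges properly intersect.
.polygonIsSimple <- function(verts) {
  n <- nrow(verts)
  if (n < 3) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (share a vertex)
      if (b == a + 1 || (a == 1 && b == n)) next
      if (.segsIntersect(verts[edges[a, 1], ], verts[edges[a, 2], ],
                         verts[edges[b, 1], ], verts[edges[b, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}
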