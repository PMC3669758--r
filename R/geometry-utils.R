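# Small vector helpers shared by the mesh and sweep code. All coordinates are
# micrometres; vectors are length-3 numerics, point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) nm_geometry_error("cannot normalize a near-zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic vector orthogonal to u
orthogonal_vector <- function(u) {
  u <- vunit(u)
  ref <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) {
    c(1, 0, 0)
  } else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  vunit(vcross(u, ref))
}

# rotate v by the rotation that maps unit vector a onto unit vector b
# (Rodrigues); identity when a ~ b, 180-degree flip handled explicitly.
rotate_between <- function(v, a, b) {
  axis <- vcross(a, b)
  s <- vnorm(axis)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(v)
    # antiparallel: rotate pi about any axis orthogonal to a
    k <- orthogonal_vector(a)
    return(2 * sum(v * k) * k - v)
  }
  k <- axis / s
  v * cth + vcross(k, v) * s + k * sum(k * v) * (1 - cth)
}

rowwise_norm <- function(m) sqrt(rowSums(m * m))
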