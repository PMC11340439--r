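# Irreducible-representation machinery.
#
# A geometric tensor is stored as a plain numeric matrix (rows = nodes
# or edges) whose columns are grouped into irrep blocks. A block of
# multiplicity m and order l occupies m*(2l+1) consecutive columns,
# multiplicity-major (the 2l+1 components of one copy are contiguous).
# Real spherical harmonics use the component order m = -l..l, i.e.
# (y, z, x) for l = 1, and are scaled so each order has unit norm on
# unit input.
#
# The coupling coefficients of the weighted tensor product are computed
# at load time by spherical quadrature of triple products of real
# spherical harmonics (the Gaunt tensor, normalised to unit Frobenius
# norm per path). Every path used by the architecture has l1+l2+l3 even,
# where this tensor spans the unique equivariant coupling; quadrature on
# a Gauss-Legendre x equispaced-azimuth product grid is exact for the
# band limit involved.

#' Construct an irreps layout
#'
#' @param spec either a string like `"64x0e+32x1o+8x2e"` (multiplicity,
#'   order l, parity e/o) or a data frame with columns `mult`, `l`,
#'   `parity` (+1 even / -1 odd).
#' @return an `eqshift_irreps` object: a data frame with columns `mult`,
#'   `l`, `parity`, `dim`, `offset` (0-based column offset of the
#'   block).
#' @examples
#' irreps("8x0e+4x1o+2x2e")
#' @export
irreps <- function(spec) {
  if (is.character(spec)) {
    parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([0-9]+)x([0-9]+)([eo])$",
                                   trimws(parts)))
    if (any(vapply(m, length, integer(1)) != 4)) {
      stop("cannot parse irreps spec: ", spec)
    }
    df <- data.frame(
      mult = vapply(m, function(x) as.integer(x[2]), integer(1)),
      l = vapply(m, function(x) as.integer(x[3]), integer(1)),
      parity = vapply(m, function(x) if (x[4] == "e") 1L else -1L,
                      integer(1))
    )
  } else {
    df <- as.data.frame(spec)[, c("mult", "l", "parity")]
  }
  stopifnot(all(df$mult >= 1), all(df$l >= 0),
            all(df$parity %in% c(-1L, 1L)))
  df$dim <- df$mult * (2L * df$l + 1L)
  df$offset <- cumsum(c(0L, df$dim))[seq_len(nrow(df))]
  structure(df, class = c("eqshift_irreps", "data.frame"))
}

irreps_dim <- function(ir) sum(ir$dim)

irreps_label <- function(ir) {
  paste(sprintf("%dx%d%s", ir$mult, ir$l,
                ifelse(ir$parity == 1L, "e", "o")), collapse = "+")
}

#' @export
print.eqshift_irreps <- function(x, ...) {
  cat("<irreps ", irreps_label(x), " (dim ", irreps_dim(x), ")>\n",
      sep = "")
  invisible(x)
}

# Columns (1-based) of block b in a layout.
irreps_block_cols <- function(ir, b) {
  ir$offset[b] + seq_len(ir$dim[b])
}

# ---- real spherical harmonics ----------------------------------------

#' Real spherical harmonics of unit directions
#'
#' Evaluates real spherical harmonics up to `l_max` on rows of `vecs`,
#' scaled so that each order l contributes a unit-norm (2l+1)-vector for
#' unit-norm input. Component order within order l is m = -l..l; for
#' l = 1 this is (y, z, x). Parity of order l is (-1)^l.
#'
#' @param vecs n x 3 matrix of unit vectors (a single vector is
#'   accepted).
#' @param l_max maximum order (supported: 0..2).
#' @return n x sum(2l+1) matrix of harmonic components.
#' @export
sh_real <- function(vecs, l_max = 2L) {
  if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = 3)
  stopifnot(l_max %in% 0:2)
  nrm <- sqrt(rowSums(vecs^2))
  if (any(nrm < 1e-12)) stop("zero vector passed to sh_real")
  x <- vecs[, 1] / nrm
  y <- vecs[, 2] / nrm
  z <- vecs[, 3] / nrm
  out <- matrix(1, nrow(vecs), 1)
  if (l_max >= 1) out <- cbind(out, y, z, x)
  if (l_max >= 2) {
    s3 <- sqrt(3)
    out <- cbind(out,
                 s3 * x * y,
                 s3 * y * z,
                 (3 * z^2 - 1) / 2,
                 s3 * z * x,
                 s3 / 2 * (x^2 - y^2))
  }
  unname(out)
}

sh_layout <- function(l_max = 2L) {
  irreps(data.frame(mult = rep(1L, l_max + 1L), l = 0:l_max,
                    parity = as.integer((-1L)^(0:l_max))))
}

# ---- Wigner matrices (numerical, from the harmonics themselves) ------

# Fixed, well-spread sample directions used to solve for D.
.wigner_sample_vecs <- function(n = 40L) {
  k <- seq_len(n)
  theta <- acos(1 - 2 * (k - 0.5) / n)
  phi <- pi * (1 + sqrt(5)) * k
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Wigner rotation matrix for real spherical harmonics
#'
#' Returns the (2l+1) x (2l+1) orthogonal matrix D with
#' `sh_real(v %*% t(R))` block-l equal to `sh_real(v)` block-l times
#' t(D), i.e. Y_l(R v) = D Y_l(v). Solved numerically by least squares
#' from the package's own harmonic implementation, so it is independent
#' of the tensor-product code path it is used to test.
#'
#' @param l order (0, 1 or 2).
#' @param R a 3 x 3 rotation (or reflection) matrix.
#' @return the block rotation matrix.
#' @export
wigner_d_real <- function(l, R) {
  if (l == 0) return(matrix(1, 1, 1))
  V <- .wigner_sample_vecs()
  cols <- (l^2 + 1):((l + 1)^2)
  A <- sh_real(V, l_max = l)[, cols, drop = FALSE]
  B <- sh_real(V %*% t(R), l_max = l)[, cols, drop = FALSE]
  t(qr.solve(A, B))
}

# Block-diagonal Wigner matrix for a whole layout (including parity
# factors when det(R) < 0).
wigner_d_layout <- function(ir, R) {
  dtot <- irreps_dim(ir)
  D <- matrix(0, dtot, dtot)
  detR <- det(R)
  for (b in seq_len(nrow(ir))) {
    Dl <- wigner_d_real(ir$l[b], R)
    if (detR < 0) {
      # wigner_d_real carries the (-1)^l of the harmonics under the
      # improper part; a feature of declared parity p transforms with p
      # instead, hence the correction p * (-1)^l (unity for blocks of
      # natural parity, the only ones this architecture uses).
      Dl <- Dl * (ir$parity[b] * (-1L)^ir$l[b])
    }
    d <- 2L * ir$l[b] + 1L
    for (u in seq_len(ir$mult[b])) {
      cc <- ir$offset[b] + (u - 1L) * d + seq_len(d)
      D[cc, cc] <- Dl
    }
  }
  D
}

# ---- coupling (Gaunt) tensors ----------------------------------------

.irreps_env <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  # Golub-Welsch on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Gaunt-type coupling tensor for real harmonics, normalised to unit
# Frobenius norm. Returns array [2l1+1, 2l2+1, 2l3+1], or NULL when the
# integral vanishes identically (odd l1+l2+l3 or triangle violation).
coupling_tensor <- function(l1, l2, l3) {
  key <- paste(l1, l2, l3, sep = "_")
  if (!is.null(.irreps_env[[key]])) return(.irreps_env[[key]])
  if (l3 < abs(l1 - l2) || l3 > l1 + l2 || (l1 + l2 + l3) %% 2 == 1) {
    return(NULL)
  }
  gl <- gauss_legendre(12L)
  nphi <- 24L
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  V <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = nphi))
  w <- rep(gl$w, times = nphi) * (2 * pi / nphi)
  lmax <- max(l1, l2, l3)
  Y <- sh_real(V, l_max = lmax)
  blk <- function(l) Y[, (l^2 + 1):((l + 1)^2), drop = FALSE]
  Y1 <- blk(l1); Y2 <- blk(l2); Y3 <- blk(l3)
  G <- array(0, c(2 * l1 + 1, 2 * l2 + 1, 2 * l3 + 1))
  for (m3 in seq_len(2 * l3 + 1)) {
    G[, , m3] <- crossprod(Y1 * (w * Y3[, m3]), Y2)
  }
  fro <- sqrt(sum(G^2))
  if (fro < 1e-10) return(NULL)
  G <- G / fro
  G[abs(G) < 1e-12] <- 0
  .irreps_env[[key]] <- G
  G
}

# Sparse representation of a coupling tensor: data frame of nonzero
# entries (m1, m2, m3, c), 1-based component indices.
coupling_entries <- function(l1, l2, l3) {
  G <- coupling_tensor(l1, l2, l3)
  if (is.null(G)) return(NULL)
  nz <- which(abs(G) > 1e-11, arr.ind = TRUE)
  data.frame(m1 = nz[, 1], m2 = nz[, 2], m3 = nz[, 3], c = G[nz])
}
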