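# Shared helpers: random typed buffers, independent brute-force oracles and
# small generators. Oracles here are loop-based and share no code with the
# implementation paths they check.

ALL_DTYPES <- c("int8", "int16", "int32", "uint8", "uint16",
                "float32", "float64")

# random values exactly representable in `dtype` AND in its nearest
# MRC-writable type (so file round trips are bit-exact by construction)
rand_values <- function(dtype, n, seed) {
  set.seed(seed)
  switch(dtype,
         int8    = sample(-128:127, n, replace = TRUE),
         int16   = sample(-3000:3000, n, replace = TRUE),
         int32   = sample(-100000:100000, n, replace = TRUE),
         uint8   = sample(0:255, n, replace = TRUE),
         uint16  = sample(0:65535, n, replace = TRUE),
         float32 = dtype_cast(stats::rnorm(n), "float64", "float32"),
         float64 = dtype_cast(stats::rnorm(n), "float64", "float32"))
}

rand_image <- function(dtype, dims, seed, pixel_size = NULL) {
  d <- c(n = dims[1], z = dims[2], y = dims[3], x = dims[4])
  v <- rand_values(dtype, prod(d), seed)
  as_em_image(array(as.double(v), dim = unname(d[c("x", "y", "z", "n")])),
              dtype = dtype, pixel_size = pixel_size)
}

# explicit two-pass moment computation (population sd), loop-based
oracle_moments <- function(x) {
  x <- as.vector(x)
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / n
  ss <- 0
  mn <- Inf; mx <- -Inf
  for (v in x) {
    ss <- ss + (v - mu)^2
    if (v < mn) mn <- v
    if (v > mx) mx <- v
  }
  c(min = mn, max = mx, mean = mu, sd = sqrt(ss / n))
}

# signed frequency of each 1-based index on an n-point grid
# (0 .. ceil(n/2)-1, then the negative half; even grids carry -n/2)
grid_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= (n - 1L) %/% 2L, k, k - n)
}

# Brute-force spectral resize oracle: full naive DFT, per-axis centred
# crop/pad by explicit frequency bookkeeping (the even-grid crop keeps the
# source -m/2 bin for the new Nyquist), Hermitian symmetrization,
# renormalization, naive inverse. `arr` has dims (x, y) or (x, y, z);
# `new_dims` the matching target extents.
oracle_resize <- function(arr, new_dims) {
  old <- dim(arr)
  new_in <- new_dims
  if (length(old) == 2L) { old <- c(old, 1L); new_dims <- c(new_dims, 1L) }
  F <- naive_dft(arr, dim(arr))
  dim(F) <- old
  map_axis <- function(n_old, n_new) {
    f_new <- grid_freqs(n_new)
    if (n_new <= n_old) {
      # kept block is -n_new/2 .. n_new/2-1; the even-grid Nyquist carries
      # the source's -n_new/2 bin, all present in the old grid
      match(f_new %% n_old, grid_freqs(n_old) %% n_old)
    } else {
      match(f_new, grid_freqs(n_old))   # NA where zero-padded
    }
  }
  ix <- map_axis(old[1], new_dims[1])
  iy <- map_axis(old[2], new_dims[2])
  iz <- map_axis(old[3], new_dims[3])
  G <- array(0 + 0i, dim = new_dims)
  for (a in seq_along(ix)) for (b in seq_along(iy)) for (c in seq_along(iz)) {
    if (!is.na(ix[a]) && !is.na(iy[b]) && !is.na(iz[c])) {
      G[a, b, c] <- F[ix[a], iy[b], iz[c]]
    }
  }
  conj_of <- function(i, n) ((n - (i - 1L)) %% n) + 1L
  H <- G
  for (a in seq_along(ix)) for (b in seq_along(iy)) for (c in seq_along(iz)) {
    H[a, b, c] <- (G[a, b, c] +
                     Conj(G[conj_of(a, new_dims[1]), conj_of(b, new_dims[2]),
                            conj_of(c, new_dims[3])])) / 2
  }
  H <- H * prod(new_dims) / prod(old)
  out <- Re(naive_idft(H, new_dims))
  dim(out) <- new_in
  out
}

oracle_resize_2d <- function(mat, new_y, new_x) {
  oracle_resize(mat, c(new_x, new_y))
}

# full spectrum from a half-layout em_spectrum item, by explicit mirroring
full_spectrum_of <- function(spec, item = 1L) {
  d <- spec$source_dims
  nx <- d[["x"]]; ny <- d[["y"]]; nz <- d[["z"]]
  nxh <- nx %/% 2 + 1L
  half <- array(spec$coeffs[, , , item], dim = c(nxh, ny, nz))
  full <- array(0 + 0i, dim = c(nx, ny, nz))
  conj_of <- function(i, n) ((n - (i - 1L)) %% n) + 1L
  for (kx in seq_len(nx)) for (ky in seq_len(ny)) for (kz in seq_len(nz)) {
    if (kx <= nxh) full[kx, ky, kz] <- half[kx, ky, kz]
    else full[kx, ky, kz] <-
        Conj(half[nx - kx + 2L, conj_of(ky, ny), conj_of(kz, nz)])
  }
  full
}

# random typed table for property tests
rand_table <- function(nrow = 100, seed = 1) {
  set.seed(seed)
  em_table(tibble::tibble(
    id = seq_len(nrow),
    val = round(stats::runif(nrow, 0, 10), 3),
    grp = sample(c("aa", "bb", "cc"), nrow, replace = TRUE),
    keep = sample(c(TRUE, FALSE), nrow, replace = TRUE)))
}

# random filter expressions over rand_table columns (complete columns only)
rand_filter_expr <- function(seed) {
  set.seed(seed)
  atom <- function() {
    col <- sample(c("id", "val", "grp"), 1)
    if (col == "grp") {
      sprintf("grp %s \"%s\"", sample(c("==", "!="), 1),
              sample(c("aa", "bb", "cc"), 1))
    } else {
      sprintf("%s %s %s", col,
              sample(c("<", "<=", ">", ">=", "==", "!="), 1),
              if (col == "id") sample(1:100, 1) else
                sprintf("%.2f", stats::runif(1, 0, 10)))
    }
  }
  a <- atom(); b <- atom()
  switch(sample(4, 1),
         a,
         sprintf("%s and %s", a, b),
         sprintf("%s or %s", a, b),
         sprintf("not (%s)", a))
}

# random STAR documents for round-trip properties
rand_star_doc <- function(seed) {
  set.seed(seed)
  nblocks <- sample(1:3, 1)
  doc <- list()
  for (b in seq_len(nblocks)) {
    ncols <- sample(1:8, 1)
    nrows <- sample(0:50, 1)
    cols <- list()
    for (j in seq_len(ncols)) {
      ctype <- sample(c("int", "float", "string"), 1)
      x <- switch(ctype,
        int = sample(-1000:1000, nrows, replace = TRUE),
        float = round(stats::rnorm(nrows), sample(1:6, 1)),
        string = sample(c("plain", "with space", "qu'ote", "x_y", "A#B"),
                        nrows, replace = TRUE))
      if (nrows > 0 && stats::runif(1) < 0.3) {
        x[sample(nrows, max(1, nrows %/% 5))] <- NA
      }
      cols[[paste0("col", j)]] <- x
    }
    doc[[paste0("block", b)]] <- em_table(
      tibble::as_tibble(cols, .name_repair = "minimal"))
  }
  doc
}

# compare two tables after a STAR round trip: names, order, row count and
# values must agree; an all-integral float column may legitimately come back
# typed int, so numeric columns compare by value
expect_table_values_equal <- function(got, want) {
  expect_identical(names(got), names(want))
  expect_identical(nrow(got), nrow(want))
  for (nm in names(want)) {
    g <- got[[nm]]; w <- want[[nm]]
    expect_identical(is.na(g), is.na(w))
    if (all(is.na(w))) next   # column type is unknowable from missing tokens
    if (is.numeric(w)) {
      expect_true(is.numeric(g))
      expect_identical(as.double(g[!is.na(g)]), as.double(w[!is.na(w)]))
    } else {
      expect_identical(as.character(g[!is.na(g)]),
                       as.character(w[!is.na(w)]))
    }
  }
}

# run an emkit CLI entry point in a fresh Rscript process; returns list
# (status, stdout lines)
run_cli_subprocess <- function(fun, args) {
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  old <- Sys.getenv("R_LIBS", unset = NA)
  Sys.setenv(R_LIBS = libs)
  on.exit(if (is.na(old)) Sys.unsetenv("R_LIBS") else
    Sys.setenv(R_LIBS = old))
  code <- sprintf(
    "quit(status = emkit::%s(commandArgs(trailingOnly = TRUE)), save = 'no')",
    fun)
  out <- suppressWarnings(
    system2("Rscript", c("-e", shQuote(code), vapply(args, shQuote,
                                                     character(1))),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
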