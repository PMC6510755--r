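# Fixtures shared across test files.  Everything is generated in code.

# A small volume with one lit voxel (value v) at index (i, j, k).
one_voxel_volume <- function(dims = c(9, 9, 5), at = c(5, 5, 3), v = 7,
                             spacing = c(1, 1, 1)) {
  arr <- array(0, dim = dims)
  arr[at[1], at[2], at[3]] <- v
  structure(list(intensities = arr, spacing = spacing, patient_id = "V1"),
            class = "pet_volume")
}

# Brute-force angle-0 MIP: max over the y axis, no interpolation.
brute_mip0 <- function(arr) {
  d <- dim(arr)
  out <- matrix(0, d[3], d[1])
  for (z in seq_len(d[3])) {
    for (xx in seq_len(d[1])) out[z, xx] <- max(arr[xx, , z])
  }
  out
}

# Exact 90-degree counterclockwise (viewed from superior) in-plane rotation
# of a square-slice volume under the package's convention:
# rotated[i, j, k] = original[j, n + 1 - i, k].
rotate90_volume <- function(arr) {
  n <- dim(arr)[1]
  stopifnot(n == dim(arr)[2])
  out <- arr
  for (i in seq_len(n)) out[i, , ] <- arr[, n + 1 - i, ]
  out
}

# A tiny synthetic MIP dataset (not phantom-based): n_pat patients with
# n_views images each.  The class signal lives entirely in `rows` (the
# pelvic band by default) as two equal-mass patterns -- solid center block
# for males, two lateral blocks for females -- so the global image mean is
# class-independent and a mean-fill mask truly destroys the signal.
toy_mip_dataset <- function(n_pat = 24, n_views = 3, rows = 42:52,
                            seed = 42, scanners = "scanner1") {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_pat))
  sex <- rep(c("male", "female"), length.out = n_pat)
  scanner <- rep(scanners, length.out = n_pat)
  cols <- list(); pid <- character(); ang <- numeric(); scn <- character()
  for (i in seq_len(n_pat)) {
    for (v in seq_len(n_views)) {
      im <- matrix(runif(4096, 0, 0.15), 64, 64)
      if (sex[i] == "male") {
        im[rows, 23:42] <- im[rows, 23:42] + 0.6
      } else {
        im[rows, 10:19] <- im[rows, 10:19] + 0.6
        im[rows, 45:54] <- im[rows, 45:54] + 0.6
      }
      cols[[length(cols) + 1L]] <- as.numeric(pmin(im, 1))
      pid <- c(pid, ids[i]); ang <- c(ang, (v - 1) * 10)
      scn <- c(scn, scanner[i])
    }
  }
  structure(list(images = do.call(cbind, cols), patient_id = pid,
                 angle = ang, scanner = scn,
                 meta = data.frame(patient_id = ids, sex = sex,
                                   age = 60, weight = 70, scanner = scanner,
                                   stringsAsFactors = FALSE),
                 out_size = 64),
            class = "mip_dataset")
}

# A small, fast network spec for tests that train.
tiny_spec <- function(head = "softmax") {
  network_spec(filters = c(4, 8, 8, 16), dense_units = 24, head = head,
               dropout_rate = 0.3)
}
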