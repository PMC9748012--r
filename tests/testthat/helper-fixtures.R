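# shared fixtures, built in code

cal_paper <- calibration(28.9, 0.4)   # system sensitivity of the study scanner
cal_exact <- calibration(28.9, 0)

# uniform-valued image helper
uniform_image <- function(value = 1, dims = c(16L, 16L, 16L), spacing = 4,
                          duration = NA_real_) {
  image_volume(array(value, dims), spacing = spacing, duration = duration)
}

# brute-force VOI oracle: explicit loop over every voxel, centre-in-sphere
brute_force_voi <- function(image, center, radius) {
  d <- dim(image$voxels)
  total <- 0; k <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    p <- (c(i, j, l) - 0.5) * image$spacing
    if (sum((p - center)^2) <= radius^2) {
      total <- total + image$voxels[i, j, l]
      k <- k + 1L
    }
  }
  list(count_rate = total, volume = k * prod(image$spacing) / 1000)
}

# Table of serial bone-metastasis activity measurements shipped with the
# package (time h, activity MBq, uncertainty MBq, quantification method)
tac_fixture_path <- function() {
  system.file("extdata", "tac_bone_metastasis.csv", package = "voiquant")
}

tac_fixture <- function() read_tac_csv(tac_fixture_path())
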