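# Shared fixtures, built once per test run. Phantoms are small enough to keep
# the suite fast but large enough that surface errors are in the asymptotic
# regime.

seg_cfg <- segConfig(min_component_volume_ml = 50)
seg_cfg_small <- segConfig(min_component_volume_ml = 1)

.fx <- new.env()
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  .fx[[name]]
}

sphere50 <- function() fixture("sphere50", function()
  makePhantom("sphere", list(r = 50), spacing_mm = 1))
sphere40 <- function() fixture("sphere40", function()
  makePhantom("sphere", list(r = 40), spacing_mm = 1))
cube50 <- function() fixture("cube50", function()
  makePhantom("cube", list(a = 50), spacing_mm = 1))
cyl_fix <- function() fixture("cyl_fix", function()
  makePhantom("cylinder", list(r = 30, h = 100), spacing_mm = 1))

# Write a synthetic axial DICOM series: uniform stored value per slice.
write_dicom_series <- function(dir, n_slices = 3, stored = 1024L, nx = 16,
                               ny = 16, z_step = 3, thickness = 3,
                               uid = "1.2.826.0.1.999999.1",
                               slope = 1, intercept = -1024,
                               names = sprintf("s%02d.dcm", seq_len(n_slices)),
                               z0 = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_slices))
    ibsa:::.write_dicom_slice(
      file.path(dir, names[i]), matrix(as.integer(stored), nx, ny),
      ipp = c(-10, -20, z0 + (i - 1) * z_step),
      pixel_spacing_yx = c(0.7, 0.7), slice_thickness = thickness,
      series_uid = uid, rescale_slope = slope, rescale_intercept = intercept)
  dir
}
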