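# Shared fixtures: a desk-scale phantom world (same 48 mm physical extent
# as the default, coarser 0.75 mm voxels so unit tests stay fast).

small_config <- function(n_fpu = 4, f = c(0.47, 0.50, 0.52, 0.60), seed = 7,
                         ...) {
  phantom_config(grid_shape = c(64, 64, 64), voxel_size_mm = rep(0.75, 3),
                 n_fpu = n_fpu, f = f, seed = seed, ...)
}

# ROI-mean VFA T1 fit for one label over a flip-angle series
fit_roi_t1 <- function(series, mask, label, acq) {
  sig <- vapply(series, roi_mean_signal, numeric(1), mask = mask, label = label)
  fit_t1_vfa(vfa_signal_set(sig, acq))
}

ivc_label_of <- function(mask) {
  mask$label_table$label[mask$label_table$role == "IVC"]
}

# noiseless VFA signals under the TE << T2 simplification
ideal_signals <- function(m0, t1, acq) {
  gre_signal(m0, t1, acq$flip_angles_deg, acq)
}
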