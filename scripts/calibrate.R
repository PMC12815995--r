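#!/usr/bin/env Rscript
# Re-derives the shipped motion-segment calibration from the three reference
# nucleus-pulposus pressures (baseline 0.15 MPa; -0.005 MPa flexible-axis
# change; +0.297 MPa stiff-axis change) and prints the constants that
# motion_segment() ships as defaults.

suppressPackageStartupMessages(library(vertegrow))

cal <- calibrate_defaults()
cat("calibrated constants:\n")
cat(sprintf("  swelling_pressure_p0     = %.12g MPa\n", cal$swelling_pressure_p0))
cat(sprintf("  np_compliance_C          = %.12g MPa^-1\n", cal$np_compliance_C))
cat(sprintf("  np_centroid_offset_delta = %.12g mm\n", cal$np_centroid_offset_delta))
cat(sprintf("  E_af                     = %.12g MPa\n", cal$E_af))
cat("achieved pressures (MPa):\n")
print(cal$achieved)

ship <- motion_segment()
stopifnot(abs(ship$C - cal$np_compliance_C) < 1e-6,
          abs(ship$delta - cal$np_centroid_offset_delta) < 1e-6,
          abs(ship$E_af - cal$E_af) < 1e-9)
cat("shipped motion_segment() defaults match the calibration.\n")
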