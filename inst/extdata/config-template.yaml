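# hfital run configuration template.
# Every key is optional; values shown are the defaults.

# Nominal sampling rate of the device (Hz). The rate inferred from the
# acceleration CSV timestamps must agree within 1%.
sample_rate_hz: 25

# Algorithm variant: "hfital" (posture-first tree, anterior-posterior-axis
# counts) or "moxal" (activity-first tree, tri-axial counts).
variant: hfital

# Adjustable parameters. Omitted values fall back to the variant preset:
# hfital -> WS 4 s, PA Th 4.3 cps, SO Th 0.8 g
# moxal  -> WS 2 s, PA Th 7 cps,   SO Th 0.8 g
ws_seconds: 4
pa_th_cps: 4.3
so_th_g: 0.8

# Counts filter: band edges (Hz) and overall Butterworth order (even) of
# the zero-phase band-pass isolating the movement component.
filter_band_hz: [0.25, 11.0]
filter_order: 4

# Mapping of anatomical roles onto the sensor columns, and per-column sign
# flips applied at load time. After flipping, quiet standing must read
# +1 g on the longitudinal axis.
axis_roles:
  longitudinal: ax
  anterior_posterior: ay
  medio_lateral: az
axis_signs:
  ax: 1
  ay: 1
  az: 1

# Manual alignment shift (s) added to reference event times; inputs are
# otherwise assumed pre-synchronized.
offset_s: 0

# Cohort aggregation of the optimizer objective: median or mean.
aggregate: median
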