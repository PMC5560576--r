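# Miniplate catalog (Modus/Trauma 2.0 style straight plates).
#
# Only the printed catalog dimensions are listed per model: overall length,
# ring counts and (where the catalog prints one) the central bar length.
# The remaining cross-section dimensions are shared defaults consistent with
# a 2.0 mm screw system and can be overridden per model. Bar lengths are
# derived from the layout closure rule (see ?plate_spec):
#   overall_length = ring_outer_diameter
#                  + (n_rings - 1) * attachment_width
#                  + sum(bar_lengths)
# where attachment_width = 2 * sqrt((ring_outer_diameter/2)^2
#                                   - (bridge_width/2)^2)
# is the chord-to-chord width of a ring between its flat attachment sides.
# New models can be added here without code changes.
defaults:
  ring_outer_diameter: 4.0   # mm
  ring_hole_diameter: 2.0    # mm, plain cylindrical screw hole
  plate_thickness: 1.0       # mm
  bridge_width: 2.0          # mm, bar cross-section width
  bridge_height: 1.0         # mm, bar cross-section height
models:
  - model_id: M-4138
    n_end_rings: 2
    n_middle_rings: 2
    overall_length: 23.0     # mm
  - model_id: M-4320
    n_end_rings: 2
    n_middle_rings: 2
    overall_length: 29.0     # mm
    central_bar: 9.0         # mm, face-to-face central bar length
  - model_id: M-4322
    n_end_rings: 2
    n_middle_rings: 4
    overall_length: 35.0     # mm
    central_bar: 9.0         # mm
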