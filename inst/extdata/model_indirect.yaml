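# Reconstructed, approximate geometry for INDIRECT immunolabeling
# (primary IgG bound by a site-specifically labeled polyclonal
# secondary IgG).
#
# Five rigid segments: primary CDR -> hinge (Fab), hinge -> secondary
# epitope (uniform over the primary Fc region, encoded as a continuous
# length range 0-7 nm along the Fc), secondary CDR -> hinge (Fab),
# hinge -> Glu295, Glu -> reporter. Same hinge flexibility and linker
# as the direct model; the secondary Fab orientation relative to the
# primary Fc is broad (+/-100). Reconstruction, not measured constants;
# see the methods vignette.
model:
  name: indirect-igg
  d_min: 1.0
  arc_res: 0.5
  microtubule:
    outer_radius: 12.5
  epitope:
    y0: 0.0
    z0: 12.5
    phi1_deg: [0, 360]
    theta1_deg: [-40, 40]
  segments:
    - name: 1CDR-1Hinge
      lengths: [7.8, 8.2]
    - name: 1Hinge-2epitope
      range: [0.1, 7.0]     # secondary epitope uniform along the Fc
      phi_deg: [-110, 110]
      theta_deg: [-110, 110]
    - name: 2CDR-2Hinge
      lengths: [7.8, 8.2]
      phi_deg: [-100, 100]
      theta_deg: [-100, 100]
    - name: 2Hinge-2Glu
      lengths: [3.0]
      phi_deg: [-110, 110]
      theta_deg: [-110, 110]
    - name: 2Glu-Reporter
      range: [0.5, 1.5]
      phi_deg: [-180, 180]
      theta_deg: [-180, 180]
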