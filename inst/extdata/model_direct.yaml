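# Reconstructed, approximate geometry for DIRECT immunolabeling of
# microtubules by a site-specifically labeled primary IgG.
#
# Three rigid segments: CDR -> hinge (Fab arm), hinge -> Glu295 (within
# the Fc CH2 domain, close to the hinge), Glu -> reporter (DBCO/DIBO
# C5-type linker plus side chain). Lengths in nm follow published IgG2a
# crystal-structure dimensions (the two Fab arms differ slightly, hence
# the two-value set). Angle bounds (degrees) encode a broad hinge
# (interval +/-110 about the preceding segment axis) and a restricted
# Fab-epitope orientation (polar tilt +/-40 about the outward surface
# normal, azimuth free). These values are the package's reconstruction,
# not measured constants; see the methods vignette.
model:
  name: direct-igg
  d_min: 1.0          # nm, steric self-avoidance
  arc_res: 0.5        # nm, clash-test sampling
  microtubule:
    outer_radius: 12.5
  epitope:
    y0: 0.0
    z0: 12.5
    phi1_deg: [0, 360]     # azimuth about the microtubule axis: free
    theta1_deg: [-40, 40]  # polar tilt of the Fab from the radial direction
  segments:
    - name: CDR-Hinge
      lengths: [7.8, 8.2]
      # orientation taken from the epitope block (first segment)
    - name: Hinge-Glu
      lengths: [3.0]
      phi_deg: [-110, 110]
      theta_deg: [-110, 110]
    - name: Glu-Reporter
      range: [0.5, 1.5]
      phi_deg: [-180, 180]
      theta_deg: [-180, 180]
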